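make_de <- function(gene_ids, sig) {
  # minimal de_result: significant genes get tiny adjusted p
  out <- tibble::tibble(
    gene_id = gene_ids,
    log2fc = ifelse(sig, 2, 0),
    stat = ifelse(sig, 5, 0),
    pval = ifelse(sig, 1e-5, 0.8),
    adj_pval = ifelse(sig, 1e-4, 0.9))
  class(out) <- c("de_result", class(out))
  out
}

test_that("ora reproduces the exhaustive hypergeometric tail", {
  genes <- sprintf("g%02d", 1:20)
  de <- make_de(genes, sig = genes %in% genes[1:5])      # K = 5
  gsc <- gene_set_collection(list(S = c(genes[1:3], genes[6:7])))  # k=3, n=5
  r <- ora(de, gsc)
  expect_equal(r$pval, 1126 / 15504, tolerance = 1e-12)
  expect_equal(r$score, 3)

  # k = 0: tail includes zero, p = 1
  gsc0 <- gene_set_collection(list(S = genes[6:12]))
  expect_equal(ora(de, gsc0)$pval, 1)

  # S = universe: p = P(X >= K) = 1
  gscU <- gene_set_collection(list(S = genes))
  expect_equal(ora(de, gscU, gs_max_size = 25)$pval, 1)
})

test_that("ora with zero significant genes warns and returns all-1 p-values", {
  genes <- sprintf("g%02d", 1:20)
  de <- make_de(genes, sig = rep(FALSE, 20))
  gsc <- gene_set_collection(list(A = genes[1:6], B = genes[7:12]))
  expect_warning(r <- ora(de, gsc), "no significant")
  expect_equal(r$pval, c(1, 1))
})

test_that("ora p-values match pmf enumeration over a parameter sweep", {
  # property: for sampled (N, K, n, k) grids with N <= 30, the upper tail
  # equals the enumerated hypergeometric sum
  for (N in c(5, 11, 18, 24, 30)) {
    genes <- sprintf("g%02d", seq_len(N))
    for (K in unique(c(0, 1, N %/% 3, N %/% 2, N))) {
      de <- make_de(genes, sig = seq_len(N) <= K)
      for (n in unique(c(1, 2, N %/% 2, N))) {
        members <- genes[seq_len(n)]
        gsc <- gene_set_collection(list(S = members))
        r <- suppressWarnings(ora(de, gsc, gs_min_size = 1,
                                  gs_max_size = N))
        k <- sum(seq_len(n) <= K)
        jj <- k:min(K, n)
        oracle <- sum(choose(K, jj) * choose(N - K, n - jj)) / choose(N, n)
        expect_equal(r$pval, oracle, tolerance = 1e-12,
                     info = sprintf("N=%d K=%d n=%d", N, K, n))
      }
    }
  }
})

test_that("running-sum enrichment score matches hand enumeration", {
  # all k members on top: ES = 1
  expect_equal(gsea_enrichment_score(c(5, 4, 3, 2, 1),
                                     c(TRUE, TRUE, FALSE, FALSE, FALSE),
                                     weight_exp = 0), 1)
  # N = 4, members at 1 and 3: running sum .5, 0, .5, 0 -> ES = .5
  expect_equal(gsea_enrichment_score(c(4, 3, 2, 1),
                                     c(TRUE, FALSE, TRUE, FALSE),
                                     weight_exp = 0), 0.5)
  # bottom-concentrated set has the same |ES| by symmetry at weight 0
  top <- gsea_enrichment_score(c(4, 3, 2, 1),
                               c(TRUE, TRUE, FALSE, FALSE), 0)
  bottom <- gsea_enrichment_score(c(4, 3, 2, 1),
                                  c(FALSE, FALSE, TRUE, TRUE), 0)
  expect_equal(abs(bottom), abs(top))
  expect_error(gsea_enrichment_score(1:3, rep(TRUE, 3), 0), "undefined")
})

test_that("weight 0 ES equals the two-sample KS statistic on tie-free input", {
  set.seed(5)
  for (rep in 1:20) {
    N <- sample(5:12, 1)
    k <- sample(2:(N - 2), 1)
    stats_desc <- sort(runif(N), decreasing = TRUE)
    mask <- seq_len(N) %in% sample(N, k)
    es <- gsea_enrichment_score(stats_desc, mask, weight_exp = 0)
    # oracle: sup difference of member vs non-member rank ECDFs
    ranks <- seq_len(N)
    cdf_in <- sapply(ranks, function(r) mean(ranks[mask] <= r))
    cdf_out <- sapply(ranks, function(r) mean(ranks[!mask] <= r))
    expect_equal(abs(es), max(abs(cdf_in - cdf_out)), tolerance = 1e-12)
  }
})

test_that("ES agrees with the fgsea reference implementation", {
  skip_if_not_installed("fgsea")
  set.seed(6)
  for (rep in 1:10) {
    N <- 50
    stats_desc <- sort(rnorm(N, sd = 2), decreasing = TRUE)
    sel <- sort(sample(N, 8))
    mask <- seq_len(N) %in% sel
    es <- gsea_enrichment_score(stats_desc, mask, weight_exp = 1)
    ref <- fgsea::calcGseaStat(stats_desc, selectedStats = sel,
                               gseaParam = 1, scoreType = "std")
    expect_equal(es, ref, tolerance = 1e-6)
  }
})

test_that("permutation p-values are never zero and count correctly", {
  expect_equal(permutation_pvalue(10, rep(1, 999)), 1 / 1000)
  expect_equal(permutation_pvalue(0, 1:999), 1)
  expect_equal(permutation_pvalue(5, c(1, 5, 7, 9)), (3 + 1) / (4 + 1))
  expect_equal(permutation_pvalue(5, c(1, 5, 7, 9), exhaustive = TRUE),
               3 / 4)
  expect_error(permutation_pvalue(1, numeric(0)), "no permutation")
})

test_that("wilcoxon statistic hits its maximum for top-ranked members", {
  # members hold the k largest |t| among N genes
  m <- rbind(matrix(rep(c(0, 0, 0, 5, 5, 5), 3), nrow = 3, byrow = TRUE),
             matrix(rnorm(7 * 6, sd = 0.01), nrow = 7))
  rownames(m) <- sprintf("g%02d", 1:10); colnames(m) <- paste0("s", 1:6)
  d <- expression_dataset(m, groups = rep(c(0L, 1L), each = 3))
  gsc <- gene_set_collection(list(S = sprintf("g%02d", 1:3)))
  r <- safe_run(d, gsc, "wilcoxon", permutation_config(10, seed = 1),
                gs_min_size = 1)
  expect_equal(r$score, 10 + 9 + 8)
})

test_that("safe_run with exhaustive relabeling equals the brute-force oracle", {
  set.seed(7)
  m <- matrix(rnorm(12 * 6), nrow = 12,
              dimnames = list(sprintf("g%02d", 1:12), paste0("s", 1:6)))
  m[1:4, 4:6] <- m[1:4, 4:6] + 2
  d <- expression_dataset(m, groups = rep(c(0L, 1L), each = 3))
  gsc <- disjoint_sets(d, n_sets = 3, set_size = 4)
  cfg <- permutation_config(seed = 1, exhaustive = TRUE)

  # engine sorts genes by id; ids here are already sorted
  idx <- lapply(unclass(gsc), function(g) match(g, d$gene_ids))

  r_w <- safe_run(d, gsc, "wilcoxon", cfg, gs_min_size = 1)
  p_w <- brute_force_exhaustive_p(d, idx, function(st, i) sum(rank(st)[i]))
  expect_equal(r_w$pval[match(names(gsc), r_w$set_id)], p_w)

  r_s <- safe_run(d, gsc, "sum_sq", cfg, gs_min_size = 1)
  p_s <- brute_force_exhaustive_p(d, idx, function(st, i) sum(st[i]^2))
  expect_equal(r_s$pval[match(names(gsc), r_s$set_id)], p_s)
})

test_that("fixed seeds make permutation rankings bit-reproducible", {
  d <- null_dataset(60, 4, seed = 8)
  gsc <- disjoint_sets(d, 6, 10)
  r1 <- sbea(d, gsc, "gsea", cfg = permutation_config(50, seed = 3))
  r2 <- sbea(d, gsc, "gsea", cfg = permutation_config(50, seed = 3))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- sbea(d, gsc, "gsea", cfg = permutation_config(50, seed = 4))
  expect_false(identical(r1$pval, r3$pval))
})

test_that("null data give roughly uniform permutation p-values", {
  d <- null_dataset(600, 5, seed = 9)
  gsc <- disjoint_sets(d, 60, 10)
  r <- safe_run(d, gsc, "wilcoxon", permutation_config(200, seed = 2))
  alpha <- 0.1
  frac <- mean(r$pval < alpha)
  se <- sqrt(alpha * (1 - alpha) / 60)
  expect_lt(abs(frac - alpha), 3 * se)
})

test_that("all four set methods top-rank a strongly spiked set", {
  sim <- simulate_study(simulation_spec(n_genes = 400, n_sets = 8,
                                        set_size = 20, effect_size = 3,
                                        seed = 11))
  de <- suppressWarnings(de_statistics(sim$data))
  cfg <- permutation_config(200, seed = 12)
  spiked <- sim$truth$set_id[sim$truth$spiked]
  expect_equal(suppressWarnings(ora(de, sim$gsc))$set_id[1], spiked)
  expect_equal(sbea(sim$data, sim$gsc, "gsea", cfg = cfg)$set_id[1], spiked)
  expect_equal(sbea(sim$data, sim$gsc, "safe", cfg = cfg)$set_id[1], spiked)
  expect_equal(sbea(sim$data, sim$gsc, "samgs", cfg = cfg)$set_id[1], spiked)
})

test_that("rankings come back sorted with sets filtered to measured genes", {
  d <- null_dataset(40, 3, seed = 13)
  gsc <- gene_set_collection(list(
    A = d$gene_ids[1:8], B = d$gene_ids[9:16],
    ghost = c("nope1", "nope2", "nope3", "nope4", "nope5")))
  expect_message(
    r <- safe_run(d, gsc, "sum_sq", permutation_config(15, seed = 1)),
    "without measured genes")
  expect_equal(sort(r$set_id), c("A", "B"))
  expect_true(!is.unsorted(r$pval))
  expect_true(all(r$adj_pval >= r$pval))
})

test_that("n_perm above the number of distinct relabelings warns", {
  d <- null_dataset(10, 2, seed = 14)   # choose(4, 2) = 6 relabelings
  gsc <- disjoint_sets(d, 1, 5)
  expect_warning(
    safe_run(d, gsc, "sum_sq", permutation_config(50, seed = 1),
             gs_min_size = 1),
    "distinct relabelings")
})
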