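de_from_lfc <- function(lfc) {
  out <- tibble::tibble(
    gene_id = names(lfc), log2fc = unname(lfc),
    stat = unname(lfc), pval = 0.5, adj_pval = 0.5)
  class(out) <- c("de_result", class(out))
  out
}

test_that("edge consistency follows the tanh-product semantics", {
  de <- de_from_lfc(c(r = 0, t = 0, up = 50, down = -50, one = 1))
  act <- regulatory_network("r", "t", "activation")
  expect_equal(edge_consistency(de, act)$consistency, 0)

  # inhibition with strongly opposed partners approaches +1
  inh <- regulatory_network("up", "down", "inhibition")
  expect_equal(edge_consistency(de, inh)$consistency, 1, tolerance = 1e-12)

  act1 <- regulatory_network("one", "one", "activation")
  expect_equal(edge_consistency(de, act1)$consistency, 0.5800256584,
               tolerance = 1e-9)

  # unmeasured endpoint: edge skipped, not an error
  ghost <- regulatory_network("r", "missing", "activation")
  expect_equal(nrow(edge_consistency(de, ghost)), 0L)
})

test_that("flipping every edge effect negates every consistency", {
  set.seed(21)
  genes <- sprintf("g%02d", 1:30)
  de <- de_from_lfc(stats::setNames(rnorm(30), genes))
  grn <- regulatory_network(sample(genes, 40, TRUE), sample(genes, 40, TRUE),
                            sample(c("activation", "inhibition"), 40, TRUE))
  flipped <- regulatory_network(grn$regulator, grn$target,
                                ifelse(grn$effect == "activation",
                                       "inhibition", "activation"))
  expect_equal(edge_consistency(de, flipped)$consistency,
               -edge_consistency(de, grn)$consistency)
})

test_that("ggea handles edge-free sets and bounds the normalized score", {
  sim <- simulate_study(simulation_spec(n_genes = 200, n_sets = 4,
                                        set_size = 20, seed = 22))
  # a set with no network edges at all: genes outside every simulated set
  free <- setdiff(sim$data$gene_ids,
                  c(unlist(sim$gsc), sim$grn$regulator, sim$grn$target))
  lonely <- gene_set_collection(c(unclass(sim$gsc),
                                  list(lonely = free[1:20])))
  r <- ggea(sim$data, lonely, sim$grn,
            permutation_config(30, seed = 1))
  lone_row <- r[r$set_id == "lonely", ]
  expect_true(lone_row$no_edges)
  expect_equal(lone_row$score, 0)
  expect_equal(lone_row$pval, 1)
  expect_true(all(abs(r$norm_score) <= 1 + 1e-12))
})

test_that("a fully consistent strongly shifted cascade maxes out ggea", {
  # activation chain with huge same-direction shifts -> norm score ~ 1
  n <- 40
  genes <- sprintf("g%02d", 1:n)
  set.seed(23)
  m <- matrix(rnorm(n * 8, sd = 0.05), nrow = n,
              dimnames = list(genes, paste0("s", 1:8)))
  m[1:6, 5:8] <- m[1:6, 5:8] + 10       # cascade genes all up in cases
  d <- expression_dataset(m, groups = rep(c(0L, 1L), each = 4))
  grn <- regulatory_network(genes[1:5], genes[2:6],
                            rep("activation", 5))
  gsc <- gene_set_collection(list(cascade = genes[1:6],
                                  noise = genes[7:16]))
  cfg <- permutation_config(60, seed = 24)
  r <- suppressWarnings(ggea(d, gsc, grn, cfg))
  cas <- r[r$set_id == "cascade", ]
  expect_gt(cas$norm_score, 0.99)
  # the raw score is invariant under the group-complement relabeling
  # (tanh is odd, so both factors of every product flip), so the smallest
  # attainable p is bounded by the rate of drawing it, not 1/(B + 1)
  expect_lt(cas$pval, 0.1)
  expect_equal(r$set_id[1], "cascade")
})

test_that("ggea exhaustive p-values equal the relabeling counting oracle", {
  set.seed(25)
  genes <- sprintf("g%02d", 1:8)
  m <- matrix(rnorm(8 * 6), nrow = 8,
              dimnames = list(genes, paste0("s", 1:6)))
  m[1:4, 4:6] <- m[1:4, 4:6] + 1.5
  d <- expression_dataset(m, groups = rep(c(0L, 1L), each = 3))
  grn <- regulatory_network(c("g01", "g03"), c("g02", "g04"),
                            c("activation", "inhibition"))
  gsc <- gene_set_collection(list(S = genes[1:4]))
  r <- ggea(d, gsc, grn, permutation_config(seed = 1, exhaustive = TRUE),
            gs_min_size = 1)

  # counting oracle over all choose(6,3) relabelings
  combos <- utils::combn(6, 3)
  score_for <- function(case_cols) {
    g <- rep(0L, 6); g[case_cols] <- 1L
    lfc <- apply(m, 1, function(v) mean(v[g == 1L]) - mean(v[g == 0L]))
    tanh(lfc["g01"]) * tanh(lfc["g02"]) -
      tanh(lfc["g03"]) * tanh(lfc["g04"])
  }
  obs <- score_for(4:6)
  perm <- apply(combos, 2, score_for)
  expect_equal(r$pval, sum(perm >= obs) / ncol(combos))
  expect_equal(r$score, unname(obs), tolerance = 1e-12)
})

test_that("consistency-spiked sets beat effect-randomized sets of equal size", {
  sim1 <- simulate_study(simulation_spec(n_genes = 300, n_sets = 6,
                                         set_size = 20, effect_size = 3,
                                         network_consistency = 1,
                                         seed = 26))
  r1 <- ggea(sim1$data, sim1$gsc, sim1$grn,
             permutation_config(100, seed = 1))
  spiked <- sim1$truth$set_id[sim1$truth$spiked]
  ns_spiked <- r1$norm_score[r1$set_id == spiked]

  sim2 <- simulate_study(simulation_spec(n_genes = 300, n_sets = 6,
                                         set_size = 20, effect_size = 3,
                                         network_consistency = 0.5,
                                         seed = 26))
  r2 <- ggea(sim2$data, sim2$gsc, sim2$grn,
             permutation_config(100, seed = 1))
  ns_half <- r2$norm_score[r2$set_id == spiked]
  expect_gt(ns_spiked, ns_half + 0.2)
  expect_lt(abs(ns_half), 0.35)   # rho = 0.5: signs cancel on average
})

test_that("the plug-in contract is enforced", {
  d <- null_dataset(30, 3, seed = 27)
  gsc <- disjoint_sets(d, 3, 10)

  bad_len <- function(data, gs, alpha, grn = NULL) c(0.1, 0.2)
  register_plugin("bad_len", bad_len)
  expect_error(run_plugin("bad_len", d, gsc), "2 value\\(s\\) for 3")

  bad_range <- function(data, gs, alpha, grn = NULL) c(0.1, 0.2, 1.7)
  register_plugin("bad_range", bad_range)
  expect_error(run_plugin("bad_range", d, gsc), "outside \\[0, 1\\]")

  needs_net <- function(data, gs, alpha, grn) rep(0.5, length(gs))
  register_plugin("needs_net", needs_net, requires_network = TRUE)
  expect_error(run_plugin("needs_net", d, gsc), "requires a regulatory")

  expect_error(run_plugin("spia", d, gsc), "reserved")
  expect_error(run_plugin("no_such", d, gsc), "unknown")

  ok <- function(data, gs, alpha, grn = NULL) {
    stats::setNames(c(0.2, 0.1, 0.9), names(gs))[names(gs)]
  }
  register_plugin("ok", ok)
  r <- run_plugin("ok", d, gsc)
  expect_equal(r$set_id[1:2], c("S02", "S01"))
  expect_true(all(r$score == -r$pval))
})

test_that("ora exposed through the plug-in interface reproduces native ora", {
  sim <- simulate_study(simulation_spec(n_genes = 300, n_sets = 6,
                                        set_size = 20, effect_size = 3,
                                        seed = 28))
  de <- suppressWarnings(de_statistics(sim$data))
  native <- suppressWarnings(ora(de, sim$gsc))

  ora_plugin <- function(data, gs, alpha, grn = NULL) {
    de_in <- suppressWarnings(de_statistics(data))
    r <- suppressWarnings(ora(de_in, gs, alpha = alpha))
    r$pval[match(names(gs), r$set_id)]
  }
  register_plugin("ora_plugin", ora_plugin)
  via_plugin <- run_plugin("ora_plugin", sim$data, sim$gsc)
  expect_equal(via_plugin$set_id, native$set_id)
  expect_equal(via_plugin$pval, native$pval)
})
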