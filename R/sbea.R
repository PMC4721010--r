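# Set-based enrichment: ORA plus a shared sample-permutation engine driving
# the SAFE-style framework (Wilcoxon rank-sum), GSEA (running-sum statistic)
# and SAMGS-type (sum of squared t) global statistics.

#' Permutation configuration
#'
#' @param n_perm Number of random sample-label permutations (default 1000).
#'   Ignored when `exhaustive = TRUE`.
#' @param seed Integer seed making the permutation null reproducible.
#' @param paired Permute within blocks (label swaps inside each case/control
#'   pair) instead of freely.
#' @param exhaustive Enumerate all distinct relabelings instead of sampling.
#'   P-values are then exact counts `b/B` over the full enumeration (the
#'   observed labeling is part of it, so they stay strictly positive);
#'   random permutations use `(b + 1)/(B + 1)`.
#' @return A list of class `permutation_config`.
#' @export
permutation_config <- function(n_perm = 1000, seed = NULL, paired = FALSE,
                               exhaustive = FALSE) {
  stopifnot(n_perm >= 1)
  structure(list(n_perm = as.integer(n_perm), seed = seed,
                 paired = isTRUE(paired), exhaustive = isTRUE(exhaustive)),
            class = "permutation_config")
}

# All distinct 0/1 label vectors with the observed number of cases.
exhaustive_labels <- function(groups) {
  n <- length(groups)
  n1 <- sum(groups)
  idx <- utils::combn(n, n1)
  L <- matrix(0L, nrow = n, ncol = ncol(idx))
  L[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n1))] <- 1L
  L
}

# samples x B matrix of 0/1 relabelings (random unless exhaustive).
# Column 0 semantics: the observed labeling is handled by the caller.
permutation_labels <- function(groups, cfg) {
  if (cfg$exhaustive) return(exhaustive_labels(groups))
  n_distinct <- choose(length(groups), sum(groups))
  if (cfg$n_perm > n_distinct) {
    warning("n_perm (", cfg$n_perm, ") exceeds the ", n_distinct,
            " distinct relabelings; duplicates permitted")
  }
  vapply(seq_len(cfg$n_perm), function(b) sample(groups),
         integer(length(groups)))
}

# Per-gene |t| local statistics for the observed labeling and each
# permutation. Returns list(obs = numeric vector, perm = genes x B matrix).
local_stat_matrix <- function(data, cfg) {
  values <- data$values
  if (data$data_type == "rnaseq") values <- log2_cpm(values)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  if (cfg$paired) {
    diffs <- paired_diffs(values, data$groups, data$blocks)
    nb <- ncol(diffs)
    signs <- if (cfg$exhaustive) {
      S <- as.matrix(expand.grid(rep(list(c(1, -1)), nb)))
      t(S)                                     # blocks x 2^nb
    } else {
      matrix(sample(c(1, -1), nb * cfg$n_perm, replace = TRUE), nrow = nb)
    }
    obs <- abs(one_sample_t(diffs)$stat)
    m <- (diffs %*% signs) / nb
    ssq <- rowSums(diffs^2)                     # sign-flip invariant
    v <- (ssq - nb * m^2) / (nb - 1)
    v[v < 0] <- 0
    se <- sqrt(v / nb)
    stat <- abs(m / se)
    stat[se == 0 & m == 0] <- 0
    stat[se == 0 & abs(m) > 0] <- Inf
    list(obs = unname(obs), perm = stat)
  } else {
    obs <- abs(drop(row_t_stats(values, matrix(data$groups, ncol = 1))$stat))
    L <- permutation_labels(data$groups, cfg)
    list(obs = unname(obs), perm = abs(row_t_stats(values, L)$stat))
  }
}

#' Permutation p-value
#'
#' For `B` randomly sampled permutation statistics the p-value is
#' `(b + 1)/(B + 1)` with `b` the number of permuted values at least as
#' large as the observed one -- strictly positive by construction. With
#' `exhaustive = TRUE` the vector is taken to be the complete enumeration
#' of relabelings (including the observed one) and the exact count `b/B`
#' is returned.
#'
#' @param observed Observed statistic.
#' @param permuted Non-empty numeric vector of permutation statistics.
#' @param exhaustive Whether `permuted` enumerates all relabelings.
#' @return A p-value in (0, 1].
#' @export
permutation_pvalue <- function(observed, permuted, exhaustive = FALSE) {
  if (!length(permuted)) stop("no permutation values", call. = FALSE)
  b <- sum(permuted >= observed)
  if (exhaustive) b / length(permuted) else (b + 1) / (length(permuted) + 1)
}

# Restrict sets to genes present in `universe`; drop empty sets silently
# (counted), apply size window with a message when it bites.
filter_sets <- function(gsc, universe, gs_min_size, gs_max_size) {
  idx <- lapply(gsc, function(g) which(universe %in% g))
  sizes <- lengths(idx)
  empty <- sizes == 0L
  if (any(empty)) {
    message(sum(empty), " set(s) without measured genes dropped")
  }
  small <- !empty & sizes < gs_min_size
  large <- sizes > gs_max_size
  if (any(small) || any(large)) {
    message(sum(small) + sum(large), " set(s) outside size window [",
            gs_min_size, ", ", gs_max_size, "] dropped")
  }
  idx[!empty & !small & !large]
}

# Shared ranking assembly: sort by p ascending, ties by score descending,
# then set id; BH adjustment across sets.
new_enrichment_ranking <- function(set_id, size, score, pval, method_name,
                                   extra = NULL) {
  out <- tibble::tibble(set_id = unname(set_id), size = as.integer(size),
                        score = unname(score), pval = unname(pval),
                        adj_pval = adjust_pvalues(unname(pval), "BH"))
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  out <- out[order(out$pval, -out$score, out$set_id), ]
  class(out) <- c("enrichment_ranking", class(out))
  attr(out, "method_name") <- method_name
  out
}

#' @export
print.enrichment_ranking <- function(x, ...) {
  cat(sprintf("<enrichment_ranking> method '%s', %d sets\n",
              attr(x, "method_name"), nrow(x)))
  NextMethod()
}

#' Glance at an enrichment ranking
#'
#' @param x An `enrichment_ranking`.
#' @param alpha Significance level on the adjusted p-value.
#' @param ... Unused.
#' @return One-row tibble: `method`, `n_sets`, `n_significant`, `top_set`.
#' @exportS3Method generics::glance
glance.enrichment_ranking <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    method = attr(x, "method_name"),
    n_sets = nrow(x),
    n_significant = sum(x$adj_pval < alpha),
    top_set = if (nrow(x)) x$set_id[1L] else NA_character_
  )
}

# Upper hypergeometric tail P(X >= k) drawing n from N with K marked.
hyper_tail <- function(k, K, n, N) {
  pmin(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE), 1)
}

#' Overrepresentation analysis (hypergeometric test)
#'
#' Tests each gene set for overrepresentation of differentially expressed
#' genes. With universe size `N` (genes in `de`), `K` significant genes,
#' `n` measured set members and `k` significant members, the p-value is the
#' upper hypergeometric tail `P(X >= k)`; the score is `k`.
#'
#' @param de A [de_statistics()] result defining the gene universe.
#' @param gsc A [gene_set_collection()].
#' @param alpha Per-gene significance level (default 0.05) applied to the
#'   adjusted p-value, or the raw p-value when `use_adjusted = FALSE`.
#' @param use_adjusted Threshold adjusted (default) or raw p-values.
#' @param gs_min_size,gs_max_size Size window on measured set members.
#' @return An `enrichment_ranking` tibble.
#' @export
ora <- function(de, gsc, alpha = 0.05, use_adjusted = TRUE,
                gs_min_size = 5, gs_max_size = 500) {
  stopifnot(alpha > 0, alpha < 1)
  universe <- de$gene_id
  p <- if (use_adjusted) de$adj_pval else de$pval
  sig <- p < alpha
  K <- sum(sig)
  if (K == 0L) {
    warning("no significant genes at alpha = ", alpha,
            "; all ORA p-values are 1")
  }
  idx <- filter_sets(gsc, universe, gs_min_size, gs_max_size)
  if (!length(idx)) stop("no gene set left after filtering", call. = FALSE)
  N <- length(universe)
  n <- lengths(idx)
  k <- vapply(idx, function(i) sum(sig[i]), integer(1))
  new_enrichment_ranking(names(idx), n, as.numeric(k),
                         hyper_tail(k, K, n, N), "ora")
}

#' GSEA running-sum enrichment score
#'
#' Walks down a ranked gene list; member genes ("hits") increment the
#' running sum by their weight `|stat|^weight_exp` (normalized so the hit
#' increments total 1), non-members decrement it by `1/(N - N_hit)`. The
#' enrichment score is the signed maximum deviation from zero (ties between
#' the positive and negative extreme resolve to the positive one).
#' `weight_exp = 0` gives the classic Kolmogorov-Smirnov form.
#'
#' @param ranked_stats Numeric vector of per-gene statistics sorted in
#'   decreasing order.
#' @param member_mask Logical vector marking set members, same length.
#' @param weight_exp Non-negative hit-weight exponent (0 = unweighted).
#' @return The enrichment score, in \[-1, 1\].
#' @export
gsea_enrichment_score <- function(ranked_stats, member_mask, weight_exp = 1) {
  if (length(ranked_stats) != length(member_mask)) {
    stop("ranked_stats and member_mask lengths differ", call. = FALSE)
  }
  if (weight_exp < 0) stop("weight_exp must be >= 0", call. = FALSE)
  n_hit <- sum(member_mask)
  if (n_hit == 0L || n_hit == length(member_mask)) {
    stop("enrichment score undefined for empty or full membership",
         call. = FALSE)
  }
  w <- abs(ranked_stats)^weight_exp
  inc <- numeric(length(ranked_stats))
  inc[member_mask] <- w[member_mask] / sum(w[member_mask])
  inc[!member_mask] <- -1 / (length(member_mask) - n_hit)
  running <- cumsum(inc)
  hi <- max(running)
  lo <- min(running)
  if (hi >= -lo) hi else lo
}

# Fast per-set ES from member positions within one ranking.
# pos: sorted positions of members; w: weights at those positions (already
# |stat|^q); N total genes. Matches gsea_enrichment_score.
es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  cw <- cumsum(w / sum(w))
  miss <- (pos - seq_len(k)) / (N - k)
  after <- cw - miss
  before <- c(0, cw[-k]) - miss
  hi <- max(after)
  lo <- min(before, 0)
  if (hi >= -lo) hi else lo
}

# Global statistics over per-gene local stats for a list of member-index sets.
# stat_col: numeric vector of local stats (one permutation or observed).
global_stats <- function(stat_col, idx, global_stat, weight_exp) {
  switch(global_stat,
    sum_sq = vapply(idx, function(i) sum(stat_col[i]^2), numeric(1)),
    wilcoxon = {
      r <- rank(stat_col)                      # mid-ranks for ties
      vapply(idx, function(i) sum(r[i]), numeric(1))
    },
    ks = {
      ord <- order(stat_col, decreasing = TRUE)
      pos_of <- integer(length(stat_col))
      pos_of[ord] <- seq_along(ord)
      N <- length(stat_col)
      w_all <- abs(stat_col)^weight_exp
      vapply(idx, function(i) {
        p <- sort(pos_of[i])
        es_from_positions(p, w_all[ord][p], N)
      }, numeric(1))
    },
    stop("unknown global statistic: ", global_stat, call. = FALSE)
  )
}

#' SAFE-style permutation enrichment analysis
#'
#' The shared engine behind the permutation-based set methods: per-gene
#' local statistics (`|t|`, pooled or paired) are recomputed for the
#' observed sample labels and for each label permutation; a per-set global
#' statistic is compared against its permutation null. Global statistics:
#' \describe{
#'   \item{`wilcoxon`}{rank-sum of member local statistics among all genes
#'     (mid-ranks for ties) -- the SAFE default, one-sided towards members
#'     having larger statistics.}
#'   \item{`ks`}{the [gsea_enrichment_score()] on genes ranked by local
#'     statistic (`weight_exp = 0` here gives the classic KS form; the
#'     `"gsea"` wrapper uses `weight_exp = 1`).}
#'   \item{`sum_sq`}{sum of squared member statistics (the SAMGS-type
#'     score; Hotelling's T-squared under a diagonal covariance).}
#' }
#'
#' Before ranking, per-gene statistics are ordered stably by gene id so
#' results do not depend on input row order.
#'
#' @param data An [expression_dataset()], at least two samples per group.
#' @param gsc A [gene_set_collection()].
#' @param global_stat `"wilcoxon"`, `"ks"` or `"sum_sq"`.
#' @param cfg A [permutation_config()].
#' @param weight_exp Hit-weight exponent for `global_stat = "ks"`.
#' @param gs_min_size,gs_max_size Size window on measured set members.
#' @param method_name Label recorded on the ranking.
#' @return An `enrichment_ranking` tibble.
#' @export
safe_run <- function(data, gsc, global_stat = c("wilcoxon", "ks", "sum_sq"),
                     cfg = permutation_config(), weight_exp = 0,
                     gs_min_size = 5, gs_max_size = 500,
                     method_name = NULL) {
  global_stat <- match.arg(global_stat)
  stopifnot(inherits(data, "expression_dataset"))
  if (sum(data$groups == 0L) < 2L || sum(data$groups == 1L) < 2L) {
    stop("need at least two samples per group", call. = FALSE)
  }
  if (is.null(method_name)) method_name <- paste0("safe_", global_stat)

  ord <- order(data$gene_ids)                  # stable gene order
  data_sorted <- data
  data_sorted$values <- data$values[ord, , drop = FALSE]
  data_sorted$gene_ids <- data$gene_ids[ord]

  idx <- filter_sets(gsc, data_sorted$gene_ids, gs_min_size, gs_max_size)
  if (!length(idx)) stop("no gene set left after filtering", call. = FALSE)

  ls <- local_stat_matrix(data_sorted, cfg)
  obs <- global_stats(ls$obs, idx, global_stat, weight_exp)
  B <- ncol(ls$perm)
  perm <- matrix(NA_real_, nrow = length(idx), ncol = B)
  for (b in seq_len(B)) {
    perm[, b] <- global_stats(ls$perm[, b], idx, global_stat, weight_exp)
  }
  pval <- vapply(seq_along(idx), function(s) {
    permutation_pvalue(obs[s], perm[s, ], exhaustive = cfg$exhaustive)
  }, numeric(1))
  new_enrichment_ranking(names(idx), lengths(idx), obs, pval, method_name)
}

#' Run a set-based enrichment method by name
#'
#' Dispatch wrapper over the native set-based methods:
#' `"ora"` ([ora()]), `"gsea"` ([safe_run()] with the weighted running-sum
#' statistic, `weight_exp = 1`), `"safe"` (Wilcoxon rank-sum) and `"samgs"`
#' (sum of squared statistics).
#'
#' @param data An [expression_dataset()].
#' @param gsc A [gene_set_collection()].
#' @param method One of `"ora"`, `"gsea"`, `"safe"`, `"samgs"`.
#' @param de Optional precomputed [de_statistics()] result (needed for
#'   `"ora"`; computed on the fly when absent).
#' @param alpha Per-gene significance level for `"ora"`.
#' @param cfg A [permutation_config()] for the permutation methods.
#' @param weight_exp Hit-weight exponent for `"gsea"` (default 1; 0 gives
#'   the classic KS statistic).
#' @param ... Passed on to the underlying method (e.g. `gs_min_size`).
#' @return An `enrichment_ranking` tibble.
#' @export
sbea <- function(data, gsc, method = c("ora", "gsea", "safe", "samgs"),
                 de = NULL, alpha = 0.05, cfg = permutation_config(),
                 weight_exp = 1, ...) {
  method <- match.arg(method)
  switch(method,
    ora = {
      if (is.null(de)) de <- de_statistics(data)
      ora(de, gsc, alpha = alpha, ...)
    },
    gsea = safe_run(data, gsc, global_stat = "ks", cfg = cfg,
                    weight_exp = weight_exp, method_name = "gsea", ...),
    safe = safe_run(data, gsc, global_stat = "wilcoxon", cfg = cfg,
                    method_name = "safe", ...),
    samgs = safe_run(data, gsc, global_stat = "sum_sq", cfg = cfg,
                     method_name = "samgs", ...)
  )
}

#' Write an enrichment ranking as TSV
#'
#' Columns: `set_id`, `size`, `score`, `pval`, `adj_pval`.
#'
#' @param ranking An `enrichment_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  readr::write_tsv(as.data.frame(ranking), path)
  invisible(path)
}
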