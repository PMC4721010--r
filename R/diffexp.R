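# Per-gene differential expression between two sample groups.
# Microarray data are assumed log2; RNA-seq counts go through log2(CPM + 0.5)
# and the same t machinery.

log2_cpm <- function(counts) {
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("sample with zero total counts", call. = FALSE)
  log2(sweep(counts, 2, libsize, "/") * 1e6 + 0.5)
}

# Pooled-variance two-sample t per row of a matrix; vectorized over a set of
# 0/1 label assignments given as columns of `labels` (samples x B).
# Returns list of matrices (genes x B): lfc, stat.
row_t_stats <- function(values, labels) {
  labels <- as.matrix(labels)
  n1 <- colSums(labels)          # cases per relabeling
  n0 <- nrow(labels) - n1
  s1 <- values %*% labels        # per-gene case sums
  s0 <- values %*% (1 - labels)
  sq <- values^2
  q1 <- sq %*% labels
  q0 <- sq %*% (1 - labels)
  m1 <- sweep(s1, 2, n1, "/")
  m0 <- sweep(s0, 2, n0, "/")
  lfc <- m1 - m0
  ss1 <- q1 - sweep(s1^2, 2, n1, "/")
  ss0 <- q0 - sweep(s0^2, 2, n0, "/")
  df <- n0 + n1 - 2
  pooled <- sweep(ss1 + ss0, 2, df, "/")
  pooled[pooled < 0] <- 0        # numerical guard
  se <- sqrt(sweep(pooled, 2, 1 / n1 + 1 / n0, "*"))
  stat <- lfc / se
  zero <- se == 0
  if (any(zero)) {
    stat[zero & lfc == 0] <- 0
    stat[zero & lfc > 0] <- Inf
    stat[zero & lfc < 0] <- -Inf
  }
  list(lfc = lfc, stat = stat, df = df)
}

# Paired t on within-block case-minus-control differences; labels fixed to
# the observed design, permutations handled by sign flips upstream.
paired_diffs <- function(values, groups, blocks) {
  if (is.null(blocks)) {
    stop("paired_t requires a block column", call. = FALSE)
  }
  split_idx <- split(seq_along(groups), blocks)
  ok <- vapply(split_idx, function(i) {
    length(i) == 2L && sum(groups[i]) == 1L
  }, logical(1))
  if (!all(ok)) {
    stop("paired_t requires each block = one case + one control",
         call. = FALSE)
  }
  case <- vapply(split_idx, function(i) i[groups[i] == 1L], integer(1))
  ctrl <- vapply(split_idx, function(i) i[groups[i] == 0L], integer(1))
  values[, case, drop = FALSE] - values[, ctrl, drop = FALSE]
}

one_sample_t <- function(diffs) {
  n <- ncol(diffs)
  m <- rowMeans(diffs)
  v <- rowSums((diffs - m)^2) / (n - 1)
  se <- sqrt(v / n)
  stat <- m / se
  zero <- se == 0
  stat[zero & m == 0] <- 0
  stat[zero & m > 0] <- Inf
  stat[zero & m < 0] <- -Inf
  list(lfc = m, stat = stat, df = n - 1)
}

t_pvalue <- function(stat, df, lfc) {
  p <- 2 * stats::pt(-abs(stat), df = df)
  inf <- is.infinite(stat)
  if (any(inf)) p[inf] <- .Machine$double.xmin
  degen <- stat == 0 & lfc == 0
  p[degen] <- 1
  pmin(p, 1)
}

#' Per-gene differential expression statistics
#'
#' Computes, for every gene, the log2 fold change (case minus control), a
#' pooled-variance two-sample t statistic (or a paired t on within-block
#' differences), the two-sided p-value and a multiplicity-adjusted p-value.
#' RNA-seq counts are transformed to log2(CPM + 0.5) first, so fold changes
#' are on the log2 scale for both data types.
#'
#' Genes with zero pooled variance get `stat = 0, pval = 1` when the fold
#' change is zero, and `stat = +/-Inf` with the smallest representable
#' positive p-value otherwise (a warning is emitted).
#'
#' @param data An [expression_dataset()] with at least two samples per group.
#' @param method `"pooled_t"` (default) or `"paired_t"` (requires blocks
#'   forming a perfect 1:1 pairing).
#' @param adjust Multiple-testing correction passed to [adjust_pvalues()];
#'   default `"BH"`.
#'
#' @return A tibble of class `de_result` with columns `gene_id`, `log2fc`,
#'   `stat`, `pval`, `adj_pval`, in input gene order; attributes `method`,
#'   `adjust`, `df`.
#' @export
de_statistics <- function(data, method = c("pooled_t", "paired_t"),
                          adjust = "BH") {
  method <- match.arg(method)
  stopifnot(inherits(data, "expression_dataset"))
  if (sum(data$groups == 0L) < 2L || sum(data$groups == 1L) < 2L) {
    stop("need at least two samples per group", call. = FALSE)
  }
  values <- data$values
  if (data$data_type == "rnaseq") values <- log2_cpm(values)

  if (method == "pooled_t") {
    res <- row_t_stats(values, matrix(data$groups, ncol = 1))
    lfc <- drop(res$lfc); stat <- drop(res$stat); df <- res$df
  } else {
    diffs <- paired_diffs(values, data$groups, data$blocks)
    res <- one_sample_t(diffs)
    lfc <- res$lfc; stat <- res$stat; df <- res$df
  }
  if (any(is.infinite(stat))) {
    warning(sum(is.infinite(stat)),
            " gene(s) with zero variance but non-zero fold change")
  }
  pval <- t_pvalue(stat, df, lfc)
  out <- tibble::tibble(
    gene_id = data$gene_ids,
    log2fc = unname(lfc),
    stat = unname(stat),
    pval = unname(pval),
    adj_pval = adjust_pvalues(unname(pval), adjust)
  )
  class(out) <- c("de_result", class(out))
  attr(out, "method") <- method
  attr(out, "adjust") <- adjust
  attr(out, "df") <- df
  out
}

#' Multiple-testing correction
#'
#' Thin validated wrapper over the standard step procedures: `"none"`,
#' `"bonferroni"`, `"holm"`, `"BH"` (Benjamini-Hochberg), `"BY"`
#' (Benjamini-Yekutieli). Output order matches input order and every
#' correction dominates the raw p-values.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param method Correction name.
#' @return Adjusted p-values, same length and order as `pvals`.
#' @export
adjust_pvalues <- function(pvals,
                           method = c("BH", "none", "bonferroni", "holm",
                                      "BY")) {
  method <- match.arg(method)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (method == "none") return(pvals)
  stats::p.adjust(pvals, method = method)
}

#' Summarize probe-level rows to gene level
#'
#' For genes measured by several probes either the per-sample arithmetic
#' mean is taken (`mode = "mean"`) or the single probe that discriminates
#' the two groups the most -- largest absolute two-sample t statistic -- is
#' kept verbatim (`mode = "best"`). Probes without a mapping are dropped
#' with a message.
#'
#' @param data An [expression_dataset()] whose rows are probes.
#' @param probe2gene Named character vector mapping probe id -> gene id.
#' @param mode `"mean"` or `"best"`.
#' @return An [expression_dataset()] with one row per gene.
#' @export
summarize_probes <- function(data, probe2gene, mode = c("mean", "best")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "expression_dataset"))
  if (!length(probe2gene)) stop("empty probe-to-gene mapping", call. = FALSE)
  mapped <- data$gene_ids %in% names(probe2gene)
  if (!all(mapped)) {
    message(sum(!mapped), " unmapped probe(s) dropped")
  }
  if (!any(mapped)) stop("no probe maps to a gene", call. = FALSE)
  values <- data$values[mapped, , drop = FALSE]
  genes <- unname(probe2gene[data$gene_ids[mapped]])

  if (mode == "mean") {
    counts <- as.vector(table(genes)[unique(genes)])
    summed <- rowsum(values, group = genes, reorder = FALSE)
    out <- summed / counts
  } else {
    stat <- abs(drop(row_t_stats(values, matrix(data$groups, ncol = 1))$stat))
    # stable: first probe wins ties within a gene
    ord <- order(factor(genes, levels = unique(genes)), -stat)
    keep <- ord[!duplicated(genes[ord])]
    keep <- keep[order(match(genes[keep], unique(genes)))]
    out <- values[keep, , drop = FALSE]
    rownames(out) <- genes[keep]
  }
  rownames(out) <- unique(genes)
  expression_dataset(out, groups = data$groups, blocks = data$blocks,
                     data_type = data$data_type)
}

#' Between-sample quantile normalization
#'
#' Optional preprocessing step (off by default in the workflow): forces all
#' sample distributions to their common quantile profile, via
#' `limma::normalizeQuantiles`.
#'
#' @param data An [expression_dataset()].
#' @return A quantile-normalized [expression_dataset()].
#' @export
normalize_between_samples <- function(data) {
  stopifnot(inherits(data, "expression_dataset"))
  if (!requireNamespace("limma", quietly = TRUE)) {
    stop("quantile normalization requires the 'limma' package",
         call. = FALSE)
  }
  values <- data$values
  if (data$data_type == "rnaseq") values <- log2_cpm(values)
  norm <- limma::normalizeQuantiles(values)
  dimnames(norm) <- dimnames(data$values)
  expression_dataset(norm, groups = data$groups, blocks = data$blocks,
                     data_type = "microarray")
}

#' Glance at a differential expression result
#'
#' @param x A `de_result`.
#' @param alpha Significance level for counting significant genes.
#' @param ... Unused.
#' @return One-row tibble: `n_genes`, `n_significant`, `method`, `adjust`.
#' @importFrom generics glance
#' @exportS3Method generics::glance
glance.de_result <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_significant = sum(x$adj_pval < alpha),
    method = attr(x, "method"),
    adjust = attr(x, "adjust")
  )
}

#' Write a differential expression result as TSV
#'
#' @param de A `de_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de <- function(de, path) {
  readr::write_tsv(as.data.frame(de), path)
  invisible(path)
}
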