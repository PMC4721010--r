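# Ranking and combination across enrichment methods: absolute, relative and
# competitive ranks of per-set statistics, aggregated by sum (default),
# mean, median or min.

#' Assign ranks to a statistic vector
#'
#' Three rank types over a per-set ranking statistic (a p-value sorted
#' ascending, or a score sorted descending):
#' \describe{
#'   \item{absolute}{dense ranks `1..N_D` over the distinct values, where
#'     `N_D` is the number of distinct values; tied sets share a rank.}
#'   \item{relative}{`absolute / N_D * 100`, in (0, 100].}
#'   \item{competitive}{the percentage of sets whose statistic is at least
#'     as extreme as the ranked set's, inclusive of the set itself (so the
#'     minimum competitive rank for a `t`-way tie at the top is
#'     `100 * t / N_GS`).}
#' }
#'
#' @param stats Non-empty numeric vector, no NA/NaN.
#' @param order `"ascending"` (smaller is more extreme, e.g. p-values) or
#'   `"descending"` (larger is more extreme, e.g. scores).
#' @param rank_type `"absolute"`, `"relative"` or `"competitive"`.
#' @return A tibble with columns `statistic` and `rank` (input order
#'   preserved), with attributes `rank_type`, `n_distinct`, `n_sets`.
#' @export
assign_ranks <- function(stats, order = c("ascending", "descending"),
                         rank_type = c("absolute", "relative",
                                       "competitive")) {
  order <- match.arg(order)
  rank_type <- match.arg(rank_type)
  if (!length(stats)) stop("empty statistic vector", call. = FALSE)
  if (anyNA(stats) || any(is.nan(stats))) {
    stop("NA/NaN in ranking statistic", call. = FALSE)
  }
  uq <- sort(unique(stats), decreasing = (order == "descending"))
  n_distinct <- length(uq)
  n_sets <- length(stats)
  absolute <- match(stats, uq)
  ranks <- switch(rank_type,
    absolute = absolute,
    relative = absolute / n_distinct * 100,
    competitive = {
      at_least <- if (order == "ascending") {
        vapply(stats, function(s) sum(stats <= s), numeric(1))
      } else {
        vapply(stats, function(s) sum(stats >= s), numeric(1))
      }
      100 * at_least / n_sets
    }
  )
  out <- tibble::tibble(statistic = stats, rank = as.numeric(ranks))
  attr(out, "rank_type") <- rank_type
  attr(out, "n_distinct") <- n_distinct
  attr(out, "n_sets") <- n_sets
  out
}

ranking_method_name <- function(rankings) {
  nm <- names(rankings)
  auto <- vapply(rankings, function(r) {
    m <- attr(r, "method_name")
    if (is.null(m)) NA_character_ else m
  }, character(1))
  if (is.null(nm)) nm <- auto
  nm[is.na(nm) | !nzchar(nm)] <- auto[is.na(nm) | !nzchar(nm)]
  if (anyNA(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("rankings must carry unique method names", call. = FALSE)
  }
  nm
}

#' Combine gene set rankings across methods
#'
#' Per method, ranks of the chosen statistic are computed over that
#' method's full ranking with [assign_ranks()]; the combination function
#' then aggregates each set's ranks across methods and the sets are
#' re-ordered by the combined value (ascending; ties broken by the best
#' single-method rank, then set id). The default -- competitive ranks of
#' the gene set p-values combined by sum -- rewards sets supported by
#' several methods and is robust to methods with many tied p-values.
#'
#' With `support = "intersection"` (default) only sets present in every
#' ranking are retained. With `support = "union"` a set missing from a
#' method contributes that method's worst possible rank (100 for
#' relative/competitive ranks, the method's `N_D` for absolute ranks).
#'
#' @param rankings Named list of `enrichment_ranking` tibbles (names
#'   default to each ranking's method name).
#' @param rank_type `"competitive"` (default), `"absolute"` or
#'   `"relative"`.
#' @param statistic Rank by `"pval"` (ascending, default) or `"score"`
#'   (descending).
#' @param combine_fn `"sum"` (default), `"mean"`, `"median"`, `"min"`, or
#'   a user-supplied function mapping a numeric vector of per-method ranks
#'   to one number.
#' @param support `"intersection"` or `"union"`.
#' @return A tibble of class `combined_ranking`: `set_id`, one
#'   `rank_<method>` column per method, `combined`, `rank`; attributes
#'   `methods`, `rank_type`, `statistic`, `combine_fn`, `support`.
#' @export
combine_rankings <- function(rankings,
                             rank_type = c("competitive", "absolute",
                                           "relative"),
                             statistic = c("pval", "score"),
                             combine_fn = c("sum", "mean", "median", "min"),
                             support = c("intersection", "union")) {
  rank_type <- match.arg(rank_type)
  statistic <- match.arg(statistic)
  support <- match.arg(support)
  if (is.character(combine_fn)) {
    combine_fn_name <- match.arg(combine_fn)
    fn <- switch(combine_fn_name, sum = sum, mean = mean,
                 median = stats::median, min = min)
  } else {
    stopifnot(is.function(combine_fn))
    fn <- combine_fn
    combine_fn_name <- "user"
  }
  if (!length(rankings)) stop("need at least one ranking", call. = FALSE)
  methods <- ranking_method_name(rankings)
  order_dir <- if (statistic == "pval") "ascending" else "descending"

  per_method <- purrr::map2(rankings, methods, function(r, m) {
    ra <- assign_ranks(r[[statistic]], order = order_dir,
                       rank_type = rank_type)
    tibble::tibble(set_id = r$set_id, rank = ra$rank,
                   penalty = if (rank_type == "absolute")
                     attr(ra, "n_distinct") else 100)
  })

  ids <- purrr::map(per_method, "set_id")
  sets <- if (support == "intersection") {
    common <- purrr::reduce(ids, intersect)
    if (!length(common)) {
      stop("empty intersection of rankings; use support = \"union\"",
           call. = FALSE)
    }
    common
  } else {
    unique(unlist(ids))
  }

  rank_mat <- vapply(per_method, function(pm) {
    r <- pm$rank[match(sets, pm$set_id)]
    miss <- is.na(r)
    if (any(miss)) {
      message(sum(miss), " set(s) missing from a ranking given the ",
              "worst-rank penalty")
      r[miss] <- pm$penalty[1L]
    }
    r
  }, numeric(length(sets)))
  rank_mat <- matrix(rank_mat, nrow = length(sets),
                     dimnames = list(NULL, methods))

  combined <- apply(rank_mat, 1, fn)
  best <- apply(rank_mat, 1, min)
  ord <- order(combined, best, sets)
  out <- tibble::as_tibble(as.data.frame(rank_mat)[ord, , drop = FALSE])
  names(out) <- paste0("rank_", methods)
  out <- dplyr::bind_cols(tibble::tibble(set_id = sets[ord]), out)
  out$combined <- combined[ord]
  out$rank <- seq_along(ord)
  class(out) <- c("combined_ranking", class(out))
  attr(out, "methods") <- methods
  attr(out, "rank_type") <- rank_type
  attr(out, "statistic") <- statistic
  attr(out, "combine_fn") <- combine_fn_name
  attr(out, "support") <- support
  out
}

#' @export
print.combined_ranking <- function(x, ...) {
  cat(sprintf("<combined_ranking> %s of %s %s ranks over {%s}, %d sets\n",
              attr(x, "combine_fn"), attr(x, "rank_type"),
              attr(x, "statistic"),
              paste(attr(x, "methods"), collapse = ", "), nrow(x)))
  NextMethod()
}

#' Glance at a combined ranking
#'
#' @param x A `combined_ranking`.
#' @param ... Unused.
#' @return One-row tibble summarizing the combination settings and winner.
#' @exportS3Method generics::glance
glance.combined_ranking <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x),
    n_methods = length(attr(x, "methods")),
    rank_type = attr(x, "rank_type"),
    combine_fn = attr(x, "combine_fn"),
    support = attr(x, "support"),
    top_set = if (nrow(x)) x$set_id[1L] else NA_character_
  )
}

#' Write a combined ranking as TSV
#'
#' @param combined A `combined_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_combined <- function(combined, path) {
  readr::write_tsv(as.data.frame(combined), path)
  invisible(path)
}
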