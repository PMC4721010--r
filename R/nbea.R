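# Network-based enrichment: consistency of signed regulatory interactions
# with observed expression changes (GGEA-style), plus the generic plug-in
# contract that lets external enrichment methods flow through the same
# ranking, combination and report machinery.

#' Consistency of a regulatory edge with observed fold changes
#'
#' Each gene's de-regulation is squashed to \[-1, 1\] by `tanh(log2fc)`;
#' an activation edge is consistent when regulator and target move in the
#' same direction (`tanh(fc_reg) * tanh(fc_tgt)`), an inhibition edge when
#' they move oppositely (the product negated). +1 means both genes are
#' maximally de-regulated exactly as the interaction predicts, -1 maximal
#' contradiction. Flipping an edge's effect negates its consistency.
#'
#' @param de A [de_statistics()] result (or any tibble with `gene_id`,
#'   `log2fc`).
#' @param grn A [regulatory_network()]. Edges with an unmeasured endpoint
#'   are dropped.
#' @return A tibble with columns `regulator`, `target`, `effect`,
#'   `consistency`.
#' @export
edge_consistency <- function(de, grn) {
  lfc <- stats::setNames(de$log2fc, de$gene_id)
  keep <- grn$regulator %in% names(lfc) & grn$target %in% names(lfc)
  edges <- grn[keep, , drop = FALSE]
  sign <- ifelse(edges$effect == "activation", 1, -1)
  cons <- sign * tanh(lfc[edges$regulator]) * tanh(lfc[edges$target])
  tibble::tibble(
    regulator = edges$regulator,
    target = edges$target,
    effect = edges$effect,
    consistency = unname(cons)
  )
}

# Edges induced by a set: "adjacent" keeps edges with >= 1 endpoint in the
# set (regulators outside the set still contribute mechanism), "within"
# requires both. Both endpoints must be measured.
induced_edges <- function(grn, members, measured, edges = "adjacent") {
  ok <- grn$regulator %in% measured & grn$target %in% measured
  touch <- if (edges == "within") {
    grn$regulator %in% members & grn$target %in% members
  } else {
    grn$regulator %in% members | grn$target %in% members
  }
  which(ok & touch)
}

#' Gene graph enrichment analysis (regulatory-consistency scoring)
#'
#' Scores each gene set by how consistently the regulatory interactions it
#' touches are reflected in the observed expression changes. Per set the
#' raw score is the sum of [edge_consistency()] values over its induced
#' edges; the normalized score divides by the number of induced edges (so
#' it lies in \[-1, 1\]). Significance comes from sample-label permutation
#' of the raw score: fold changes are recomputed for every relabeling.
#' Sets without induced edges get score 0, p-value 1 and are flagged.
#'
#' @param data An [expression_dataset()].
#' @param gsc A [gene_set_collection()].
#' @param grn A non-empty [regulatory_network()].
#' @param cfg A [permutation_config()].
#' @param edges `"adjacent"` (default; >= 1 endpoint in the set) or
#'   `"within"` (both endpoints).
#' @param gs_min_size,gs_max_size Size window on measured set members.
#' @return An `enrichment_ranking` tibble with extra columns
#'   `norm_score` (score / number of induced edges), `n_edges` and
#'   `no_edges` flag.
#' @export
ggea <- function(data, gsc, grn, cfg = permutation_config(),
                 edges = c("adjacent", "within"),
                 gs_min_size = 5, gs_max_size = 500) {
  edges <- match.arg(edges)
  stopifnot(inherits(data, "expression_dataset"))
  if (!nrow(grn)) stop("regulatory network is empty", call. = FALSE)

  ord <- order(data$gene_ids)
  values <- data$values[ord, , drop = FALSE]
  gene_ids <- data$gene_ids[ord]
  if (data$data_type == "rnaseq") values <- log2_cpm(values)

  idx <- filter_sets(gsc, gene_ids, gs_min_size, gs_max_size)
  if (!length(idx)) stop("no gene set left after filtering", call. = FALSE)

  # observed and permuted log2 fold changes
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  L <- if (cfg$exhaustive) exhaustive_labels(data$groups) else
    permutation_labels(data$groups, cfg)
  lfc_obs <- drop(row_t_stats(values, matrix(data$groups, ncol = 1))$lfc)
  T_obs <- tanh(lfc_obs)
  T_perm <- tanh(row_t_stats(values, L)$lfc)

  gene_pos <- stats::setNames(seq_along(gene_ids), gene_ids)
  measured <- gene_ids
  edge_sign <- ifelse(grn$effect == "activation", 1, -1)

  n_sets <- length(idx)
  score <- numeric(n_sets); n_edges <- integer(n_sets)
  pval <- numeric(n_sets); norm_score <- numeric(n_sets)
  for (s in seq_len(n_sets)) {
    members <- gene_ids[idx[[s]]]
    e <- induced_edges(grn, members, measured, edges)
    n_edges[s] <- length(e)
    if (!length(e)) {
      score[s] <- 0; norm_score[s] <- 0; pval[s] <- 1
      next
    }
    ri <- gene_pos[grn$regulator[e]]
    ti <- gene_pos[grn$target[e]]
    sg <- edge_sign[e]
    obs_s <- sum(sg * T_obs[ri] * T_obs[ti])
    perm_s <- colSums(sg * T_perm[ri, , drop = FALSE] *
                        T_perm[ti, , drop = FALSE])
    score[s] <- obs_s
    norm_score[s] <- obs_s / length(e)
    pval[s] <- permutation_pvalue(obs_s, perm_s, exhaustive = cfg$exhaustive)
  }
  new_enrichment_ranking(
    names(idx), lengths(idx), score, pval, "ggea",
    extra = tibble::tibble(norm_score = norm_score, n_edges = n_edges,
                           no_edges = n_edges == 0L)
  )
}

#' Per-set edge consistency table
#'
#' The edge-level view behind a set's network report page: every induced
#' regulatory edge of the set with its consistency value.
#'
#' @param de A [de_statistics()] result.
#' @param grn A [regulatory_network()].
#' @param members Character vector of the set's gene ids.
#' @param edges `"adjacent"` or `"within"` (see [ggea()]).
#' @return A tibble: `regulator`, `target`, `effect`, `consistency`.
#' @export
set_edge_table <- function(de, grn, members, edges = c("adjacent", "within")) {
  edges <- match.arg(edges)
  e <- induced_edges(grn, members, de$gene_id, edges)
  edge_consistency(de, grn[e, , drop = FALSE])
}

# ---- generic method plug-in registry ------------------------------------

plugin_registry <- new.env(parent = emptyenv())
RESERVED_PLUGINS <- c("spia", "nea", "pathnet")

#' Register an enrichment method plug-in
#'
#' A plug-in is a function with signature
#' `function(data, gsc, alpha, grn = NULL)` returning one p-value per gene
#' set in `gsc` (a numeric vector in \[0, 1\], in collection order). Once
#' registered, the method can be named anywhere a native method can: it is
#' run through [run_plugin()] and its ranking participates in combination
#' and reporting unchanged. The names `spia`, `nea` and `pathnet` are
#' reserved slots for the corresponding published methods and cannot be
#' bound to other callables under a different contract.
#'
#' @param name Method name (lower-case string).
#' @param fn The callable.
#' @param requires_network Whether a regulatory network must be supplied.
#' @return The plug-in record, invisibly.
#' @export
register_plugin <- function(name, fn, requires_network = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  rec <- list(name = name, fn = fn,
              requires_network = isTRUE(requires_network))
  assign(name, rec, envir = plugin_registry)
  invisible(rec)
}

#' List registered plug-ins
#' @return Character vector of plug-in names.
#' @export
list_plugins <- function() ls(plugin_registry)

get_plugin <- function(name) {
  if (!exists(name, envir = plugin_registry, inherits = FALSE)) {
    if (name %in% RESERVED_PLUGINS) {
      stop("method '", name, "' is a reserved plug-in slot; register an ",
           "implementation with register_plugin()", call. = FALSE)
    }
    stop("unknown method/plug-in: ", name, call. = FALSE)
  }
  get(name, envir = plugin_registry, inherits = FALSE)
}

#' Run a plugged-in enrichment method
#'
#' Validates the plug-in contract (vector length = number of gene sets,
#' values in \[0, 1\], network present when required) and wraps the
#' returned p-values into an `enrichment_ranking` with `score = -p`, so
#' combination and reporting work unchanged.
#'
#' @param plugin A plug-in record from [register_plugin()], or its name.
#' @param data An [expression_dataset()].
#' @param gsc A [gene_set_collection()].
#' @param alpha Significance level forwarded to the plug-in.
#' @param grn Optional [regulatory_network()].
#' @return An `enrichment_ranking` tibble.
#' @export
run_plugin <- function(plugin, data, gsc, alpha = 0.05, grn = NULL) {
  if (is.character(plugin)) plugin <- get_plugin(plugin)
  if (plugin$requires_network && is.null(grn)) {
    stop("plug-in '", plugin$name, "' requires a regulatory network",
         call. = FALSE)
  }
  p <- plugin$fn(data, gsc, alpha, grn)
  if (!is.numeric(p) || length(p) != length(gsc)) {
    stop("plug-in '", plugin$name, "' returned ", length(p),
         " value(s) for ", length(gsc), " gene set(s)", call. = FALSE)
  }
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("plug-in '", plugin$name, "' returned p-values outside [0, 1]",
         call. = FALSE)
  }
  sizes <- vapply(gsc, function(g) sum(g %in% data$gene_ids), integer(1))
  new_enrichment_ranking(names(gsc), sizes, score = -p, pval = p,
                         method_name = plugin$name)
}

#' Run a network-based enrichment method by name
#'
#' `"ggea"` dispatches to the native [ggea()]; any other name is looked up
#' in the plug-in registry.
#'
#' @param data An [expression_dataset()].
#' @param gsc A [gene_set_collection()].
#' @param grn A [regulatory_network()].
#' @param method Method name (default `"ggea"`).
#' @param cfg A [permutation_config()] (native methods).
#' @param alpha Significance level (plug-ins).
#' @param ... Passed to the underlying method.
#' @return An `enrichment_ranking` tibble.
#' @export
nbea <- function(data, gsc, grn, method = "ggea",
                 cfg = permutation_config(), alpha = 0.05, ...) {
  if (method == "ggea") {
    ggea(data, gsc, grn, cfg = cfg, ...)
  } else {
    run_plugin(method, data, gsc, alpha = alpha, grn = grn)
  }
}
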