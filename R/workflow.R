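# End-to-end orchestration: differential expression -> enrichment methods
# -> rank combination -> TSVs + HTML report, driven by a validated
# configuration. The command-line wrapper in inst/scripts/encore-cli.R is a
# thin shell over these functions.

NATIVE_SBEA <- c("ora", "gsea", "safe", "samgs")
NATIVE_NBEA <- c("ggea")

#' Build and validate a workflow configuration
#'
#' @param expression,groups,gene_sets,network Input file paths (network
#'   optional). Alternatively supply in-memory objects via `sim`.
#' @param sim Optional list with elements `data`, `gsc`, `grn` (e.g. from
#'   [simulate_study()]); overrides the file paths.
#' @param data_type `"microarray"` or `"rnaseq"`.
#' @param methods Character vector of enrichment methods to run; native
#'   names are `ora`, `gsea`, `safe`, `samgs`, `ggea`; anything else must
#'   be a registered plug-in.
#' @param de_method,adjust,alpha Differential expression options.
#' @param n_perm,paired Permutation options (seeded from `seed`).
#' @param rank_type,statistic,combine_fn,support Combination options (see
#'   [combine_rankings()]); combination runs when >= 2 methods are named.
#' @param report Render the HTML bundle.
#' @param outdir Output directory.
#' @param seed Integer seed propagated to every stochastic step.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(expression = NULL, groups = NULL, gene_sets = NULL,
                       network = NULL, sim = NULL,
                       data_type = "microarray",
                       methods = c("ora", "ggea"),
                       de_method = "pooled_t", adjust = "BH", alpha = 0.05,
                       n_perm = 1000, paired = FALSE,
                       rank_type = "competitive", statistic = "pval",
                       combine_fn = "sum", support = "intersection",
                       report = TRUE, outdir = "encore_out", seed = 1) {
  cfg <- list(expression = expression, groups = groups,
              gene_sets = gene_sets, network = network, sim = sim,
              data_type = match.arg(data_type,
                                    c("microarray", "rnaseq")),
              methods = methods, de_method = de_method, adjust = adjust,
              alpha = as.numeric(alpha), n_perm = as.integer(n_perm),
              paired = isTRUE(paired) || identical(paired, "TRUE"),
              rank_type = rank_type, statistic = statistic,
              combine_fn = combine_fn, support = support,
              report = isTRUE(report) || identical(report, "TRUE"),
              outdir = outdir, seed = as.integer(seed))
  known <- c(NATIVE_SBEA, NATIVE_NBEA, list_plugins())
  unknown <- setdiff(cfg$methods, known)
  if (length(unknown)) {
    stop("unregistered method(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  needs_net <- intersect(cfg$methods, NATIVE_NBEA)
  for (m in setdiff(cfg$methods, c(NATIVE_SBEA, NATIVE_NBEA))) {
    if (get_plugin(m)$requires_network) needs_net <- c(needs_net, m)
  }
  has_net <- !is.null(cfg$network) ||
    (!is.null(sim) && !is.null(sim$grn) && nrow(sim$grn) > 0)
  if (length(needs_net) && !has_net) {
    stop("method(s) ", paste(needs_net, collapse = ", "),
         " need a regulatory network", call. = FALSE)
  }
  if (is.null(sim)) {
    for (p in c(cfg$expression, cfg$groups, cfg$gene_sets, cfg$network)) {
      if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Parse a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key<TAB>value`); `#` comments and
#' blank lines are skipped; `methods` may be a comma-separated list.
#' Values given in `...` override the file.
#'
#' @param path Config file path.
#' @param ... Overrides forwarded to [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*[=\t]\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("config line not of the form key = value: ", lines[bad][1L],
         call. = FALSE)
  }
  vals <- stats::setNames(lapply(kv, `[[`, 2L),
                          vapply(kv, `[[`, character(1), 1L))
  if (!is.null(vals$methods)) {
    vals$methods <- strsplit(vals$methods, ",")[[1L]]
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' Run the full enrichment workflow
#'
#' Executes, in order: input loading (or the supplied simulation),
#' differential expression, every configured enrichment method, rank
#' combination (when two or more methods ran) and, optionally, the HTML
#' report. All rankings and the DE table are written as TSV under
#' `cfg$outdir`.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list: `de`, `rankings`, `combined`, `outdir`.
#' @export
run_workflow <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(cfg$sim)) {
    data <- cfg$sim$data; gsc <- cfg$sim$gsc; grn <- cfg$sim$grn
  } else {
    data <- read_expression(cfg$expression, cfg$groups,
                            data_type = cfg$data_type)
    gsc <- read_gmt(cfg$gene_sets)
    grn <- if (!is.null(cfg$network)) read_network(cfg$network) else NULL
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  de <- de_statistics(data, method = cfg$de_method, adjust = cfg$adjust)
  write_de(de, file.path(cfg$outdir, "de.tsv"))

  rankings <- list()
  for (i in seq_along(cfg$methods)) {
    m <- cfg$methods[i]
    pcfg <- permutation_config(n_perm = cfg$n_perm,
                               seed = cfg$seed + i,  # independent nulls
                               paired = cfg$paired)
    r <- if (m %in% NATIVE_SBEA) {
      sbea(data, gsc, method = m, de = de, alpha = cfg$alpha, cfg = pcfg)
    } else if (m %in% NATIVE_NBEA) {
      nbea(data, gsc, grn, method = m, cfg = pcfg)
    } else {
      run_plugin(m, data, gsc, alpha = cfg$alpha, grn = grn)
    }
    rankings[[m]] <- r
    write_ranking(r, file.path(cfg$outdir,
                               paste0("ranking_", safe_name(m), ".tsv")))
  }

  combined <- NULL
  if (length(rankings) >= 2L) {
    combined <- combine_rankings(rankings, rank_type = cfg$rank_type,
                                 statistic = cfg$statistic,
                                 combine_fn = cfg$combine_fn,
                                 support = cfg$support)
    write_combined(combined, file.path(cfg$outdir, "combined.tsv"))
  }

  if (cfg$report) {
    render_report(de, rankings, combined = combined, gsc = gsc, grn = grn,
                  data = data, outdir = file.path(cfg$outdir, "report"),
                  alpha = cfg$alpha)
  }
  message("workflow done: ", length(rankings), " method(s), seed ",
          cfg$seed, ", output in ", cfg$outdir)
  invisible(list(de = de, rankings = rankings, combined = combined,
                 outdir = cfg$outdir))
}
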