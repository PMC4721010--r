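# Seeded synthetic-data generator: expression matrices with spiked
# differentially expressed gene sets and effect-consistent regulatory
# networks, so every analysis module is testable without external data.

#' Simulation specification
#'
#' Defaults describe the benchmark condition used throughout the package's
#' tests: 2000 genes, 6 + 6 samples, 20 disjoint sets of 25 genes, one
#' spiked set whose genes shift by 2 log2 units (unit noise SD), and a
#' within-set regulatory network whose edge signs match the simulated
#' per-gene directions (consistency 1) for spiked sets.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_group Samples per group (control and case).
#' @param n_sets Number of gene sets (disjoint samples of the gene space).
#' @param set_size Genes per set; `set_size * n_sets <= n_genes`.
#' @param n_spiked_sets Number of spiked (truly de-regulated) sets.
#' @param effect_size Mean log2 shift `delta` of spiked-set genes in cases
#'   (sign per gene is drawn and recorded).
#' @param noise_sd Normal noise standard deviation `sigma`.
#' @param network_consistency Fraction `rho` of spiked-set edges whose
#'   effect sign matches the simulated gene directions.
#' @param edges_per_set Regulatory edges drawn within each set.
#' @param baseline Baseline log2 expression level.
#' @param data_type `"microarray"` (Normal noise on the log2 scale) or
#'   `"rnaseq"` (negative-binomial counts, log-linear group effect,
#'   dispersion 0.1).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 2000, n_samples_per_group = 6,
                            n_sets = 20, set_size = 25, n_spiked_sets = 1,
                            effect_size = 2, noise_sd = 1,
                            network_consistency = 1, edges_per_set = 24,
                            baseline = 8,
                            data_type = c("microarray", "rnaseq"),
                            seed = 1) {
  data_type <- match.arg(data_type)
  spec <- list(n_genes = n_genes, n_samples_per_group = n_samples_per_group,
               n_sets = n_sets, set_size = set_size,
               n_spiked_sets = n_spiked_sets, effect_size = effect_size,
               noise_sd = noise_sd,
               network_consistency = network_consistency,
               edges_per_set = edges_per_set, baseline = baseline,
               data_type = data_type, seed = as.integer(seed))
  if (spec$effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (spec$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (spec$network_consistency < 0 || spec$network_consistency > 1) {
    stop("network_consistency must lie in [0, 1]", call. = FALSE)
  }
  if (spec$n_spiked_sets > spec$n_sets) {
    stop("n_spiked_sets must not exceed n_sets", call. = FALSE)
  }
  if (spec$set_size * spec$n_sets > spec$n_genes) {
    stop("infeasible: set_size * n_sets exceeds n_genes (disjoint sets)",
         call. = FALSE)
  }
  structure(spec, class = "simulation_spec")
}

#' Simulate an expression study with spiked gene sets
#'
#' Background genes are drawn Normal(baseline, sigma^2) in both groups
#' (microarray) or negative binomial around a common mean (rnaseq).
#' Spiked-set genes additionally shift by +/- `effect_size` in cases; the
#' direction of each gene is drawn once and recorded in the truth table.
#' Gene sets are disjoint subsets of a shuffled gene space. Within every
#' set, `edges_per_set` regulatory edges are drawn (a chain plus random
#' extras); for spiked sets, each edge's effect is set so that activation
#' connects same-direction genes and inhibition opposite-direction genes
#' with probability `network_consistency`, and flipped otherwise; for
#' background sets effect signs are random.
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements `data` ([expression_dataset()]),
#'   `gsc` ([gene_set_collection()]), `grn` ([regulatory_network()]) and
#'   `truth` (a tibble: `set_id`, `spiked`; gene-level directions in
#'   attribute `gene_truth`).
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  ns <- spec$n_samples_per_group
  gene_ids <- sprintf("g%05d", seq_len(n))
  sample_ids <- c(sprintf("ctrl%02d", seq_len(ns)),
                  sprintf("case%02d", seq_len(ns)))
  groups <- rep(c(0L, 1L), each = ns)

  # disjoint sets over a shuffled gene space
  shuffled <- sample(gene_ids)
  set_ids <- sprintf("set%02d", seq_len(spec$n_sets))
  sets <- stats::setNames(
    split(shuffled[seq_len(spec$n_sets * spec$set_size)],
          rep(seq_len(spec$n_sets), each = spec$set_size)),
    set_ids)
  spiked <- set_ids[seq_len(spec$n_spiked_sets)]

  # per-gene true shift (0 for background)
  direction <- stats::setNames(integer(n), gene_ids)
  for (sid in spiked) {
    direction[sets[[sid]]] <- sample(c(-1L, 1L), spec$set_size,
                                     replace = TRUE)
  }
  shift <- direction * spec$effect_size

  if (spec$data_type == "microarray") {
    values <- matrix(stats::rnorm(n * 2 * ns, mean = spec$baseline,
                                  sd = spec$noise_sd),
                     nrow = n, dimnames = list(gene_ids, sample_ids))
    values[, groups == 1L] <- values[, groups == 1L] + shift
  } else {
    mu0 <- 2^spec$baseline
    mu <- outer(rep(mu0, n), rep(1, 2 * ns))
    mu[, groups == 1L] <- mu[, groups == 1L] * 2^shift
    values <- matrix(stats::rnbinom(n * 2 * ns, mu = as.vector(mu),
                                    size = 1 / 0.1),
                     nrow = n, dimnames = list(gene_ids, sample_ids))
  }
  data <- expression_dataset(values, groups = groups,
                             data_type = spec$data_type)
  gsc <- gene_set_collection(sets,
                             stats::setNames(
                               ifelse(set_ids %in% spiked,
                                      "spiked set", "background set"),
                               set_ids))

  # within-set network: chain + random extra pairs
  reg <- character(0); tgt <- character(0); eff <- character(0)
  for (sid in set_ids) {
    g <- sets[[sid]]
    chain <- cbind(g[-length(g)], g[-1L])
    extra_n <- max(0L, spec$edges_per_set - nrow(chain))
    pairs <- chain
    if (extra_n > 0L) {
      extra <- t(replicate(extra_n, sample(g, 2L)))
      pairs <- rbind(chain, extra)
    } else {
      pairs <- chain[seq_len(min(nrow(chain), spec$edges_per_set)), ,
                     drop = FALSE]
    }
    d1 <- direction[pairs[, 1L]]
    d2 <- direction[pairs[, 2L]]
    if (sid %in% spiked) {
      consistent_eff <- ifelse(d1 * d2 >= 0, "activation", "inhibition")
      keep <- stats::runif(nrow(pairs)) < spec$network_consistency
      e <- ifelse(keep, consistent_eff,
                  ifelse(consistent_eff == "activation",
                         "inhibition", "activation"))
    } else {
      e <- sample(c("activation", "inhibition"), nrow(pairs),
                  replace = TRUE)
    }
    reg <- c(reg, pairs[, 1L]); tgt <- c(tgt, pairs[, 2L]); eff <- c(eff, e)
  }
  grn <- regulatory_network(reg, tgt, eff)

  truth <- tibble::tibble(set_id = set_ids, spiked = set_ids %in% spiked)
  attr(truth, "gene_truth") <- tibble::tibble(
    gene_id = gene_ids, direction = unname(direction))
  list(data = data, gsc = gsc, grn = grn, truth = truth)
}

#' Write a simulated study to disk in the package's file dialects
#'
#' Emits `expression.tsv`, `groups.tsv`, `sets.gmt`, `network.tsv`,
#' `truth.tsv` (set-level truth) and `gene_truth.tsv` into `dir`.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$data, file.path(dir, "expression.tsv"),
                   file.path(dir, "groups.tsv"))
  write_gmt(sim$gsc, file.path(dir, "sets.gmt"))
  write_network(sim$grn, file.path(dir, "network.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(attr(sim$truth, "gene_truth"),
                   file.path(dir, "gene_truth.tsv"))
  invisible(dir)
}

#' Read a simulated study back from disk
#'
#' @param dir Directory written by [write_study()].
#' @param data_type Expression data type.
#' @return A list like [simulate_study()]'s.
#' @export
read_study <- function(dir, data_type = "microarray") {
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           show_col_types = FALSE)
  attr(truth, "gene_truth") <- readr::read_tsv(
    file.path(dir, "gene_truth.tsv"), show_col_types = FALSE)
  list(
    data = read_expression(file.path(dir, "expression.tsv"),
                           file.path(dir, "groups.tsv"),
                           data_type = data_type),
    gsc = read_gmt(file.path(dir, "sets.gmt")),
    grn = read_network(file.path(dir, "network.tsv")),
    truth = truth
  )
}
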