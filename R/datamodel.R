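#' Construct an expression dataset
#'
#' Bundles a genes-by-samples expression matrix with its two-group sample
#' classification. Values are log2 intensities for `data_type = "microarray"`
#' and non-negative integer read counts for `data_type = "rnaseq"`.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers (opaque, case-sensitive strings), column names are
#'   sample identifiers.
#' @param groups Integer vector of 0/1 labels, one per sample
#'   (0 = control, 1 = case).
#' @param blocks Optional per-sample block labels for paired designs
#'   (each block must contain exactly one case and one control when used
#'   with paired statistics).
#' @param data_type `"microarray"` (log2 scale) or `"rnaseq"` (counts).
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `groups`, `blocks`, `data_type`.
#' @export
expression_dataset <- function(values, groups,
                               blocks = NULL,
                               data_type = c("microarray", "rnaseq")) {
  data_type <- match.arg(data_type)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric", call. = FALSE)
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("expression matrix needs row (gene) and column (sample) names",
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene ids: ", paste(dups, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("missing values are not supported", call. = FALSE)
  }
  groups <- as.integer(groups)
  if (length(groups) != ncol(values)) {
    stop("length(groups) must equal the number of samples", call. = FALSE)
  }
  if (!all(groups %in% c(0L, 1L))) {
    stop("groups must be coded 0 (control) / 1 (case)", call. = FALSE)
  }
  if (sum(groups == 0L) < 1L || sum(groups == 1L) < 1L) {
    stop("each group needs at least one sample", call. = FALSE)
  }
  if (data_type == "rnaseq" && any(values < 0)) {
    stop("rnaseq counts must be non-negative", call. = FALSE)
  }
  if (!is.null(blocks)) {
    blocks <- as.character(blocks)
    if (length(blocks) != ncol(values)) {
      stop("length(blocks) must equal the number of samples", call. = FALSE)
    }
  }
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         groups = groups, blocks = blocks, data_type = data_type),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples (%s), %d control / %d case\n",
              nrow(x$values), ncol(x$values), x$data_type,
              sum(x$groups == 0L), sum(x$groups == 1L)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Tidy an expression dataset into long form
#'
#' @param x An `expression_dataset`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `group`, `value`.
#' @importFrom generics tidy
#' @exportS3Method generics::tidy
tidy.expression_dataset <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(x$gene_ids, times = ncol(x$values)),
    sample_id = rep(x$sample_ids, each = nrow(x$values)),
    group = rep(x$groups, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors of gene identifiers; names are
#'   set identifiers. Within-set duplicates are removed, preserving first
#'   occurrence order.
#' @param descriptions Optional named character vector of free-text set
#'   descriptions; missing entries default to `""`.
#'
#' @return An object of class `gene_set_collection`: a named list of
#'   character vectors with a `descriptions` attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) && (is.null(names(sets)) || any(!nzchar(names(sets))))) {
    stop("every gene set needs a non-empty id", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    dups <- unique(names(sets)[duplicated(names(sets))])
    stop("duplicate set ids: ", paste(dups, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  desc <- stats::setNames(rep("", length(sets)), names(sets))
  if (!is.null(descriptions)) {
    hit <- intersect(names(descriptions), names(desc))
    desc[hit] <- descriptions[hit]
  }
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, sizes %s\n", length(x),
              if (length(x)) paste0(min(lengths(x)), "-", max(lengths(x)))
              else "-"))
  invisible(x)
}

#' Tidy a gene set collection
#'
#' @param x A `gene_set_collection`.
#' @param ... Unused.
#' @return A tibble with columns `set_id`, `gene_id`.
#' @exportS3Method generics::tidy
tidy.gene_set_collection <- function(x, ...) {
  tibble::tibble(
    set_id = rep(names(x), lengths(x)),
    gene_id = unlist(x, use.names = FALSE)
  )
}

#' Construct a regulatory network
#'
#' Directed signed edges over gene identifiers. Exact duplicate triples are
#' collapsed; conflicting duplicates (same regulator/target pair with both
#' effects) are retained as distinct edges.
#'
#' @param regulator,target Character vectors of gene identifiers.
#' @param effect Character vector, `"activation"` or `"inhibition"`.
#'
#' @return A tibble of class `regulatory_network` with columns
#'   `regulator`, `target`, `effect`.
#' @export
regulatory_network <- function(regulator, target, effect) {
  effect <- as.character(effect)
  bad <- setdiff(unique(effect), c("activation", "inhibition"))
  if (length(bad)) {
    stop("unknown effect value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  edges <- tibble::tibble(
    regulator = as.character(regulator),
    target = as.character(target),
    effect = effect
  )
  edges <- dplyr::distinct(edges)
  class(edges) <- c("regulatory_network", class(edges))
  edges
}

new_gmt_error <- function(msg) stop(msg, call. = FALSE)

#' Read a gene set collection from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `set_id`, `description`, then one or more gene identifiers.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()]. Line order is preserved; genes are
#'   deduplicated within each set.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(gene_set_collection(stats::setNames(list(), character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    new_gmt_error(sprintf("GMT format error: line %d has %d field(s), need >= 3",
                          which(nf < 3L)[1L], nf[which(nf < 3L)[1L]]))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    new_gmt_error(sprintf("duplicate set id in GMT: %s",
                          ids[duplicated(ids)][1L]))
  }
  desc <- stats::setNames(vapply(fields, `[[`, character(1), 2L), ids)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), ids)
  gene_set_collection(sets, desc)
}

#' Write a gene set collection to a GMT file
#'
#' @param gsc A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  desc <- attr(gsc, "descriptions")
  lines <- vapply(names(gsc), function(id) {
    paste(c(id, desc[[id]], gsc[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a regulatory network from a 3-column TSV file
#'
#' Dialect: `regulator<TAB>target<TAB>effect` with effect `+` (activation)
#' or `-` (inhibition); lines starting with `#` are skipped.
#'
#' @param path Path to the TSV file.
#' @return A [regulatory_network()] with exact duplicates collapsed.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) {
    return(regulatory_network(character(), character(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    stop(sprintf("network format error: line %d has %d column(s), need 3",
                 which(nf != 3L)[1L], nf[which(nf != 3L)[1L]]), call. = FALSE)
  }
  sym <- vapply(fields, `[[`, character(1), 3L)
  bad <- setdiff(unique(sym), c("+", "-"))
  if (length(bad)) {
    stop("network format error: unknown effect symbol(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  regulatory_network(
    regulator = vapply(fields, `[[`, character(1), 1L),
    target = vapply(fields, `[[`, character(1), 2L),
    effect = ifelse(sym == "+", "activation", "inhibition")
  )
}

#' Write a regulatory network to the 3-column TSV dialect
#'
#' @param grn A `regulatory_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(grn, path) {
  sym <- ifelse(grn$effect == "activation", "+", "-")
  writeLines(paste(grn$regulator, grn$target, sym, sep = "\t"), path)
  invisible(path)
}

#' Read an expression dataset from matrix + groups TSV files
#'
#' The matrix file has a header line `gene_id<TAB>sample1<TAB>...` and one
#' row per gene. The groups file has one line per sample:
#' `sample_id<TAB>group[<TAB>block]` with group coded 0/1. The groups file
#' defines sample order, so downstream results do not depend on matrix
#' column order.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param groups_path Path to the sample classification TSV.
#' @param data_type `"microarray"` or `"rnaseq"`.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, groups_path,
                            data_type = c("microarray", "rnaseq")) {
  data_type <- match.arg(data_type)
  for (p in c(matrix_path, groups_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  grp_lines <- readLines(groups_path, warn = FALSE)
  grp_lines <- grp_lines[nzchar(trimws(grp_lines))]
  grp_fields <- strsplit(grp_lines, "\t", fixed = TRUE)
  nf <- lengths(grp_fields)
  if (any(nf < 2L)) {
    stop("groups file: line ", which(nf < 2L)[1L],
         " needs at least sample_id and group", call. = FALSE)
  }
  g_samples <- vapply(grp_fields, `[[`, character(1), 1L)
  g_labels <- vapply(grp_fields, `[[`, character(1), 2L)
  if (!all(g_labels %in% c("0", "1"))) {
    stop("groups file: group labels must be 0 or 1 (got: ",
         paste(unique(setdiff(g_labels, c("0", "1"))), collapse = ", "), ")",
         call. = FALSE)
  }
  blocks <- NULL
  if (all(nf >= 3L)) {
    blocks <- vapply(grp_fields, `[[`, character(1), 3L)
  }

  tab <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  gene_ids <- tab[[1L]]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id in matrix: ",
         gene_ids[duplicated(gene_ids)][1L], call. = FALSE)
  }
  m_samples <- colnames(tab)[-1L]
  missing_in_groups <- setdiff(m_samples, g_samples)
  missing_in_matrix <- setdiff(g_samples, m_samples)
  if (length(missing_in_groups) || length(missing_in_matrix)) {
    stop("sample mismatch between matrix and groups file",
         if (length(missing_in_groups))
           paste0("; not in groups file: ",
                  paste(missing_in_groups, collapse = ", ")),
         if (length(missing_in_matrix))
           paste0("; not in matrix: ",
                  paste(missing_in_matrix, collapse = ", ")),
         call. = FALSE)
  }
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 gene_ids[idx[1L]], m_samples[idx[2L]]), call. = FALSE)
  }
  dimnames(num) <- list(gene_ids, m_samples)
  num <- num[, g_samples, drop = FALSE]   # groups file fixes sample order
  expression_dataset(num, groups = as.integer(g_labels), blocks = blocks,
                     data_type = data_type)
}

#' Write an expression dataset to matrix + groups TSV files
#'
#' @param data An `expression_dataset`.
#' @param matrix_path,groups_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(data, matrix_path, groups_path) {
  header <- paste(c("gene_id", data$sample_ids), collapse = "\t")
  body <- vapply(seq_along(data$gene_ids), function(i) {
    paste(c(data$gene_ids[i],
            format(data$values[i, ], trim = TRUE, scientific = FALSE,
                   digits = 15)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), matrix_path)
  grp <- paste(data$sample_ids, data$groups, sep = "\t")
  if (!is.null(data$blocks)) grp <- paste(grp, data$blocks, sep = "\t")
  writeLines(grp, groups_path)
  invisible(matrix_path)
}
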