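# In-code fixtures shared across test files.

# Tiny two-group dataset: genes x (3 control + 3 case), deterministic.
tiny_dataset <- function(values, data_type = "microarray") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  expression_dataset(values,
                     groups = rep(c(0L, 1L), each = ncol(values) / 2),
                     data_type = data_type)
}

# Null dataset: pure noise, no group signal.
null_dataset <- function(n_genes, n_per_group, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 2 * n_per_group), nrow = n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(2 * n_per_group))))
  expression_dataset(m, groups = rep(c(0L, 1L), each = n_per_group))
}

# Disjoint gene set collection over the rows of a dataset.
disjoint_sets <- function(data, n_sets, set_size) {
  ids <- data$gene_ids
  stopifnot(n_sets * set_size <= length(ids))
  sets <- split(ids[seq_len(n_sets * set_size)],
                rep(seq_len(n_sets), each = set_size))
  names(sets) <- sprintf("S%02d", seq_len(n_sets))
  gene_set_collection(sets)
}

# Brute-force exhaustive-relabeling p-values for a per-set global statistic.
# global_fn(abs_t, member_idx) -> scalar; counts assignments (including the
# observed one) whose statistic is at least the observed.
brute_force_exhaustive_p <- function(data, member_idx_list, global_fn) {
  X <- data$values
  n <- ncol(X)
  n1 <- sum(data$groups)
  combos <- utils::combn(n, n1)
  abs_t_for <- function(case_cols) {
    g <- integer(n); g[case_cols] <- 1L
    apply(X, 1, function(v) {
      x1 <- v[g == 1L]; x0 <- v[g == 0L]
      sp2 <- (sum((x1 - mean(x1))^2) + sum((x0 - mean(x0))^2)) /
        (n - 2)
      if (sp2 == 0) {
        if (mean(x1) == mean(x0)) 0 else Inf
      } else {
        abs((mean(x1) - mean(x0)) /
              sqrt(sp2 * (1 / length(x1) + 1 / length(x0))))
      }
    })
  }
  obs_stats <- abs_t_for(which(data$groups == 1L))
  obs <- vapply(member_idx_list, function(i) global_fn(obs_stats, i),
                numeric(1))
  perm <- matrix(NA_real_, nrow = length(member_idx_list),
                 ncol = ncol(combos))
  for (b in seq_len(ncol(combos))) {
    st <- abs_t_for(combos[, b])
    perm[, b] <- vapply(member_idx_list, function(i) global_fn(st, i),
                        numeric(1))
  }
  vapply(seq_along(member_idx_list), function(s) {
    sum(perm[s, ] >= obs[s]) / ncol(combos)
  }, numeric(1))
}

# Crawl a bundle from index.html: every href/src must resolve to a file,
# and every file in the bundle must be reachable.
crawl_bundle <- function(dir) {
  seen <- character(0)
  queue <- "index.html"
  dangling <- character(0)
  while (length(queue)) {
    page <- queue[[1L]]; queue <- queue[-1L]
    if (page %in% seen) next
    seen <- c(seen, page)
    path <- file.path(dir, page)
    if (!file.exists(path)) {
      dangling <- c(dangling, page)
      next
    }
    if (!grepl("\\.html$", page)) next
    doc <- xml2::read_html(path)
    refs <- c(xml2::xml_attr(xml2::xml_find_all(doc, "//a"), "href"),
              xml2::xml_attr(xml2::xml_find_all(doc, "//img"), "src"),
              xml2::xml_attr(xml2::xml_find_all(doc, "//link"), "href"))
    refs <- refs[!is.na(refs) & !startsWith(refs, "#") &
                   !grepl("^[a-z]+:", refs)]
    queue <- c(queue, setdiff(refs, seen))
  }
  list(reached = seen, dangling = dangling)
}

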