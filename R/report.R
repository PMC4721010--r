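# Static HTML report: index page, gene report, per-method flat rankings,
# per-set detail pages (set-based and network-based views) and the
# combined page. Output is deterministic for identical inputs: no
# timestamps, fixed number formatting, hand-assembled SVG graphics.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15, format(x, scientific = FALSE,
                                                      trim = TRUE),
                format(signif(x, 4), trim = TRUE)))
}

safe_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

html_table <- function(df, id = "tbl", sortable = TRUE) {
  cells <- vapply(seq_len(nrow(df)), function(i) {
    row <- vapply(seq_along(df), function(j) {
      v <- df[[j]][i]
      if (is.numeric(v)) sprintf("<td class=\"num\">%s</td>", fmt_num(v))
      else sprintf("<td>%s</td>", html_escape(as.character(v)))
    }, character(1))
    paste0("<tr>", paste(row, collapse = ""), "</tr>")
  }, character(1))
  head <- paste0("<tr>", paste(sprintf("<th>%s</th>",
                                       html_escape(names(df))),
                               collapse = ""), "</tr>")
  sprintf("<table id=\"%s\"%s><thead>%s</thead><tbody>\n%s\n</tbody></table>",
          id, if (sortable) " class=\"sortable\"" else "",
          head, paste(cells, collapse = "\n"))
}

html_page <- function(title, body, css = "style.css") {
  paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>\n",
    sprintf("<title>%s</title>\n", html_escape(title)),
    sprintf("<link rel=\"stylesheet\" href=\"%s\"/>\n", css),
    "</head><body>\n",
    sprintf("<h1>%s</h1>\n", html_escape(title)),
    body,
    "\n<script>\n", sort_js(), "</script>\n",
    "</body></html>\n"
  )
}

sort_js <- function() {
  paste(
    "document.querySelectorAll('table.sortable th').forEach(function(th){",
    " th.addEventListener('click', function(){",
    "  var tb=th.closest('table').querySelector('tbody');",
    "  var i=Array.prototype.indexOf.call(th.parentNode.children,th);",
    "  var rows=Array.prototype.slice.call(tb.querySelectorAll('tr'));",
    "  var asc=!(th.dataset.asc==='1'); th.dataset.asc=asc?'1':'0';",
    "  rows.sort(function(a,b){",
    "   var x=a.children[i].textContent,y=b.children[i].textContent;",
    "   var nx=parseFloat(x),ny=parseFloat(y);",
    "   var c=(!isNaN(nx)&&!isNaN(ny))?nx-ny:x.localeCompare(y);",
    "   return asc?c:-c;});",
    "  rows.forEach(function(r){tb.appendChild(r);});",
    " });",
    "});", sep = "\n")
}

report_css <- function() {
  paste(
    "body{font-family:sans-serif;margin:2em;max-width:70em;}",
    "table{border-collapse:collapse;margin:1em 0;}",
    "th,td{border:1px solid #999;padding:0.25em 0.6em;}",
    "th{background:#eee;cursor:pointer;}",
    "td.num{text-align:right;font-variant-numeric:tabular-nums;}",
    "img{border:1px solid #ccc;margin:0.5em 0;}",
    "a{color:#06c;}", sep = "\n")
}

# Deterministic SVG scatter (volcano plot: log2fc vs -log10 p).
svg_scatter <- function(x, y, highlight = logical(length(x)),
                        xlab = "log2 fold change",
                        ylab = "-log10(p)", width = 480, height = 360) {
  pad <- 45
  finite_y <- y[is.finite(y)]
  xr <- range(x, 0, finite = TRUE)
  yr <- range(finite_y, 0)
  if (diff(xr) == 0) xr <- xr + c(-1, 1)
  if (diff(yr) == 0) yr <- yr + c(0, 1)
  y[!is.finite(y)] <- yr[2L]
  px <- pad + (x - xr[1L]) / diff(xr) * (width - 2 * pad)
  py <- height - pad - (y - yr[1L]) / diff(yr) * (height - 2 * pad)
  pts <- sprintf("<circle cx=\"%.1f\" cy=\"%.1f\" r=\"2.5\" fill=\"%s\"/>",
                 px, py, ifelse(highlight, "#d40", "#69b"))
  paste0(
    sprintf("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" height=\"%d\">",
            width, height),
    sprintf("<rect width=\"%d\" height=\"%d\" fill=\"white\"/>", width, height),
    sprintf("<line x1=\"%d\" y1=\"%d\" x2=\"%d\" y2=\"%d\" stroke=\"black\"/>",
            pad, height - pad, width - pad, height - pad),
    sprintf("<line x1=\"%d\" y1=\"%d\" x2=\"%d\" y2=\"%d\" stroke=\"black\"/>",
            pad, pad, pad, height - pad),
    sprintf("<text x=\"%d\" y=\"%d\" font-size=\"12\" text-anchor=\"middle\">%s</text>",
            width %/% 2, height - 10, html_escape(xlab)),
    sprintf("<text x=\"14\" y=\"%d\" font-size=\"12\" text-anchor=\"middle\" transform=\"rotate(-90 14 %d)\">%s</text>",
            height %/% 2, height %/% 2, html_escape(ylab)),
    paste(pts, collapse = ""),
    "</svg>")
}

# Deterministic SVG expression heatmap, rows/cols ordered by
# average-linkage hierarchical clustering of Euclidean distances.
svg_heatmap <- function(values, width = 480, height = 360) {
  if (nrow(values) > 2L) {
    values <- values[stats::hclust(stats::dist(values),
                                   method = "average")$order, ,
                     drop = FALSE]
  }
  if (ncol(values) > 2L) {
    values <- values[, stats::hclust(stats::dist(t(values)),
                                     method = "average")$order,
                     drop = FALSE]
  }
  rng <- range(values)
  z <- if (diff(rng) == 0) values * 0 + 0.5 else
    (values - rng[1L]) / diff(rng)
  cw <- width / ncol(values); ch <- height / nrow(values)
  cells <- character(0)
  for (i in seq_len(nrow(values))) {
    for (j in seq_len(ncol(values))) {
      v <- z[i, j]
      col <- grDevices::rgb(v, 0.2 + 0.3 * (1 - v), 1 - v)
      cells <- c(cells,
                 sprintf("<rect x=\"%.1f\" y=\"%.1f\" width=\"%.1f\" height=\"%.1f\" fill=\"%s\"/>",
                         (j - 1) * cw, (i - 1) * ch, cw, ch, col))
    }
  }
  paste0(
    sprintf("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" height=\"%d\">",
            width, height),
    paste(cells, collapse = ""), "</svg>")
}

# Binned -log10 p-value histogram as SVG.
svg_histogram <- function(p, bins = 20, width = 480, height = 240) {
  counts <- tabulate(pmin(floor(p * bins) + 1L, bins), nbins = bins)
  mx <- max(counts, 1L)
  pad <- 30
  bw <- (width - 2 * pad) / bins
  bars <- sprintf(
    "<rect x=\"%.1f\" y=\"%.1f\" width=\"%.1f\" height=\"%.1f\" fill=\"#69b\"/>",
    pad + (seq_len(bins) - 1) * bw,
    height - pad - counts / mx * (height - 2 * pad),
    bw * 0.9, counts / mx * (height - 2 * pad))
  paste0(
    sprintf("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" height=\"%d\">",
            width, height),
    sprintf("<rect width=\"%d\" height=\"%d\" fill=\"white\"/>", width, height),
    sprintf("<line x1=\"%d\" y1=\"%d\" x2=\"%d\" y2=\"%d\" stroke=\"black\"/>",
            pad, height - pad, width - pad, height - pad),
    paste(bars, collapse = ""), "</svg>")
}

write_file <- function(text, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(text, con, sep = "\n", useBytes = TRUE)
}

#' Render a static HTML report
#'
#' Writes a self-contained bundle: `index.html` linking a gene report
#' (per-gene differential expression with volcano plot and p-value
#' histogram), one flat ranking page per method, per-set detail pages for
#' significant sets (member-gene table + member-highlighting volcano, an
#' expression heatmap when `data` is given, and an edge-consistency table
#' when a network is given), and the combined page. Every table is also
#' written as TSV alongside. Output is byte-identical across re-renders of
#' identical inputs.
#'
#' @param de A [de_statistics()] result.
#' @param rankings Named list of `enrichment_ranking` tibbles.
#' @param combined Optional [combine_rankings()] result.
#' @param gsc The [gene_set_collection()] analysed.
#' @param grn Optional [regulatory_network()] (enables the network view).
#' @param data Optional [expression_dataset()] (enables heatmaps).
#' @param outdir Output directory, created if needed.
#' @param alpha Adjusted-p threshold defining which sets get detail pages.
#' @return The output directory, invisibly (class `report_bundle`).
#' @export
render_report <- function(de, rankings, combined = NULL, gsc, grn = NULL,
                          data = NULL, outdir, alpha = 0.05) {
  if (!length(rankings)) stop("no rankings to report", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)
  methods <- ranking_method_name(rankings)

  write_file(report_css(), file.path(outdir, "style.css"))

  # ---- gene report ----
  de_tbl <- as.data.frame(de)
  readr::write_tsv(de_tbl, file.path(outdir, "genes.tsv"))
  write_file(svg_scatter(de$log2fc, -log10(pmax(de$pval, 1e-300)),
                         highlight = de$adj_pval < alpha),
             file.path(outdir, "volcano.svg"))
  write_file(svg_histogram(de$pval), file.path(outdir, "pvalues.svg"))
  gene_body <- paste0(
    "<p><a href=\"index.html\">index</a> | <a href=\"genes.tsv\">TSV</a></p>\n",
    "<img src=\"volcano.svg\" alt=\"volcano plot\"/>\n",
    "<img src=\"pvalues.svg\" alt=\"p-value histogram\"/>\n",
    html_table(de_tbl, id = "genes"))
  write_file(html_page("Gene report", gene_body),
             file.path(outdir, "genes.html"))

  # ---- per-method ranking + detail pages ----
  detail_links <- character(0)
  ranking_pages <- character(length(methods))
  for (m in seq_along(methods)) {
    method <- methods[m]
    r <- rankings[[m]]
    base <- paste0("ranking_", safe_name(method))
    readr::write_tsv(as.data.frame(r), file.path(outdir,
                                                 paste0(base, ".tsv")))
    sig <- r$set_id[r$adj_pval < alpha]
    rows2 <- as.data.frame(r)
    links <- ifelse(
      rows2$set_id %in% sig,
      sprintf("<a href=\"set_%s_%s.html\">%s</a>", safe_name(method),
              safe_name(rows2$set_id), html_escape(rows2$set_id)),
      html_escape(rows2$set_id))
    # set_id column holds pre-rendered links, so the table is assembled
    # cell by cell rather than through html_table (which escapes)
    cells <- vapply(seq_len(nrow(rows2)), function(i) {
      first <- sprintf("<td>%s</td>", links[i])
      rest <- vapply(2:ncol(rows2), function(j) {
        v <- rows2[[j]][i]
        if (is.numeric(v)) sprintf("<td class=\"num\">%s</td>", fmt_num(v))
        else sprintf("<td>%s</td>", html_escape(as.character(v)))
      }, character(1))
      paste0("<tr>", first, paste(rest, collapse = ""), "</tr>")
    }, character(1))
    head_row <- paste0("<tr>", paste(sprintf("<th>%s</th>",
                                             html_escape(names(rows2))),
                                     collapse = ""), "</tr>")
    tbl <- sprintf(
      "<table id=\"%s\" class=\"sortable\"><thead>%s</thead><tbody>\n%s\n</tbody></table>",
      base, head_row, paste(cells, collapse = "\n"))
    body <- paste0(
      "<p><a href=\"index.html\">index</a> | <a href=\"", base,
      ".tsv\">TSV</a></p>\n", tbl)
    write_file(html_page(paste("Ranking:", method), body),
               file.path(outdir, paste0(base, ".html")))
    ranking_pages[m] <- paste0(base, ".html")

    for (sid in sig) {
      page <- render_set_page(method, sid, de, gsc, grn, data, outdir,
                              alpha)
      detail_links <- c(detail_links, page)
    }
  }

  # ---- combined page ----
  combined_link <- NULL
  if (!is.null(combined)) {
    readr::write_tsv(as.data.frame(combined),
                     file.path(outdir, "combined.tsv"))
    body <- paste0(
      "<p><a href=\"index.html\">index</a> | ",
      "<a href=\"combined.tsv\">TSV</a></p>\n",
      sprintf("<p>%s of %s %s ranks over: %s (support: %s). Click a column header to sort.</p>\n",
              attr(combined, "combine_fn"), attr(combined, "rank_type"),
              attr(combined, "statistic"),
              paste(attr(combined, "methods"), collapse = ", "),
              attr(combined, "support")),
      html_table(as.data.frame(combined), id = "combined"))
    write_file(html_page("Combined ranking", body),
               file.path(outdir, "combined.html"))
    combined_link <- "combined.html"
  }

  # ---- index ----
  items <- c(
    "<li><a href=\"genes.html\">Gene report</a></li>",
    sprintf("<li><a href=\"%s\">Ranking: %s</a></li>", ranking_pages,
            html_escape(methods)),
    if (!is.null(combined_link))
      sprintf("<li><a href=\"%s\">Combined ranking</a></li>", combined_link),
    if (length(detail_links))
      sprintf("<li>Significant set pages: %s</li>",
              paste(sprintf("<a href=\"%s\">%s</a>", detail_links,
                            html_escape(sub("\\.html$", "",
                                            sub("^set_", "", detail_links)))),
                    collapse = " ")))
  write_file(html_page("Enrichment analysis report",
                       paste0("<ul>\n", paste(items, collapse = "\n"),
                              "\n</ul>")),
             file.path(outdir, "index.html"))
  structure(invisible(outdir), class = "report_bundle")
}

render_set_page <- function(method, sid, de, gsc, grn, data, outdir,
                            alpha) {
  fname <- sprintf("set_%s_%s.html", safe_name(method), safe_name(sid))
  members <- if (sid %in% names(gsc)) gsc[[sid]] else character(0)
  in_set <- de$gene_id %in% members
  member_tbl <- as.data.frame(de[in_set, , drop = FALSE])
  base <- sprintf("set_%s_%s", safe_name(method), safe_name(sid))
  readr::write_tsv(member_tbl, file.path(outdir, paste0(base, ".tsv")))
  write_file(svg_scatter(de$log2fc, -log10(pmax(de$pval, 1e-300)),
                         highlight = in_set),
             file.path(outdir, paste0(base, "_volcano.svg")))
  body <- paste0(
    "<p><a href=\"index.html\">index</a> | <a href=\"", base,
    ".tsv\">TSV</a></p>\n",
    sprintf("<p>%d member gene(s) measured; set members highlighted in the volcano plot.</p>\n",
            sum(in_set)),
    sprintf("<img src=\"%s_volcano.svg\" alt=\"volcano\"/>\n", base),
    "<h2>Member genes</h2>\n",
    html_table(member_tbl, id = paste0(base, "_genes")))
  if (!is.null(data) && sum(in_set) >= 2) {
    hm <- svg_heatmap(data$values[data$gene_ids %in% members, ,
                                  drop = FALSE])
    write_file(hm, file.path(outdir, paste0(base, "_heatmap.svg")))
    body <- paste0(body,
                   "<h2>Expression heatmap</h2>\n",
                   sprintf("<img src=\"%s_heatmap.svg\" alt=\"heatmap\"/>\n",
                           base))
  }
  if (!is.null(grn)) {
    et <- set_edge_table(de, grn, members)
    if (nrow(et)) {
      readr::write_tsv(as.data.frame(et),
                       file.path(outdir, paste0(base, "_edges.tsv")))
      body <- paste0(
        body, "<h2>Regulatory interactions</h2>\n",
        "<p><a href=\"", base, "_edges.tsv\">TSV</a></p>\n",
        html_table(as.data.frame(et), id = paste0(base, "_edges")))
    }
  }
  write_file(html_page(sprintf("%s: %s", method, sid), body),
             file.path(outdir, fname))
  fname
}
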