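# Self-contained HTML report: plain string templating, no timestamps, no
# external assets, so a fixed input regenerates the file byte-identically.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

df_to_html <- function(df, max_rows = 500L) {
  if (is.null(df) || nrow(df) == 0L) return("<p class='empty'>none</p>")
  shown <- utils::head(df, max_rows)
  for (col in names(shown)) {
    if (is.numeric(shown[[col]])) {
      shown[[col]] <- vapply(shown[[col]], function(v) {
        if (is.na(v)) "NA"
        else if (v == round(v) && abs(v) < 1e15) format(v, scientific = FALSE)
        else format(v, digits = 6)
      }, character(1))
    }
  }
  head_row <- paste0("<th>", html_escape(names(shown)), "</th>", collapse = "")
  body <- apply(shown, 1L, function(r) {
    paste0("<tr>", paste0("<td>", html_escape(r), "</td>", collapse = ""), "</tr>")
  })
  note <- if (nrow(df) > max_rows) {
    sprintf("<p class='empty'>showing %d of %d rows; see the TSV for the full table</p>",
            max_rows, nrow(df))
  } else ""
  paste0("<table><thead><tr>", head_row, "</tr></thead><tbody>",
         paste(body, collapse = "\n"), "</tbody></table>", note)
}

#' Render the pipeline HTML report
#'
#' A single self-contained HTML file (inline CSS, no scripts, no network
#' fetches, no timestamps) mirroring the written TSV tables: run
#' parameters, per-caller gain/loss summaries, caller-subset (Venn)
#' counts, consensus segments, gene assignments, enrichment results and
#' evaluation metrics. Every number shown comes from the corresponding
#' table.
#'
#' @param bundle A `cnv_pipeline_result`.
#' @param path Output HTML path.
#' @return `path`, invisibly.
#' @export
render_report <- function(bundle, path) {
  cfg <- bundle$config
  meta <- data.frame(
    parameter = c("package", "sample", "callers", "gene_coverage",
                  "min_callers", "min_segment_bp", "universe", "seed"),
    value = c(paste0("cnvconsensus ",
                     as.character(utils::packageVersion("cnvconsensus"))),
              cfg$sample, paste(names(bundle$callsets), collapse = ", "),
              format(cfg$gene_coverage), format(cfg$min_callers),
              format(cfg$min_segment_bp), cfg$universe, format(cfg$seed)),
    stringsAsFactors = FALSE)
  section <- function(title, html) {
    sprintf("<section><h2>%s</h2>\n%s\n</section>", html_escape(title), html)
  }
  parts <- c(
    section("Run parameters", df_to_html(meta)),
    section("Per-caller gain/loss summary", df_to_html(bundle$summaries)),
    section("Caller-subset (Venn) counts", df_to_html(bundle$venn_counts)),
    section(sprintf("Consensus segments (multiplicity >= %d)", cfg$min_callers),
            df_to_html(bundle$consensus$segments)),
    section(sprintf("Gene assignments (coverage >= %s)", format(cfg$gene_coverage)),
            df_to_html(bundle$genes)),
    section("Term enrichment (one-sided Fisher, BH-adjusted)",
            df_to_html(bundle$enrichment, max_rows = 200L)),
    if (!is.null(bundle$metrics)) {
      section("Evaluation vs truth (base-level TPR/FDR/precision)",
              df_to_html(bundle$metrics))
    } else NULL
  )
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'>",
    "<title>CNV consensus report: ", html_escape(cfg$sample), "</title>",
    "<style>body{font-family:sans-serif;margin:2em;max-width:70em}",
    "h1{border-bottom:2px solid #444}h2{color:#2c5777;margin-top:1.6em}",
    "table{border-collapse:collapse;font-size:0.85em}",
    "th,td{border:1px solid #bbb;padding:2px 8px;text-align:left}",
    "th{background:#eef3f7}.empty{color:#888;font-style:italic}",
    "</style></head><body>\n",
    "<h1>CNV consensus pipeline report</h1>\n",
    paste(parts, collapse = "\n"),
    "\n</body></html>\n")
  writeLines(html, path, sep = "")
  invisible(path)
}
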