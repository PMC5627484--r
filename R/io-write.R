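# Deterministic TSV output. Coordinates and bp totals are printed as plain
# integers (never scientific notation) so re-running on identical input is
# byte-identical.

fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

write_tsv <- function(df, path) {
  for (col in intersect(names(df), c("start", "end", "bp", "tp_bp", "fp_bp",
                                     "fn_bp", "tn_bp"))) {
    df[[col]] <- fmt_int(df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Write the pipeline result tables
#'
#' Emits deterministic, byte-stable TSVs into `output_dir`:
#' `per_caller_calls.tsv`, `consensus.tsv`, `genes.tsv`, `enrichment.tsv`,
#' `venn_counts.tsv`, and `metrics.tsv` when a truth profile was
#' evaluated. All genomic tables are sorted by chromosome (natural order:
#' chr1 < chr2 < ... < chr10 < chrX < chrY) and start.
#'
#' @param bundle A `cnv_pipeline_result` from [run_pipeline()], or a list
#'   with the corresponding data-frame elements.
#' @param output_dir Directory to write into (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_tables <- function(bundle, output_dir) {
  ok <- dir.exists(output_dir) || dir.create(output_dir, recursive = TRUE,
                                             showWarnings = FALSE)
  if (!dir.exists(output_dir)) {
    stop(sprintf("cannot create output directory: %s", output_dir))
  }
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(output_dir, name)
    write_tsv(df, p)
    paths <<- c(paths, p)
  }
  emit(bundle$per_caller_calls, "per_caller_calls.tsv")
  emit(bundle$consensus$segments %||% bundle$consensus, "consensus.tsv")
  emit(bundle$genes %||% empty_genes_table(), "genes.tsv")
  emit(bundle$enrichment %||% empty_enrichment_table(), "enrichment.tsv")
  emit(bundle$venn_counts, "venn_counts.tsv")
  if (!is.null(bundle$metrics)) emit(bundle$metrics, "metrics.tsv")
  invisible(paths)
}

empty_genes_table <- function() {
  data.frame(gene_id = character(0), multiplicity_class = integer(0),
             class = character(0), direction = character(0),
             coverage_fraction = numeric(0), callers = character(0),
             stringsAsFactors = FALSE)
}

empty_enrichment_table <- function() {
  data.frame(term_id = character(0), catalog = character(0),
             description = character(0), a = integer(0), b = integer(0),
             c = integer(0), d = integer(0), odds_ratio = numeric(0),
             p_value = numeric(0), p_adjusted = numeric(0),
             stringsAsFactors = FALSE)
}
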