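#' Per-caller gain/loss summary
#'
#' Event counts and covered bp per direction, per chromosome and in
#' total, for one normalized call set.
#'
#' @param callset A normalized `cnv_callset`.
#' @return Data frame: `caller`, `chrom` (chromosomes in natural order,
#'   then a `total` row), `gain_n`, `gain_bp`, `loss_n`, `loss_bp`.
#' @export
summarize_caller <- function(callset) {
  stopifnot(inherits(callset, "cnv_callset"))
  df <- as.data.frame(callset)
  chroms <- unique(df$chrom)
  chroms <- chroms[order(chrom_rank(chroms))]
  one <- function(sub, label) {
    data.frame(caller = callset_caller(callset), chrom = label,
               gain_n = sum(sub$direction == "gain"),
               gain_bp = sum((sub$end - sub$start)[sub$direction == "gain"]),
               loss_n = sum(sub$direction == "loss"),
               loss_bp = sum((sub$end - sub$start)[sub$direction == "loss"]),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(chroms, function(ch) one(df[df$chrom == ch, , drop = FALSE], ch))
  rows[[length(rows) + 1L]] <- one(df, "total")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Default assay space for evaluation: per chromosome, [0, max end) over all
# inputs.
default_assay_space <- function(callsets, truth) {
  all <- do.call(rbind, c(
    lapply(callsets, function(cs) as.data.frame(cs)[, c("chrom", "start", "end")]),
    list(as.data.frame(truth)[, c("chrom", "start", "end")])))
  if (nrow(all) == 0L) stop("cannot derive an assay space from empty inputs")
  agg <- stats::aggregate(end ~ chrom, data = all, FUN = max)
  sort_intervals(data.frame(chrom = agg$chrom, start = 0, end = agg$end,
                            stringsAsFactors = FALSE))
}

read_assay_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  rows <- strsplit(lines, "\t")
  if (any(vapply(rows, length, integer(1)) < 3L)) {
    stop(sprintf("%s: assay BED needs >= 3 columns", path))
  }
  iv_reduce(data.frame(
    chrom = vapply(rows, `[`, character(1), 1L),
    start = as.numeric(vapply(rows, `[`, character(1), 2L)),
    end = as.numeric(vapply(rows, `[`, character(1), 3L)),
    stringsAsFactors = FALSE))
}

#' Run the full consensus pipeline
#'
#' One call executes the whole workflow: read every caller's seg file,
#' build the caller-multiplicity consensus, apply the min-caller filter,
#' map genes into multiplicity classes by coverage fraction, run Fisher
#' enrichment per term catalog, score callers and consensus thresholds
#' against a truth profile when one is supplied, and write the TSV tables
#' plus a self-contained `report.html` into the output directory. Outputs
#' are deterministic: re-running on identical inputs reproduces the files
#' byte for byte, for any `threads` setting.
#'
#' @param config A config file path or a `pipeline_config` from
#'   [read_pipeline_config()].
#' @return A `cnv_pipeline_result` (invisibly): list with `callsets`,
#'   `consensus` (filtered), `consensus_full`, `summaries`,
#'   `per_caller_calls`, `venn_counts`, `genes`, `enrichment`, `metrics`
#'   (or NULL), `config`, and the written `paths`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else read_pipeline_config(config)
  callsets <- lapply(cfg$callers, function(cl) {
    read_seg(cl$path, cl$dialect, caller = cl$name, sample = cfg$sample)
  })
  names(callsets) <- vapply(cfg$callers, `[[`, character(1), "name")

  per_caller_calls <- do.call(rbind, lapply(callsets, function(cs) {
    as.data.frame(cs)[, c("chrom", "start", "end", "copy_number",
                          "direction", "caller")]
  }))
  per_caller_calls <- per_caller_calls[order(chrom_rank(per_caller_calls$chrom),
                                             per_caller_calls$start,
                                             per_caller_calls$caller), ]
  rownames(per_caller_calls) <- NULL

  consensus_full <- build_consensus(callsets, min_segment_bp = cfg$min_segment_bp)
  consensus <- filter_min_callers(consensus_full, cfg$min_callers)
  summaries <- do.call(rbind, lapply(callsets[order(names(callsets))],
                                     summarize_caller))
  rownames(summaries) <- NULL

  genes_tab <- NULL
  gene_models <- NULL
  if (!is.null(cfg$genes)) {
    gene_models <- read_gene_bed(cfg$genes)
    genes_tab <- map_genes(consensus, gene_models, coverage = cfg$gene_coverage)
  }

  enrichment <- NULL
  if (length(cfg$catalogs) > 0L) {
    if (is.null(gene_models)) {
      stop("config: term catalogs require a 'genes' BED (the mapping source and default universe)")
    }
    catalogs <- lapply(cfg$catalogs, read_gmt)
    cnv_gene_ids <- unique(genes_tab$gene_id)
    run_one <- function(cat) {
      uni <- if (cfg$universe == "genes") gene_models$gene_id else catalog_genes(cat)
      fisher_enrichment(cnv_gene_ids, cat, uni)
    }
    parts <- if (cfg$threads > 1L && length(catalogs) > 1L) {
      parallel::mclapply(catalogs, run_one, mc.cores = cfg$threads)
    } else {
      lapply(catalogs, run_one)
    }
    enrichment <- do.call(rbind, parts)
    rownames(enrichment) <- NULL
  }

  metrics <- NULL
  if (!is.null(cfg$truth)) {
    truth <- read_seg(cfg$truth, cfg$truth_dialect, caller = "truth",
                      sample = cfg$sample)
    assay <- if (!is.null(cfg$assay)) read_assay_bed(cfg$assay)
             else default_assay_space(callsets, truth)
    metrics <- evaluate_thresholds(callsets, truth, assay,
                                   consensus = consensus_full)
    metrics <- cbind(sample = cfg$sample, metrics)
  }

  bundle <- structure(list(
    callsets = callsets, consensus = consensus, consensus_full = consensus_full,
    summaries = summaries, per_caller_calls = per_caller_calls,
    venn_counts = consensus$venn_counts, genes = genes_tab,
    enrichment = enrichment, metrics = metrics, config = cfg),
    class = "cnv_pipeline_result")
  bundle$paths <- write_tables(bundle, cfg$output_dir)
  report <- file.path(cfg$output_dir, "report.html")
  render_report(bundle, report)
  bundle$paths <- c(bundle$paths, report)
  invisible(bundle)
}

#' @export
print.cnv_pipeline_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("CNV consensus pipeline result: sample '%s'\n", cfg$sample))
  cat(sprintf("  callers (%d): %s\n", length(x$callsets),
              paste(names(x$callsets), collapse = ", ")))
  cat(sprintf("  consensus segments (multiplicity >= %d): %d\n",
              cfg$min_callers, nrow(x$consensus$segments)))
  if (!is.null(x$genes)) {
    cat(sprintf("  gene assignments (coverage >= %.2f): %d\n",
                cfg$gene_coverage, nrow(x$genes)))
  }
  if (!is.null(x$enrichment)) {
    cat(sprintf("  enrichment records: %d (min adjusted p = %s)\n",
                nrow(x$enrichment),
                if (nrow(x$enrichment)) format(min(x$enrichment$p_adjusted), digits = 3)
                else "NA"))
  }
  if (!is.null(x$metrics)) {
    cat("  evaluation vs truth:\n")
    print.data.frame(x$metrics[, c("label", "tpr", "fdr", "precision")],
                     digits = 4)
  }
  cat(sprintf("  outputs: %s\n", cfg$output_dir))
  invisible(x)
}
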