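#' Base-level confusion counts of a call set against a truth profile
#'
#' Scoring is base-level and direction-aware, with two direction slots
#' (gain and loss) per assayed base. Within one slot a base is a true
#' positive when call and truth both cover it in that direction, a false
#' positive when only the call does, a false negative when only the truth
#' does, and a true negative otherwise. A base where the call says gain
#' but the truth says loss therefore counts as both a false positive (in
#' the gain slot) and a false negative (in the loss slot), and
#' `tp + fp + fn + tn` always equals twice the assay-space size in bp.
#' Copy-number magnitude is ignored: only direction is scored.
#'
#' @param called A `cnv_callset`, or a named list with elements `gain` and
#'   `loss` holding interval data frames (chrom, start, end).
#' @param truth A `cnv_callset` holding the truth CNV profile.
#' @param assay_space Interval data frame (chrom, start, end): the region
#'   over which bases are scored. Calls and truth are intersected with it.
#' @return A one-row `cnv_metrics` data frame: `tp_bp`, `fp_bp`, `fn_bp`,
#'   `tn_bp`, `tpr`, `fdr`, `precision` (ratios are `NA` when their
#'   denominator is zero, never 0).
#' @export
confusion_counts <- function(called, truth, assay_space) {
  if (is.null(assay_space) || nrow(assay_space) == 0L) {
    stop("assay_space must be a non-empty interval set")
  }
  assay <- iv_reduce(assay_space)
  assay_bp <- iv_length(assay)
  get_dir <- function(x, d) {
    if (inherits(x, "cnv_callset") || (is.data.frame(x) && "direction" %in% names(x))) {
      iv_reduce(x[x$direction == d, c("chrom", "start", "end"), drop = FALSE])
    } else if (is.list(x)) {
      iv_reduce(x[[d]] %||% iv_empty())
    } else stop("called/truth must be a cnv_callset or a list(gain=, loss=)")
  }
  tp <- fp <- fn <- tn <- 0
  for (d in c("gain", "loss")) {
    cd <- iv_intersect(get_dir(called, d), assay)
    td <- iv_intersect(get_dir(truth, d), assay)
    tp_d <- iv_length(iv_intersect(cd, td))
    fp_d <- iv_length(cd) - tp_d
    fn_d <- iv_length(td) - tp_d
    tp <- tp + tp_d; fp <- fp + fp_d; fn <- fn + fn_d
    tn <- tn + (assay_bp - tp_d - fp_d - fn_d)
  }
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- data.frame(tp_bp = tp, fp_bp = fp, fn_bp = fn, tn_bp = tn,
                    tpr = ratio(tp, tp + fn),
                    fdr = ratio(fp, tp + fp),
                    precision = ratio(tp, tp + fp))
  structure(out, class = c("cnv_metrics", "data.frame"), assay_bp = assay_bp)
}

#' Score every caller and every consensus threshold against a truth profile
#'
#' Produces one metrics row per individual caller and one per consensus
#' min-caller threshold k in 1..N (segments with multiplicity >= k,
#' collapsed to an interval set per direction).
#'
#' @param callsets List of normalized `cnv_callset`s (one per caller).
#' @param truth A `cnv_callset` truth profile for the same sample.
#' @param assay_space Interval data frame defining the scored space.
#' @param consensus Optional precomputed `cnv_consensus` for `callsets`.
#' @return Data frame with a `label` column ("<caller>" or
#'   "consensus>=k") followed by the [confusion_counts()] columns.
#' @export
evaluate_thresholds <- function(callsets, truth, assay_space, consensus = NULL) {
  if (inherits(callsets, "cnv_callset")) callsets <- list(callsets)
  cons <- consensus %||% build_consensus(callsets)
  n <- length(cons$callers)
  rows <- list()
  for (cs in callsets[order(vapply(callsets, callset_caller, character(1)))]) {
    m <- confusion_counts(cs, truth, assay_space)
    rows[[length(rows) + 1L]] <- cbind(label = callset_caller(cs),
                                       as.data.frame(m))
  }
  for (k in seq_len(n)) {
    called <- list(gain = consensus_footprint(cons, k, "gain"),
                   loss = consensus_footprint(cons, k, "loss"))
    m <- confusion_counts(called, truth, assay_space)
    rows[[length(rows) + 1L]] <- cbind(label = sprintf("consensus>=%d", k),
                                       as.data.frame(m))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.cnv_metrics <- function(x, ...) {
  cat(sprintf("Base-level metrics over %s assayed bp (2 direction slots/base):\n",
              format(attr(x, "assay_bp") %||% NA, big.mark = ",")))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Replicated benchmark of single-caller vs integrated calling
#'
#' For each seed, simulates a full study (truth profiles per
#' [truth_spec()], noisy per-caller call sets per the noise profiles),
#' scores every caller and every consensus threshold against the truth,
#' and aggregates the base-level confusion counts over all samples of the
#' seed before deriving TPR/FDR/precision. This is the package's
#' desk-scale mirror of benchmarking integration against individual
#' callers.
#'
#' @param seeds Integer vector of simulation seeds (one replicate each).
#' @param genome A [genome_spec()].
#' @param spec A [truth_spec()].
#' @param profiles List of [noise_profile()]s.
#' @return Data frame: `seed`, `label` ("<caller>" or "consensus>=k"),
#'   aggregated `tp_bp`/`fp_bp`/`fn_bp`/`tn_bp` and derived `tpr`, `fdr`,
#'   `precision`.
#' @export
benchmark_consensus <- function(seeds = 1:20, genome = genome_spec(),
                                spec = truth_spec(),
                                profiles = caller_noise_profiles()) {
  assay <- data.frame(chrom = names(genome), start = 0,
                      end = as.numeric(genome), stringsAsFactors = FALSE)
  rows <- lapply(seeds, function(sd) {
    truth <- simulate_truth(genome, spec, seed = sd)
    acc <- NULL
    for (lab in names(truth)) {
      calls <- simulate_calls(truth[[lab]], profiles, genome, seed = sd)
      tab <- evaluate_thresholds(calls, truth[[lab]], assay)
      bp <- tab[, c("tp_bp", "fp_bp", "fn_bp", "tn_bp")]
      if (is.null(acc)) {
        acc <- cbind(tab["label"], bp)
      } else {
        stopifnot(identical(acc$label, tab$label))
        acc[, -1L] <- acc[, -1L] + bp
      }
    }
    ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
    acc$tpr <- ratio(acc$tp_bp, acc$tp_bp + acc$fn_bp)
    acc$fdr <- ratio(acc$fp_bp, acc$tp_bp + acc$fp_bp)
    acc$precision <- ratio(acc$tp_bp, acc$tp_bp + acc$fp_bp)
    cbind(seed = sd, acc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
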