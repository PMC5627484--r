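#' Construct a set of CNV calls for one caller and one sample
#'
#' A call is a genomic interval (0-based half-open coordinates) with an
#' integer copy number. Direction is derived from the diploid baseline of 2:
#' copy number above 2 is a gain, below 2 a loss. Copy number 2 is not a CNV
#' and is rejected here (file readers skip such rows with a warning instead).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors; 0-based half-open, `start < end`.
#' @param copy_number Integer vector of copy numbers (>= 0, never 2).
#' @param caller Caller identifier (length-1 character).
#' @param sample Sample identifier (length-1 character).
#' @return A `cnv_callset`: a data frame with columns `chrom`, `start`,
#'   `end`, `copy_number`, `direction` ("gain"/"loss"), `caller`, `sample`,
#'   sorted by chromosome (natural order) then start.
#' @examples
#' cnv_calls("chr1", 100, 300, 5, caller = "toolA", sample = "s1")
#' @export
cnv_calls <- function(chrom, start, end, copy_number,
                      caller = "caller", sample = "sample") {
  stopifnot(is.character(caller), length(caller) == 1L,
            is.character(sample), length(sample) == 1L)
  n <- length(chrom)
  if (length(start) != n || length(end) != n || length(copy_number) != n) {
    stop("chrom, start, end and copy_number must have equal length")
  }
  start <- as.numeric(start); end <- as.numeric(end)
  copy_number <- as.numeric(copy_number)
  if (n > 0L) {
    if (any(!is.finite(start)) || any(!is.finite(end)) || any(start < 0)) {
      stop("interval coordinates must be finite and start >= 0")
    }
    if (any(start >= end)) {
      bad <- which(start >= end)[1L]
      stop(sprintf("empty or inverted interval at %s:%s-%s (start must be < end)",
                   chrom[bad], format(start[bad], scientific = FALSE),
                   format(end[bad], scientific = FALSE)))
    }
    if (any(copy_number < 0) || any(copy_number != round(copy_number))) {
      stop("copy_number must be a non-negative integer")
    }
    if (any(copy_number == 2)) {
      stop("copy number 2 is the diploid baseline, not a CNV call")
    }
  }
  df <- data.frame(
    chrom = as.character(chrom), start = start, end = end,
    copy_number = copy_number,
    direction = ifelse(copy_number > 2, "gain", "loss"),
    caller = rep(caller, n), sample = rep(sample, n),
    stringsAsFactors = FALSE
  )
  df <- sort_intervals(df)
  rownames(df) <- NULL
  structure(df, class = c("cnv_callset", "data.frame"),
            caller = caller, sample = sample, normalized = FALSE)
}

callset_caller <- function(x) attr(x, "caller") %||% unique(x$caller)
callset_sample <- function(x) attr(x, "sample") %||% unique(x$sample)

#' Normalize a call set
#'
#' Sorts calls and merges overlapping or bookended intervals of the same
#' direction on the same chromosome into a single call. The merged copy
#' number is the extreme one: the maximum over a run of gains, the minimum
#' over a run of losses, so the strongest event is preserved. Overlapping
#' calls of opposite direction within one caller are malformed input and
#' raise an error naming the loci.
#'
#' @param calls A `cnv_callset` (all calls share one caller and sample).
#' @return A normalized `cnv_callset`.
#' @examples
#' x <- cnv_calls(c("chr1", "chr1"), c(100, 150), c(200, 300), c(3, 5))
#' normalize_callset(x)
#' @export
normalize_callset <- function(calls) {
  if (!inherits(calls, "cnv_callset")) {
    stop("normalize_callset() expects a cnv_callset; see cnv_calls()")
  }
  caller <- callset_caller(calls)
  sample <- callset_sample(calls)
  if (length(caller) != 1L || length(sample) != 1L) {
    stop("all calls must share one caller and one sample identifier")
  }
  if (nrow(calls) == 0L) {
    out <- calls
    attr(out, "normalized") <- TRUE
    return(out)
  }
  merged <- lapply(c("gain", "loss"), function(d) {
    sub <- calls[calls$direction == d, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    gr <- iv_to_gr(sub)
    red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
    cn <- vapply(S4Vectors::mcols(red)$revmap, function(idx) {
      if (d == "gain") max(sub$copy_number[idx]) else min(sub$copy_number[idx])
    }, numeric(1))
    cbind(gr_to_iv(red), copy_number = cn)
  })
  gain <- merged[[1L]]; loss <- merged[[2L]]
  if (!is.null(gain) && !is.null(loss)) {
    g <- align_gr(iv_to_gr(gain), iv_to_gr(loss))
    hits <- GenomicRanges::findOverlaps(g[[1L]], g[[2L]])
    if (length(hits) > 0L) {
      i <- S4Vectors::queryHits(hits)[1L]
      j <- S4Vectors::subjectHits(hits)[1L]
      stop(sprintf(
        "caller '%s': overlapping gain and loss calls at %s:%s-%s vs %s:%s-%s",
        caller,
        gain$chrom[i], format(gain$start[i], scientific = FALSE),
        format(gain$end[i], scientific = FALSE),
        loss$chrom[j], format(loss$start[j], scientific = FALSE),
        format(loss$end[j], scientific = FALSE)))
    }
  }
  parts <- Filter(Negate(is.null), list(gain, loss))
  df <- do.call(rbind, parts)
  out <- cnv_calls(df$chrom, df$start, df$end, df$copy_number,
                   caller = caller, sample = sample)
  attr(out, "normalized") <- TRUE
  out
}

#' Base-pair overlap between two genomic intervals
#'
#' @param a,b Lists or one-row data frames with elements `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return Integer overlap length in bp; 0 when the chromosomes differ.
#'   Symmetric in its arguments.
#' @examples
#' interval_overlap(list(chrom = "chr1", start = 0, end = 10),
#'                  list(chrom = "chr1", start = 5, end = 8))
#' @export
interval_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

#' @export
print.cnv_callset <- function(x, ...) {
  cat(sprintf("CNV call set: caller '%s', sample '%s', %d call(s)%s\n",
              callset_caller(x), callset_sample(x), nrow(x),
              if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

# Footprint (merged interval set) of one direction of a call set.
callset_footprint <- function(calls, direction) {
  iv_reduce(calls[calls$direction == direction, c("chrom", "start", "end"),
                  drop = FALSE])
}
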