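#' Multiplicity class name for a supporting-caller count
#'
#' @param k Integer vector of caller multiplicities.
#' @return Character vector: 1 is "unique", 2 "double", 3 "triple",
#'   4 "tetrad", higher counts "k-caller".
#' @export
multiplicity_class <- function(k) {
  nm <- c("unique", "double", "triple", "tetrad")
  ifelse(k >= 1 & k <= 4, nm[pmin(pmax(k, 1), 4)], paste0(k, "-caller"))
}

# Merge adjacent rows of a sorted segment frame when `key` matches and the
# intervals are bookended on the same chromosome.
merge_adjacent <- function(df, key) {
  if (nrow(df) <= 1L) return(df)
  run <- cumsum(c(TRUE, !(df$chrom[-1L] == df$chrom[-nrow(df)] &
                          df$start[-1L] == df$end[-nrow(df)] &
                          key[-1L] == key[-nrow(df)])))
  out <- df[!duplicated(run), , drop = FALSE]
  out$end <- as.numeric(tapply(df$end, run, max)[as.character(unique(run))])
  rownames(out) <- NULL
  out
}

#' Build caller-multiplicity consensus segments
#'
#' For each direction (gain and loss independently), the union of all
#' callers' intervals is partitioned at every distinct call breakpoint;
#' each atomic piece is labelled with exactly the set of callers whose
#' calls cover it, and maximal runs of pieces with identical direction,
#' caller set and per-caller copy numbers are merged back. Segments with
#' one supporting caller are "unique", two "double", three "triple", four
#' "tetrad". Gains and losses never co-support a segment: sharing is
#' direction-stratified.
#'
#' @param callsets List of normalized `cnv_callset`s for one sample, with
#'   distinct caller names.
#' @param min_segment_bp Minimum reported segment length in bp (default 1,
#'   i.e. even 1-bp shared slivers are kept).
#' @return A `cnv_consensus`: list with `segments` (data frame: chrom,
#'   start, end, direction, multiplicity, class, callers, per_caller_cn),
#'   `callers` (sorted caller names), `sample`, and `venn_counts` (data
#'   frame per exact caller subset and direction: region count and bp).
#' @export
build_consensus <- function(callsets, min_segment_bp = 1) {
  if (inherits(callsets, "cnv_callset")) callsets <- list(callsets)
  if (length(callsets) < 1L) stop("need at least one call set")
  for (cs in callsets) {
    if (!inherits(cs, "cnv_callset")) stop("callsets must be cnv_callset objects")
    if (!isTRUE(attr(cs, "normalized"))) stop("callsets must be normalized (see normalize_callset())")
  }
  callers <- vapply(callsets, callset_caller, character(1))
  if (anyDuplicated(callers)) {
    stop(sprintf("duplicate caller name(s): %s",
                 paste(unique(callers[duplicated(callers)]), collapse = ", ")))
  }
  samples <- unique(vapply(callsets, callset_sample, character(1)))
  if (length(samples) > 1L) {
    stop(sprintf("call sets mix samples: %s", paste(samples, collapse = ", ")))
  }
  # caller input order must not matter: fix a canonical order
  ord <- order(callers)
  callsets <- callsets[ord]
  callers <- callers[ord]

  seg_list <- lapply(c("gain", "loss"), function(d) {
    pool <- do.call(rbind, lapply(callsets, function(cs) {
      sub <- as.data.frame(cs)[cs$direction == d,
                               c("chrom", "start", "end", "copy_number", "caller"),
                               drop = FALSE]
      sub
    }))
    if (is.null(pool) || nrow(pool) == 0L) return(NULL)
    gr <- iv_to_gr(pool)
    pieces <- GenomicRanges::disjoin(gr, with.revmap = TRUE)
    rev <- S4Vectors::mcols(pieces)$revmap
    lab <- vapply(rev, function(idx) {
      o <- idx[order(pool$caller[idx])]
      paste(paste0(pool$caller[o], "=",
                   format(pool$copy_number[o], scientific = FALSE, trim = TRUE)),
            collapse = ",")
    }, character(1))
    who <- vapply(rev, function(idx) paste(sort(pool$caller[idx]), collapse = ","),
                  character(1))
    mult <- vapply(rev, length, integer(1))
    df <- gr_to_iv_keep(pieces)
    df$direction <- d
    df$multiplicity <- mult
    df$callers <- who
    df$per_caller_cn <- lab
    df <- df[order(chrom_rank(df$chrom), df$start), , drop = FALSE]
    merge_adjacent(df, paste(df$direction, df$per_caller_cn))
  })
  segments <- do.call(rbind, Filter(Negate(is.null), seg_list))
  if (is.null(segments)) {
    segments <- data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0), direction = character(0),
                           multiplicity = integer(0), callers = character(0),
                           per_caller_cn = character(0), stringsAsFactors = FALSE)
  }
  segments <- segments[segments$end - segments$start >= min_segment_bp, , drop = FALSE]
  segments <- segments[order(chrom_rank(segments$chrom), segments$start,
                             segments$direction), , drop = FALSE]
  segments$class <- multiplicity_class(segments$multiplicity)
  segments <- segments[, c("chrom", "start", "end", "direction",
                           "multiplicity", "class", "callers", "per_caller_cn")]
  rownames(segments) <- NULL
  res <- structure(list(segments = segments, callers = callers,
                        sample = samples %||% "sample",
                        min_segment_bp = min_segment_bp),
                   class = "cnv_consensus")
  res$venn_counts <- venn_counts(res)
  res
}

# gr_to_iv without re-sorting (disjoin output order is kept per direction).
gr_to_iv_keep <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = as.numeric(GenomicRanges::start(gr)) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             stringsAsFactors = FALSE)
}

# Per exact caller subset and direction: number of maximal regions (adjacent
# same-subset segments merged regardless of copy number) and total bp.
venn_counts <- function(result) {
  seg <- result$segments
  if (nrow(seg) == 0L) {
    return(data.frame(direction = character(0), callers = character(0),
                      n_regions = integer(0), bp = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(seg, paste(seg$direction, seg$callers, sep = "\r")),
                function(s) {
    s <- s[order(chrom_rank(s$chrom), s$start), , drop = FALSE]
    m <- merge_adjacent(s, s$callers)
    data.frame(direction = s$direction[1L], callers = s$callers[1L],
               n_regions = nrow(m), bp = sum(s$end - s$start),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$direction, -out$bp, out$callers), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only consensus segments supported by at least `min_callers` callers
#'
#' Venn counts are recomputed on the retained segments.
#'
#' @param result A `cnv_consensus`.
#' @param min_callers Integer >= 1.
#' @return A filtered `cnv_consensus`.
#' @export
filter_min_callers <- function(result, min_callers) {
  stopifnot(inherits(result, "cnv_consensus"),
            length(min_callers) == 1L, min_callers >= 1)
  out <- result
  out$segments <- result$segments[result$segments$multiplicity >= min_callers, ,
                                  drop = FALSE]
  rownames(out$segments) <- NULL
  out$min_callers <- min_callers
  out$venn_counts <- venn_counts(out)
  out
}

#' Merged regions of exactly-k caller support
#'
#' Returns, per direction, the union of consensus segments with
#' multiplicity exactly `k`, merging bookended segments (regardless of
#' which callers support them).
#'
#' @param result A `cnv_consensus`.
#' @param k Multiplicity (1 <= k; values above the caller count give an
#'   empty result).
#' @param direction Optional `"gain"` or `"loss"` to restrict the output.
#' @return Data frame: chrom, start, end, direction.
#' @export
class_regions <- function(result, k, direction = NULL) {
  stopifnot(inherits(result, "cnv_consensus"), length(k) == 1L, k >= 1)
  seg <- result$segments[result$segments$multiplicity == k, , drop = FALSE]
  if (!is.null(direction)) seg <- seg[seg$direction == direction, , drop = FALSE]
  if (nrow(seg) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(seg, seg$direction), function(s) {
    s <- s[order(chrom_rank(s$chrom), s$start), , drop = FALSE]
    m <- merge_adjacent(s, rep("x", nrow(s)))
    m[, c("chrom", "start", "end", "direction")]
  })
  out <- do.call(rbind, out)
  out <- out[order(chrom_rank(out$chrom), out$start, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merged footprint of segments with at-least-k caller support
#'
#' @param result A `cnv_consensus`.
#' @param k Minimum multiplicity.
#' @param direction `"gain"` or `"loss"`.
#' @return Data frame of merged intervals: chrom, start, end.
#' @export
consensus_footprint <- function(result, k, direction) {
  seg <- result$segments
  seg <- seg[seg$multiplicity >= k & seg$direction == direction, , drop = FALSE]
  iv_reduce(seg[, c("chrom", "start", "end"), drop = FALSE])
}

#' @export
print.cnv_consensus <- function(x, ...) {
  cat(sprintf("CNV consensus: sample '%s', %d caller(s) [%s], %d segment(s)\n",
              x$sample, length(x$callers), paste(x$callers, collapse = ", "),
              nrow(x$segments)))
  if (nrow(x$segments) > 0L) {
    tab <- tapply(x$segments$end - x$segments$start,
                  list(x$segments$class, x$segments$direction), sum)
    cat("bp per multiplicity class:\n")
    print(tab)
  }
  invisible(x)
}

#' @export
summary.cnv_consensus <- function(object, ...) {
  seg <- object$segments
  if (nrow(seg) == 0L) {
    return(data.frame(direction = character(0), multiplicity = integer(0),
                      class = character(0), n_segments = integer(0),
                      bp = numeric(0)))
  }
  agg <- stats::aggregate(cbind(bp = seg$end - seg$start),
                          by = list(direction = seg$direction,
                                    multiplicity = seg$multiplicity),
                          FUN = sum)
  cnt <- stats::aggregate(cbind(n_segments = seg$start),
                          by = list(direction = seg$direction,
                                    multiplicity = seg$multiplicity),
                          FUN = length)
  out <- merge(cnt, agg)
  out$class <- multiplicity_class(out$multiplicity)
  out <- out[order(out$direction, out$multiplicity),
             c("direction", "multiplicity", "class", "n_segments", "bp")]
  rownames(out) <- NULL
  out
}
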