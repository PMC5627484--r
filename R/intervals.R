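# Internal interval-set algebra on 0-based half-open (BED-style)
# coordinates. The sets handled here are small (tens of intervals), so
# plain sort-and-sweep in base R is used; GenomicRanges enters only where
# its machinery earns its keep (disjoin with revmap in the consensus
# partition, findOverlaps in normalization and gene mapping) via the
# converters below (+1 shift to its 1-based closed convention).

iv_empty <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             stringsAsFactors = FALSE)
}

iv_to_gr <- function(df) {
  if (is.null(df) || nrow(df) == 0L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = as.integer(df$start) + 1L,
                              end = as.integer(df$end))
  )
}

gr_to_iv <- function(gr) {
  if (length(gr) == 0L) return(iv_empty())
  sort_intervals(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.numeric(GenomicRanges::start(gr)) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    stringsAsFactors = FALSE
  ))
}

# Put two GRanges on a shared seqlevels set so cross-object operations do
# not warn about disjoint sequence universes.
align_gr <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

# Union of an interval set, merging overlapping and bookended pieces.
iv_reduce <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(iv_empty())
  df <- df[order(chrom_rank(df$chrom), df$start, df$end), , drop = FALSE]
  # a new run starts where the interval begins beyond the running maximum
  # end of its chromosome block
  n <- nrow(df)
  new_chrom <- c(TRUE, df$chrom[-1L] != df$chrom[-n])
  run_end <- df$end
  run <- integer(n)
  run[1L] <- 1L
  if (n > 1L) {
    for (i in 2:n) {
      if (new_chrom[i] || df$start[i] > run_end[i - 1L]) {
        run[i] <- run[i - 1L] + 1L
        run_end[i] <- df$end[i]
      } else {
        run[i] <- run[i - 1L]
        run_end[i] <- max(run_end[i - 1L], df$end[i])
      }
    }
  }
  keep <- !duplicated(run)
  ends <- tapply(run_end, run, max)[as.character(run[keep])]
  out <- data.frame(chrom = df$chrom[keep], start = df$start[keep],
                    end = as.numeric(ends), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Intersection of two interval sets (two-pointer sweep over reduced sets).
iv_intersect <- function(a, b) {
  a <- iv_reduce(a); b <- iv_reduce(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv_empty())
  parts <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    x <- a[a$chrom == ch, , drop = FALSE]
    y <- b[b$chrom == ch, , drop = FALSE]
    i <- 1L; j <- 1L
    ss <- numeric(0); ee <- numeric(0)
    while (i <= nrow(x) && j <= nrow(y)) {
      s <- max(x$start[i], y$start[j])
      e <- min(x$end[i], y$end[j])
      if (e > s) { ss <- c(ss, s); ee <- c(ee, e) }
      if (x$end[i] <= y$end[j]) i <- i + 1L else j <- j + 1L
    }
    if (length(ss) > 0L) {
      parts[[length(parts) + 1L]] <- data.frame(chrom = ch, start = ss,
                                                end = ee,
                                                stringsAsFactors = FALSE)
    }
  }
  if (length(parts) == 0L) return(iv_empty())
  out <- do.call(rbind, parts)
  out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
}

iv_length <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(0)
  sum(df$end - df$start)
}

# Total bp of the union of a overlapped by the union of b.
iv_overlap_length <- function(a, b) {
  iv_length(iv_intersect(a, b))
}

# TRUE when interval (chrom, s, e) overlaps any interval in df by >= 1 bp.
iv_hits_any <- function(df, chrom, s, e) {
  if (is.null(df) || nrow(df) == 0L) return(FALSE)
  any(df$chrom == chrom & df$start < e & df$end > s)
}
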