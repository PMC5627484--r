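# Independent brute-force oracles used across the suite. They work base by
# base on small coordinate ranges and share no code with the package's
# interval machinery.

chrom_rank_key <- function(chrom) cnvconsensus:::chrom_rank(chrom)

# Size in bp of the per-base union of a set of raw intervals.
oracle_union_bp <- function(df) {
  if (nrow(df) == 0L) return(0)
  total <- 0
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    covered <- logical(max(sub$end))
    for (i in seq_len(nrow(sub))) covered[(sub$start[i] + 1):sub$end[i]] <- TRUE
    total <- total + sum(covered)
  }
  total
}

# Per-base consensus: label every base with its covering callers and their
# copy numbers, recompress into maximal identical runs. Encodes (caller,
# cn) per base as a base-64 digit per caller, so it requires cn <= 62.
oracle_consensus_segments <- function(callsets) {
  callers <- sort(vapply(callsets, function(x) attr(x, "caller"), character(1)))
  rows <- list()
  for (d in c("gain", "loss")) {
    pool <- do.call(rbind, lapply(callsets, function(cs) {
      as.data.frame(cs)[cs$direction == d, , drop = FALSE]
    }))
    if (is.null(pool) || nrow(pool) == 0L) next
    for (ch in unique(pool$chrom)) {
      sub <- pool[pool$chrom == ch, , drop = FALSE]
      key <- numeric(max(sub$end))
      for (i in seq_len(nrow(sub))) {
        ci <- match(sub$caller[i], callers)
        idx <- (sub$start[i] + 1):sub$end[i]
        key[idx] <- key[idx] + (sub$copy_number[i] + 1) * 64^(ci - 1)
      }
      r <- rle(key)
      pos <- cumsum(c(0, r$lengths))
      for (j in seq_along(r$values)) {
        v <- r$values[j]
        if (v == 0) next
        who <- character(0); cns <- numeric(0)
        rem <- v
        for (ci in seq_along(callers)) {
          digit <- rem %% 64
          rem <- rem %/% 64
          if (digit > 0) { who <- c(who, callers[ci]); cns <- c(cns, digit - 1) }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = pos[j], end = pos[j + 1L], direction = d,
          multiplicity = length(who), callers = paste(who, collapse = ","),
          per_caller_cn = paste(paste0(who, "=", cns), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      direction = character(0), multiplicity = integer(0),
                      callers = character(0), per_caller_cn = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(chrom_rank_key(out$chrom), out$start, out$direction), ]
  rownames(out) <- NULL
  out
}

# Per-base direction-aware confusion counts with two direction slots per
# assayed base.
oracle_confusion <- function(called, truth, assay) {
  get_dir <- function(x, d) {
    if (is.data.frame(x) && "direction" %in% names(x)) {
      x[x$direction == d, c("chrom", "start", "end"), drop = FALSE]
    } else x[[d]]
  }
  tp <- fp <- fn <- tn <- 0
  for (ch in unique(assay$chrom)) {
    L <- max(assay$end[assay$chrom == ch])
    in_assay <- logical(L)
    sub <- assay[assay$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) in_assay[(sub$start[i] + 1):sub$end[i]] <- TRUE
    for (d in c("gain", "loss")) {
      mark <- function(df) {
        v <- logical(L)
        df <- df[df$chrom == ch & df$start < L, , drop = FALSE]
        for (i in seq_len(nrow(df))) {
          v[(df$start[i] + 1):min(L, df$end[i])] <- TRUE
        }
        v & in_assay
      }
      cv <- mark(get_dir(called, d))
      tv <- mark(get_dir(truth, d))
      tp <- tp + sum(cv & tv)
      fp <- fp + sum(cv & !tv)
      fn <- fn + sum(!cv & tv)
      tn <- tn + sum(in_assay & !cv & !tv)
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Exact one-sided hypergeometric tail P(X >= a) by direct enumeration of
# the PMF via log-binomials (independent of phyper/dhyper).
oracle_hyper_tail <- function(a, b, c, d) {
  K <- a + c; n <- a + b; N <- a + b + c + d
  ks <- seq(max(0, a), min(K, n))
  if (length(ks) == 0L) return(if (a <= 0) 1 else 0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Random normalized call sets: <= 4 callers, <= max_calls calls each,
# coordinates < max_coord, opposite-direction overlaps within a caller
# discarded at generation time.
random_callsets <- function(seed, n_callers = NULL, max_calls = 30,
                            max_coord = 1e5, chroms = c("chr1", "chr2")) {
  with_seed(seed, {
    if (is.null(n_callers)) n_callers <- sample(1:4, 1)
    lapply(paste0("caller", seq_len(n_callers)), function(cl) {
      n <- sample(0:max_calls, 1)
      acc <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), cn = numeric(0),
                        direction = character(0), stringsAsFactors = FALSE)
      for (i in seq_len(n)) {
        s <- sample(0:(max_coord - 2), 1)
        e <- min(max_coord, s + sample(1:ceiling(max_coord / 10), 1))
        ch <- sample(chroms, 1)
        cn <- sample(c(0, 1, 3:8), 1)
        dir <- if (cn > 2) "gain" else "loss"
        opp <- acc[acc$chrom == ch & acc$direction != dir, , drop = FALSE]
        if (nrow(opp) > 0L && any(pmin(opp$end, e) > pmax(opp$start, s))) next
        acc <- rbind(acc, data.frame(chrom = ch, start = s, end = e, cn = cn,
                                     direction = dir, stringsAsFactors = FALSE))
      }
      normalize_callset(cnv_calls(acc$chrom, acc$start, acc$end, acc$cn,
                                  caller = cl, sample = "s1"))
    })
  })
}

# Strip the derived class column for comparison against the oracle.
segments_core <- function(cons) {
  seg <- cons$segments[, c("chrom", "start", "end", "direction",
                           "multiplicity", "callers", "per_caller_cn")]
  seg <- seg[order(chrom_rank_key(seg$chrom), seg$start, seg$direction), ]
  rownames(seg) <- NULL
  seg
}
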