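#' Run code with a temporary RNG seed
#'
#' Evaluates `code` after `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded helpers never disturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a stream seed from a global seed and a stable label
#'
#' Sub-streams (per sample, per caller) are keyed by label, not by
#' generation order, so adding a caller or sample never changes the draws
#' of the others. The result is always a valid 32-bit seed.
#'
#' @param seed Integer global seed.
#' @param label Character scalar naming the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label), length(label) == 1L)
  h <- 0
  for (cp in utf8ToInt(label)) h <- (h * 131 + cp) %% 1000000007
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483646)
}

# Natural chromosome ordering: chr1 < chr2 < ... < chr10 < chrX < chrY < chrM,
# then anything else alphabetically. Returns a numeric sort key.
chrom_rank <- function(chrom) {
  base <- sub("^chr", "", chrom, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(base))
  rank <- rep(NA_real_, length(chrom))
  rank[!is.na(num)] <- num[!is.na(num)]
  rank[toupper(base) == "X"] <- 1e6
  rank[toupper(base) == "Y"] <- 1e6 + 1
  rank[toupper(base) %in% c("M", "MT")] <- 1e6 + 2
  left <- is.na(rank)
  if (any(left)) {
    rank[left] <- 2e6 + match(base[left], sort(unique(base[left])))
  }
  rank
}

# Order rows of an interval data.frame by (chrom natural order, start, end).
sort_intervals <- function(df, extra = NULL) {
  if (nrow(df) == 0L) return(df)
  ord <- order(chrom_rank(df$chrom), df$start, df$end)
  df[ord, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
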