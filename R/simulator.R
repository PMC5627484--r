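#' Genome specification for simulation
#'
#' @param lengths Named numeric vector of chromosome lengths in bp.
#'   Default: three 60 Mb chromosomes, ample room for the default truth
#'   CNV sizes (0.5-4.5 Mb) plus 1 Mb gaps.
#' @return A `genome_spec` (named numeric vector).
#' @export
genome_spec <- function(lengths = c(chr1 = 6e7, chr2 = 6e7, chr3 = 6e7)) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths)))) {
    stop("chromosome lengths must be named")
  }
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  structure(as.numeric(lengths), names = names(lengths), class = "genome_spec")
}

#' Truth-profile specification
#'
#' Defaults mirror the benchmark design this package emulates: 13 samples,
#' each carrying 10 CNV events with copy numbers drawn uniformly from
#' 1..20 excluding the diploid 2 and sizes uniform between 500 kb and
#' 4.5 Mb, placed without overlap and with at least 1 Mb between events on
#' a chromosome.
#'
#' @param n_samples Number of samples (default 13).
#' @param cnvs_per_sample CNV events per sample (default 10).
#' @param copy_number_range Integer vector of permitted copy numbers
#'   (default `c(1, 3:20)`; must exclude 2).
#' @param size_range_bp Length-2 numeric: min and max event size (default
#'   `c(5e5, 4.5e6)`).
#' @param min_gap_bp Minimum gap between events on one chromosome
#'   (default 1 Mb).
#' @return A `truth_spec` list.
#' @export
truth_spec <- function(n_samples = 13L, cnvs_per_sample = 10L,
                       copy_number_range = c(1L, 3:20),
                       size_range_bp = c(5e5, 4.5e6), min_gap_bp = 1e6) {
  if (2 %in% copy_number_range) stop("copy_number_range must exclude the diploid 2")
  if (length(size_range_bp) != 2L || size_range_bp[1L] > size_range_bp[2L] ||
      size_range_bp[1L] <= 0) {
    stop("size_range_bp must be c(min, max) with 0 < min <= max")
  }
  structure(list(n_samples = as.integer(n_samples),
                 cnvs_per_sample = as.integer(cnvs_per_sample),
                 copy_number_range = as.integer(copy_number_range),
                 size_range_bp = as.numeric(size_range_bp),
                 min_gap_bp = as.numeric(min_gap_bp)),
            class = "truth_spec")
}

#' Simulate truth CNV profiles
#'
#' Event sizes are uniform over the spec's size range, copy numbers
#' uniform over its copy-number range, placements uniform over the genome
#' subject to non-overlap and the minimum gap. Fully reproducible: every
#' sample has its own RNG stream derived from the seed and the sample
#' label, so results do not depend on sample order.
#'
#' @param genome A [genome_spec()].
#' @param spec A [truth_spec()].
#' @param seed Integer seed.
#' @return Named list of `cnv_callset`s (caller `"truth"`), one per sample
#'   (`sample01`, `sample02`, ...).
#' @export
simulate_truth <- function(genome = genome_spec(), spec = truth_spec(), seed = 1L) {
  if (max(spec$size_range_bp) >= max(genome)) {
    stop("largest permitted CNV does not fit on any chromosome; use a larger genome")
  }
  labels <- sprintf("sample%02d", seq_len(spec$n_samples))
  profiles <- lapply(labels, function(lab) {
    with_seed(derive_seed(seed, paste0("truth:", lab)), {
      place_sample(genome, spec, lab)
    })
  })
  names(profiles) <- labels
  profiles
}

# Rejection-sample one sample's events. Restarts the whole sample when a
# placement gets stuck; errors out after bounded retries.
place_sample <- function(genome, spec, sample_label) {
  n <- spec$cnvs_per_sample
  if (n == 0L) {
    return(normalize_callset(cnv_calls(character(0), numeric(0), numeric(0),
                                       numeric(0), "truth", sample_label)))
  }
  chroms <- names(genome)
  for (attempt in seq_len(25L)) {
    sizes <- round(stats::runif(n, spec$size_range_bp[1L], spec$size_range_bp[2L]))
    cns <- sample(spec$copy_number_range, n, replace = TRUE)
    placed <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0), stringsAsFactors = FALSE)
    ok <- TRUE
    for (i in seq_len(n)) {
      hit <- FALSE
      for (try in seq_len(200L)) {
        chr <- sample(chroms, 1L, prob = as.numeric(genome))
        if (genome[[chr]] <= sizes[i]) next
        s <- floor(stats::runif(1L, 0, genome[[chr]] - sizes[i]))
        e <- s + sizes[i]
        same <- placed[placed$chrom == chr, , drop = FALSE]
        if (nrow(same) == 0L ||
            all(s >= same$end + spec$min_gap_bp | e <= same$start - spec$min_gap_bp)) {
          placed <- rbind(placed, data.frame(chrom = chr, start = s, end = e,
                                             stringsAsFactors = FALSE))
          hit <- TRUE
          break
        }
      }
      if (!hit) { ok <- FALSE; break }
    }
    if (ok) {
      return(normalize_callset(cnv_calls(placed$chrom, placed$start, placed$end,
                                         cns, "truth", sample_label)))
    }
  }
  stop("infeasible truth placement after bounded retries; use a larger genome or fewer/smaller CNVs")
}

#' Construct a caller noise profile
#'
#' Describes how a simulated caller distorts the truth: a size-dependent
#' detection probability, Gaussian breakpoint jitter, a Poisson
#' false-positive process with log-uniform event sizes, and a chance of
#' mis-reporting the copy number (never across the gain/loss boundary).
#'
#' @param name Caller name.
#' @param detection_prob Function of event size (bp) returning a
#'   probability in `[0, 1]`.
#' @param jitter_sd_bp SD of the Gaussian start/end jitter (bp, >= 0).
#' @param fp_rate_per_mb Expected false-positive events per Mb of genome.
#' @param fp_size_range_bp Length-2 numeric: false-positive sizes are
#'   log-uniform over this range.
#' @param cn_error_prob Probability a detected event's copy number is
#'   perturbed (direction-preserving).
#' @return A `caller_noise_profile`.
#' @export
noise_profile <- function(name, detection_prob, jitter_sd_bp = 1e4,
                          fp_rate_per_mb = 0.05, fp_size_range_bp = c(1e4, 3e5),
                          cn_error_prob = 0.1) {
  stopifnot(is.function(detection_prob), jitter_sd_bp >= 0,
            fp_rate_per_mb >= 0, cn_error_prob >= 0, cn_error_prob <= 1,
            length(fp_size_range_bp) == 2L, all(fp_size_range_bp > 0))
  structure(list(name = name, detection_prob = detection_prob,
                 jitter_sd_bp = jitter_sd_bp, fp_rate_per_mb = fp_rate_per_mb,
                 fp_size_range_bp = as.numeric(fp_size_range_bp),
                 cn_error_prob = cn_error_prob),
            class = "caller_noise_profile")
}

#' Default caller noise profiles
#'
#' Four profiles encoding the size preferences reported for common exome
#' CNV callers: `excavator_like` favours large events (monotone increasing
#' detection probability), `adtex_like` mid-size events (unimodal around
#' 2.5 Mb), while `freec_like` and `exomecnv_like` favour smaller events
#' (decreasing). Numeric values are this package's defaults, chosen to
#' satisfy those qualitative biases at the default truth sizes.
#'
#' @return Named list of `caller_noise_profile`s.
#' @export
caller_noise_profiles <- function() {
  clamp <- function(p) pmin(1, pmax(0.02, p))
  list(
    excavator_like = noise_profile(
      "excavator_like",
      function(size) clamp(0.40 + 0.55 * stats::plogis((size - 1.5e6) / 8e5)),
      jitter_sd_bp = 2e4, fp_rate_per_mb = 0.03,
      fp_size_range_bp = c(5e4, 1e6), cn_error_prob = 0.10),
    adtex_like = noise_profile(
      "adtex_like",
      function(size) clamp(0.10 + 0.85 * exp(-((size - 2.5e6) / 1.5e6)^2)),
      jitter_sd_bp = 1.5e4, fp_rate_per_mb = 0.04,
      fp_size_range_bp = c(3e4, 5e5), cn_error_prob = 0.10),
    freec_like = noise_profile(
      "freec_like",
      function(size) clamp(0.95 - 0.10 * size / 1e6),
      jitter_sd_bp = 1e4, fp_rate_per_mb = 0.06,
      fp_size_range_bp = c(1e4, 3e5), cn_error_prob = 0.15),
    exomecnv_like = noise_profile(
      "exomecnv_like",
      function(size) clamp(0.05 + 0.90 * exp(-size / 4e6)),
      jitter_sd_bp = 1e4, fp_rate_per_mb = 0.08,
      fp_size_range_bp = c(1e4, 2e5), cn_error_prob = 0.15)
  )
}

#' Simulate noisy per-caller call sets from a truth profile
#'
#' Each truth event is detected with the profile's size-dependent
#' probability; detected events get independent Gaussian start/end jitter
#' (clamped to stay on-chromosome and positive-length) and, with the
#' profile's error probability, a perturbed copy number that never crosses
#' the gain/loss boundary. False positives arrive as a Poisson process
#' over the genome with log-uniform sizes, placed so they overlap neither
#' the truth footprint nor the caller's own calls. Per-caller RNG streams
#' are derived from the seed and the caller/sample labels, so adding a
#' caller leaves the others' draws unchanged.
#'
#' @param truth A truth `cnv_callset` (one sample).
#' @param profiles List of [noise_profile()]s; default
#'   [caller_noise_profiles()].
#' @param genome The [genome_spec()] the truth was simulated on.
#' @param seed Integer seed.
#' @return Named list of normalized `cnv_callset`s, one per profile.
#' @export
simulate_calls <- function(truth, profiles = caller_noise_profiles(),
                           genome = genome_spec(), seed = 1L) {
  stopifnot(inherits(truth, "cnv_callset"))
  if (length(profiles) == 0L) stop("profiles must be non-empty")
  sample_label <- callset_sample(truth)
  truth_fp <- iv_reduce(as.data.frame(truth)[, c("chrom", "start", "end")])
  out <- lapply(profiles, function(pr) {
    with_seed(derive_seed(seed, paste0("calls:", pr$name, ":", sample_label)), {
      simulate_one_caller(truth, truth_fp, pr, genome, sample_label)
    })
  })
  names(out) <- vapply(profiles, `[[`, character(1), "name")
  out
}

simulate_one_caller <- function(truth, truth_fp, pr, genome, sample_label) {
  tdf <- as.data.frame(truth)
  calls <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), copy_number = numeric(0),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tdf))) {
    size <- tdf$end[i] - tdf$start[i]
    if (stats::runif(1L) > pr$detection_prob(size)) next
    len <- genome[[tdf$chrom[i]]]
    s <- tdf$start[i] + round(stats::rnorm(1L, 0, pr$jitter_sd_bp))
    e <- tdf$end[i] + round(stats::rnorm(1L, 0, pr$jitter_sd_bp))
    s <- max(0, s); e <- min(len, e)
    if (e <= s) { s <- max(0, tdf$start[i]); e <- min(len, tdf$end[i]) }
    cn <- tdf$copy_number[i]
    if (stats::runif(1L) < pr$cn_error_prob) {
      delta <- sample(c(-2L, -1L, 1L, 2L), 1L)
      cn2 <- cn + delta
      # direction-preserving: gains stay > 2, losses stay in {0, 1}
      cn <- if (cn > 2) max(3, cn2) else min(1, max(0, cn2))
    }
    calls <- rbind(calls, data.frame(chrom = tdf$chrom[i], start = s, end = e,
                                     copy_number = cn, stringsAsFactors = FALSE))
  }
  genome_mb <- sum(as.numeric(genome)) / 1e6
  n_fp <- stats::rpois(1L, pr$fp_rate_per_mb * genome_mb)
  if (n_fp > 0L) {
    avoid <- rbind(truth_fp, calls[, c("chrom", "start", "end")])
    lr <- log(pr$fp_size_range_bp)
    for (j in seq_len(n_fp)) {
      size <- round(exp(stats::runif(1L, lr[1L], lr[2L])))
      for (try in seq_len(50L)) {
        chr <- sample(names(genome), 1L, prob = as.numeric(genome))
        if (genome[[chr]] <= size) next
        s <- floor(stats::runif(1L, 0, genome[[chr]] - size))
        if (!iv_hits_any(avoid, chr, s, s + size)) {
          cn <- if (stats::runif(1L) < 0.5) sample(3:6, 1L) else 1L
          cand <- data.frame(chrom = chr, start = s, end = s + size,
                             stringsAsFactors = FALSE)
          calls <- rbind(calls, cbind(cand, copy_number = cn))
          avoid <- rbind(avoid, cand)
          break
        }
      }
    }
  }
  normalize_callset(cnv_calls(calls$chrom, calls$start, calls$end,
                              calls$copy_number, pr$name, sample_label))
}

#' Write a simulated benchmark to disk
#'
#' Writes each sample's truth profile and per-caller call sets as bed5 seg
#' files plus a `manifest.tsv` (sample, caller, role, path).
#'
#' @param truth Named list of truth `cnv_callset`s ([simulate_truth()]).
#' @param calls Named list (per sample) of named lists of `cnv_callset`s
#'   ([simulate_calls()] per sample).
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_simulation <- function(truth, calls, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (lab in names(truth)) {
    tp <- file.path(dir, sprintf("%s.truth.seg", lab))
    write_seg(truth[[lab]], tp)
    rows[[length(rows) + 1L]] <- data.frame(sample = lab, caller = "truth",
                                            role = "truth", path = basename(tp),
                                            stringsAsFactors = FALSE)
    for (cl in names(calls[[lab]])) {
      cp <- file.path(dir, sprintf("%s.%s.seg", lab, cl))
      write_seg(calls[[lab]][[cl]], cp)
      rows[[length(rows) + 1L]] <- data.frame(sample = lab, caller = cl,
                                              role = "calls", path = basename(cp),
                                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
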