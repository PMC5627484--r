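noiseless_profiles <- function(names = c("p1", "p2")) {
  lapply(names, function(nm) {
    noise_profile(nm, function(size) 1, jitter_sd_bp = 0, fp_rate_per_mb = 0,
                  fp_size_range_bp = c(1e4, 1e5), cn_error_prob = 0)
  })
}

test_that("default truth spec reproduces the benchmark shape", {
  g <- genome_spec()
  truth <- simulate_truth(g, truth_spec(), seed = 42)
  expect_length(truth, 13L)
  for (tp in truth) {
    df <- as.data.frame(tp)
    expect_equal(nrow(df), 10L)
    sizes <- df$end - df$start
    expect_true(all(sizes >= 5e5 & sizes <= 4.5e6))
    expect_true(all(df$copy_number %in% c(1, 3:20)))
    expect_true(all(df$end <= g[df$chrom]))
    # pairwise gaps >= 1 Mb within a chromosome
    for (ch in unique(df$chrom)) {
      sub <- df[df$chrom == ch, ]
      sub <- sub[order(sub$start), ]
      if (nrow(sub) > 1L) {
        expect_true(all(sub$start[-1] - sub$end[-nrow(sub)] >= 1e6))
      }
    }
  }
})

test_that("simulation is a pure function of spec and seed, per-sample streams label-keyed", {
  g <- genome_spec()
  t1 <- simulate_truth(g, truth_spec(n_samples = 3), seed = 5)
  t2 <- simulate_truth(g, truth_spec(n_samples = 3), seed = 5)
  expect_identical(t1, t2)
  t3 <- simulate_truth(g, truth_spec(n_samples = 3), seed = 6)
  expect_false(identical(as.data.frame(t1[[1]]), as.data.frame(t3[[1]])))
  # growing n_samples does not change earlier samples' draws
  t5 <- simulate_truth(g, truth_spec(n_samples = 5), seed = 5)
  expect_identical(as.data.frame(t1[[2]]), as.data.frame(t5[[2]]))
  # same for calls: adding a caller leaves others' draws unchanged
  pr <- caller_noise_profiles()
  c1 <- simulate_calls(t1[[1]], pr, g, seed = 5)
  c2 <- simulate_calls(t1[[1]], pr[1:2], g, seed = 5)
  expect_identical(as.data.frame(c1[[2]]), as.data.frame(c2[[2]]))
  # files written twice are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(t1["sample01"], list(sample01 = c1), d1)
  write_simulation(t1["sample01"],
                   list(sample01 = simulate_calls(t1[[1]], pr, g, seed = 5)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("cnvs_per_sample = 0 yields empty profiles", {
  truth <- simulate_truth(genome_spec(), truth_spec(n_samples = 2,
                                                    cnvs_per_sample = 0),
                          seed = 1)
  expect_true(all(vapply(truth, nrow, integer(1)) == 0L))
})

test_that("noiseless simulation reproduces the truth footprint exactly, end to end", {
  g <- genome_spec()
  truth <- simulate_truth(g, truth_spec(n_samples = 2), seed = 11)
  assay <- data.frame(chrom = names(g), start = 0, end = as.numeric(g))
  for (lab in names(truth)) {
    calls <- simulate_calls(truth[[lab]], noiseless_profiles(), g, seed = 11)
    for (cs in calls) {
      expect_identical(
        as.data.frame(cs)[, c("chrom", "start", "end", "copy_number")],
        as.data.frame(truth[[lab]])[, c("chrom", "start", "end", "copy_number")])
    }
    tab <- evaluate_thresholds(calls, truth[[lab]], assay)
    expect_true(all(tab$tpr == 1))
    expect_true(all(tab$fdr == 0))
    expect_true(all(tab$precision == 1))
  }
})

test_that("zero detection and zero FP rate give empty call sets", {
  g <- genome_spec()
  truth <- simulate_truth(g, truth_spec(n_samples = 1), seed = 3)
  pr <- noise_profile("mute", function(size) 0, 0, 0, c(1e4, 1e5), 0)
  calls <- simulate_calls(truth[[1]], list(pr), g, seed = 3)
  expect_equal(nrow(calls[[1]]), 0L)
})

test_that("copy-number errors never cross the gain/loss boundary", {
  g <- genome_spec()
  truth <- simulate_truth(g, truth_spec(n_samples = 3), seed = 21)
  pr <- noise_profile("noisy", function(size) 1, jitter_sd_bp = 0,
                      fp_rate_per_mb = 0, fp_size_range_bp = c(1e4, 1e5),
                      cn_error_prob = 1)
  for (lab in names(truth)) {
    cs <- simulate_calls(truth[[lab]], list(pr), g, seed = 21)[[1]]
    tdf <- as.data.frame(truth[[lab]])
    expect_identical(cs$direction, tdf$direction)
    expect_false(any(cs$copy_number == 2))
  }
})

test_that("event recall tracks the analytic detection probability", {
  g <- genome_spec()
  truth <- simulate_truth(g, truth_spec(), seed = 8)
  pr <- caller_noise_profiles()$excavator_like
  detected <- 0L; expected <- 0; varsum <- 0
  for (lab in names(truth)) {
    tdf <- as.data.frame(truth[[lab]])
    cs <- simulate_calls(truth[[lab]], list(pr), g, seed = 8)[[1]]
    p <- pr$detection_prob(tdf$end - tdf$start)
    expected <- expected + sum(p)
    varsum <- varsum + sum(p * (1 - p))
    for (i in seq_len(nrow(tdf))) {
      hit <- any(cs$chrom == tdf$chrom[i] & cs$direction == tdf$direction[i] &
                   pmin(cs$end, tdf$end[i]) > pmax(cs$start, tdf$start[i]))
      detected <- detected + hit
    }
  }
  expect_lt(abs(detected - expected), 3 * sqrt(varsum))
})

test_that("infeasible placement errors with a helpful message", {
  tiny <- genome_spec(c(chrA = 6e6))
  expect_error(simulate_truth(tiny, truth_spec(n_samples = 1), seed = 1),
               "larger genome")
})
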