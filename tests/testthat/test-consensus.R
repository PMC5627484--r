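two_caller_example <- function() {
  list(normalize_callset(cnv_calls("chr1", 100, 300, 3, "A", "s1")),
       normalize_callset(cnv_calls("chr1", 200, 400, 4, "B", "s1")))
}

test_that("breakpoint partition labels each piece with its covering callers", {
  cons <- build_consensus(two_caller_example())
  seg <- cons$segments
  expect_equal(seg$start, c(100, 200, 300))
  expect_equal(seg$end, c(200, 300, 400))
  expect_equal(seg$callers, c("A", "A,B", "B"))
  expect_equal(seg$multiplicity, c(1L, 2L, 1L))
  expect_equal(seg$class, c("unique", "double", "unique"))
  expect_equal(seg$per_caller_cn, c("A=3", "A=3,B=4", "B=4"))
})

test_that("a single caller yields unique segments equal to its own footprint", {
  cs <- normalize_callset(cnv_calls("chr1", 100, 300, 5, "A", "s1"))
  cons <- build_consensus(list(cs))
  expect_equal(nrow(cons$segments), 1L)
  expect_equal(cons$segments$multiplicity, 1L)
  expect_equal(class_regions(cons, 1)$end, 300)
})

test_that("gains and losses never co-support a segment", {
  cs <- list(normalize_callset(cnv_calls("chr1", 100, 200, 5, "A", "s1")),
             normalize_callset(cnv_calls("chr1", 100, 200, 1, "B", "s1")))
  cons <- build_consensus(cs)
  expect_equal(nrow(cons$segments), 2L)
  expect_equal(sort(cons$segments$direction), c("gain", "loss"))
  expect_true(all(cons$segments$multiplicity == 1L))
  expect_identical(segments_core(cons), oracle_consensus_segments(cs))
})

test_that("mixed samples and duplicate callers are rejected", {
  a <- normalize_callset(cnv_calls("chr1", 0, 100, 3, "A", "s1"))
  b <- normalize_callset(cnv_calls("chr1", 0, 100, 3, "A", "s2"))
  expect_error(build_consensus(list(a, b)), "duplicate caller")
  b2 <- normalize_callset(cnv_calls("chr1", 0, 100, 3, "B", "s2"))
  expect_error(build_consensus(list(a, b2)), "mix samples")
  expect_error(build_consensus(list(cnv_calls("chr1", 0, 100, 3, "B", "s1"))),
               "normalized")
})

test_that("consensus equals the per-base caller-set oracle on random instances", {
  for (seed in 1:40) {
    cs <- random_callsets(seed, max_coord = 2e4)
    cons <- build_consensus(cs)
    expect_identical(segments_core(cons), oracle_consensus_segments(cs),
                     info = sprintf("seed %d", seed))
  }
})

test_that("class bp decomposes the union and filtering is monotone", {
  for (seed in 41:60) {
    cs <- random_callsets(seed, max_coord = 2e4)
    cons <- build_consensus(cs)
    for (d in c("gain", "loss")) {
      raw <- do.call(rbind, lapply(cs, function(x) {
        as.data.frame(x)[x$direction == d, c("chrom", "start", "end"), drop = FALSE]
      }))
      seg <- cons$segments[cons$segments$direction == d, , drop = FALSE]
      expect_equal(sum(seg$end - seg$start), oracle_union_bp(raw))
      venn <- cons$venn_counts
      expect_equal(sum(venn$bp[venn$direction == d]), oracle_union_bp(raw))
    }
    bp_at <- vapply(seq_len(length(cs) + 1L), function(k) {
      f <- filter_min_callers(cons, k)
      sum(f$segments$end - f$segments$start)
    }, numeric(1))
    expect_true(all(diff(bp_at) <= 0))
    expect_equal(bp_at[length(bp_at)], 0) # min_callers > n callers -> empty
    expect_identical(filter_min_callers(cons, 1)$segments, cons$segments)
  }
})

test_that("caller input order changes no boundaries or labels", {
  for (seed in 61:70) {
    cs <- random_callsets(seed, n_callers = 3, max_coord = 2e4)
    cons1 <- build_consensus(cs)
    cons2 <- build_consensus(rev(cs))
    expect_identical(cons1$segments, cons2$segments)
    expect_identical(cons1$venn_counts, cons2$venn_counts)
  }
})

test_that("class_regions returns merged exactly-k regions per direction", {
  cons <- build_consensus(two_caller_example())
  r2 <- class_regions(cons, 2)
  expect_equal(nrow(r2), 1L)
  expect_equal(c(r2$start, r2$end), c(200, 300))
  expect_equal(r2$direction, "gain")
  expect_equal(nrow(class_regions(cons, 4)), 0L)
  # adjacent exactly-k segments with different caller sets merge
  cs <- list(normalize_callset(cnv_calls("chr1", 0, 100, 3, "A", "s1")),
             normalize_callset(cnv_calls("chr1", 100, 200, 4, "B", "s1")))
  r1 <- class_regions(build_consensus(cs), 1)
  expect_equal(nrow(r1), 1L)
  expect_equal(c(r1$start, r1$end), c(0, 200))
})

test_that("min_segment_bp drops shared slivers below the configured length", {
  cs <- list(normalize_callset(cnv_calls("chr1", 0, 101, 3, "A", "s1")),
             normalize_callset(cnv_calls("chr1", 100, 200, 4, "B", "s1")))
  expect_equal(nrow(build_consensus(cs)$segments), 3L)
  cons <- build_consensus(cs, min_segment_bp = 5)
  expect_equal(nrow(cons$segments), 2L)
  expect_false(any(cons$segments$multiplicity == 2L))
})
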