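make_genes <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  structure(df[, c("gene_id", "chrom", "start", "end")],
            class = c("gene_models", "data.frame"))
}

one_caller_consensus <- function(regions_df, cn = 3) {
  build_consensus(list(normalize_callset(
    cnv_calls(regions_df$chrom, regions_df$start, regions_df$end,
              rep(cn, nrow(regions_df)), "A", "s1"))))
}

test_that("the coverage threshold is inclusive at the boundary", {
  genes <- make_genes(gene_id = "G1", chrom = "chr1", start = 0, end = 1000)
  cons <- one_caller_consensus(data.frame(chrom = "chr1", start = 0, end = 700))
  hit <- map_genes(cons, genes, coverage = 0.7)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$coverage_fraction, 0.7)
  expect_equal(hit$class, "unique")
  expect_equal(hit$callers, "A")
  cons699 <- one_caller_consensus(data.frame(chrom = "chr1", start = 0, end = 699))
  expect_equal(nrow(map_genes(cons699, genes, coverage = 0.7)), 0L)
})

test_that("coverage accumulates over the union of same-class regions", {
  genes <- make_genes(gene_id = "G1", chrom = "chr1", start = 0, end = 1000)
  cons <- one_caller_consensus(data.frame(chrom = c("chr1", "chr1"),
                                          start = c(0, 500), end = c(400, 900)))
  hit <- map_genes(cons, genes, coverage = 0.7)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$coverage_fraction, 0.8)
})

test_that("threshold extremes: near-zero keeps any overlap, 1.0 keeps only contained genes", {
  genes <- make_genes(gene_id = c("G1", "G2", "G3"), chrom = "chr1",
                      start = c(0, 600, 2000), end = c(500, 1500, 2500))
  cons <- one_caller_consensus(data.frame(chrom = "chr1", start = 100, end = 1600))
  lo <- map_genes(cons, genes, coverage = 1e-9)
  expect_setequal(lo$gene_id, c("G1", "G2"))
  hi <- map_genes(cons, genes, coverage = 1)
  expect_equal(hi$gene_id, "G2")
  expect_error(map_genes(cons, genes, coverage = 0), "coverage threshold")
  expect_error(map_genes(cons, genes, coverage = 1.2), "coverage threshold")
})

test_that("gene coverage matches a per-base union oracle on random instances", {
  for (seed in 1:15) {
    cs <- random_callsets(seed, max_coord = 1e4)
    cons <- build_consensus(cs)
    genes <- with_seed(seed * 1000, {
      s <- sample(0:9000, 8)
      make_genes(gene_id = paste0("G", 1:8),
                 chrom = sample(c("chr1", "chr2"), 8, replace = TRUE),
                 start = s, end = s + sample(200:1200, 8, replace = TRUE))
    })
    got <- map_genes(cons, genes, coverage = 0.5)
    for (k in sort(unique(cons$segments$multiplicity))) {
      for (d in c("gain", "loss")) {
        regions <- class_regions(cons, k, direction = d)
        for (i in seq_len(nrow(genes))) {
          covered <- if (nrow(regions) == 0L) 0 else {
            sum(vapply(seq_len(nrow(regions)), function(j) {
              interval_overlap(as.list(genes[i, ]), as.list(regions[j, 1:3]))
            }, numeric(1)))
          }
          frac <- covered / (genes$end[i] - genes$start[i])
          emitted <- any(got$gene_id == genes$gene_id[i] &
                           got$multiplicity_class == k & got$direction == d)
          expect_equal(emitted, frac >= 0.5,
                       info = sprintf("seed %d gene %d k=%d %s", seed, i, k, d))
          if (emitted) {
            expect_equal(got$coverage_fraction[got$gene_id == genes$gene_id[i] &
                                                 got$multiplicity_class == k &
                                                 got$direction == d], frac)
          }
        }
      }
    }
  }
})

make_catalog <- function(terms, name = "demo") {
  structure(list(name = name,
                 terms = lapply(terms, function(g) list(description = "d",
                                                        genes = sort(g)))),
            class = "term_catalog")
}

test_that("one-sided Fisher p matches the exact hypergeometric tail on random tables", {
  set.seed(99)
  for (i in 1:1000) {
    N <- sample(4:200, 1)
    K <- sample(1:(N - 1), 1)      # term genes in universe
    n <- sample(1:(N - 1), 1)      # CNV genes in universe
    universe <- paste0("g", seq_len(N))
    term <- universe[seq_len(K)]
    cnv <- sample(universe, n)
    rec <- fisher_enrichment(cnv, make_catalog(list(T1 = term)), universe)
    expect_equal(rec$a + rec$b, n)
    expect_equal(rec$a + rec$c, K)
    expect_equal(rec$a + rec$b + rec$c + rec$d, N)
    expect_equal(rec$p_value, oracle_hyper_tail(rec$a, rec$b, rec$c, rec$d),
                 tolerance = 1e-12)
  }
})

test_that("enrichment agrees with fisher.test(alternative = 'greater')", {
  tabs <- list(c(3, 7, 2, 88), c(0, 10, 5, 85), c(10, 0, 10, 80), c(1, 1, 1, 1))
  for (t in tabs) {
    universe <- paste0("g", seq_len(sum(t)))
    cnv <- universe[seq_len(t[1] + t[2])]
    term <- c(universe[seq_len(t[1])],
              universe[t[1] + t[2] + seq_len(t[3])])
    rec <- fisher_enrichment(cnv, make_catalog(list(T1 = term)), universe)
    ft <- stats::fisher.test(matrix(c(t[1], t[2], t[3], t[4]), 2, byrow = TRUE),
                             alternative = "greater")
    expect_equal(rec$p_value, ft$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate enrichment cases give p = 1 exactly", {
  universe <- paste0("g", 1:50)
  # no overlap with the term: P(X >= 0) = 1
  rec <- fisher_enrichment(universe[1:10],
                           make_catalog(list(T1 = universe[11:20])), universe)
  expect_identical(rec$p_value, 1)
  # cnv genes == universe: X degenerate at the term size
  rec2 <- fisher_enrichment(universe,
                            make_catalog(list(T1 = universe[1:5],
                                              T2 = universe[6:30])), universe)
  expect_equal(rec2$p_value, c(1, 1))
  expect_error(fisher_enrichment("g1", make_catalog(list(T1 = "g1")),
                                 character(0)), "universe is empty")
  expect_warning(fisher_enrichment(universe[1],
                                   make_catalog(list(T1 = "absent")), universe),
                 "skipped")
})

test_that("BH adjustment satisfies p_adj >= p and step-up monotonicity; records sorted", {
  set.seed(7)
  universe <- paste0("g", 1:120)
  terms <- lapply(1:25, function(i) sample(universe, sample(3:40, 1)))
  names(terms) <- sprintf("T%02d", 1:25)
  rec <- fisher_enrichment(sample(universe, 30), make_catalog(terms), universe)
  expect_true(all(rec$p_adjusted >= rec$p_value))
  expect_true(all(diff(rec$p_value) >= 0))
  expect_true(all(diff(rec$p_adjusted) >= 0))
  expect_identical(rec$p_adjusted, p.adjust(rec$p_value, "BH"))
})

test_that("padding the universe with never-hit genes only grows d and never raises p", {
  universe <- paste0("g", 1:60)
  cnv <- universe[1:12]
  term <- universe[c(1:4, 30:40)]
  base <- fisher_enrichment(cnv, make_catalog(list(T1 = term)), universe)
  for (extra in c(10, 100)) {
    uni2 <- c(universe, paste0("pad", seq_len(extra)))
    rec <- fisher_enrichment(cnv, make_catalog(list(T1 = term)), uni2)
    expect_equal(rec$a, base$a)
    expect_equal(rec$b, base$b)
    expect_equal(rec$c, base$c)
    expect_equal(rec$d, base$d + extra)
    expect_lte(rec$p_value, base$p_value)
  }
})
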