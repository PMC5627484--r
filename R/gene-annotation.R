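#' Map genes into CNV multiplicity classes by coverage fraction
#'
#' For every multiplicity class and direction, a gene's coverage fraction
#' is the number of its bases overlapped by the union of that class's
#' merged regions, divided by the gene length. A gene is retrieved when
#' its coverage fraction reaches the threshold (comparison is inclusive,
#' so exactly 70% qualifies under the default 0.7). Coverage is computed
#' against the class-wide region union, so a gene split across adjacent
#' regions of one class still qualifies.
#'
#' @param result A `cnv_consensus` (optionally already filtered with
#'   [filter_min_callers()]).
#' @param genes A `gene_models` data frame from [read_gene_bed()].
#' @param coverage Threshold fraction in (0, 1]; default 0.7.
#' @return Data frame of assignments: `gene_id`, `multiplicity_class`,
#'   `class`, `direction`, `coverage_fraction`, `callers` (union over the
#'   overlapping segments, comma-separated).
#' @export
map_genes <- function(result, genes, coverage = 0.7) {
  stopifnot(inherits(result, "cnv_consensus"))
  if (!is.data.frame(genes) || !all(c("gene_id", "chrom", "start", "end") %in% names(genes))) {
    stop("genes must be a gene_models data frame (see read_gene_bed())")
  }
  if (length(coverage) != 1L || coverage <= 0 || coverage > 1) {
    stop("coverage threshold must be in (0, 1]")
  }
  if (any(genes$end <= genes$start)) stop("zero-length gene interval in gene models")
  gene_gr <- iv_to_gr(genes)
  ks <- sort(unique(result$segments$multiplicity))
  rows <- list()
  for (k in ks) {
    for (d in c("gain", "loss")) {
      regions <- class_regions(result, k, direction = d)
      if (nrow(regions) == 0L) next
      g <- align_gr(gene_gr, iv_to_gr(regions))
      gene_gr_a <- g[[1L]]; reg_gr <- g[[2L]]
      ov <- GenomicRanges::findOverlaps(gene_gr_a, reg_gr)
      if (length(ov) == 0L) next
      qi <- S4Vectors::queryHits(ov)
      w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(gene_gr_a)[qi],
        GenomicRanges::ranges(reg_gr)[S4Vectors::subjectHits(ov)]))
      covered <- tapply(w, qi, sum)
      gi <- as.integer(names(covered))
      frac <- as.numeric(covered) / (genes$end[gi] - genes$start[gi])
      keep <- frac >= coverage
      if (!any(keep)) next
      gi <- gi[keep]; frac <- frac[keep]
      # supporting callers: union over class-k segments overlapping the gene
      seg <- result$segments
      seg <- seg[seg$multiplicity == k & seg$direction == d, , drop = FALSE]
      g2 <- align_gr(gene_gr[gi], iv_to_gr(seg))
      ov2 <- GenomicRanges::findOverlaps(g2[[1L]], g2[[2L]])
      callers <- vapply(seq_along(gi), function(j) {
        hit <- S4Vectors::subjectHits(ov2)[S4Vectors::queryHits(ov2) == j]
        paste(sort(unique(unlist(strsplit(seg$callers[hit], ",")))), collapse = ",")
      }, character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes$gene_id[gi], multiplicity_class = k,
        class = multiplicity_class(k), direction = d,
        coverage_fraction = frac, callers = callers,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0), multiplicity_class = integer(0),
                      class = character(0), direction = character(0),
                      coverage_fraction = numeric(0), callers = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$multiplicity_class, out$direction, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' One-sided Fisher's-exact-test term enrichment
#'
#' For each term of a catalog, forms the 2x2 table over the gene universe
#' (`a` = CNV genes in the term, `b` = CNV genes outside it, `c` =
#' background-only genes in the term, `d` = the rest) and computes the
#' one-sided enrichment p-value, i.e. the hypergeometric upper tail
#' P(X >= a) with X ~ Hypergeom(N = a+b+c+d, K = a+c, n = a+b). P-values
#' are Benjamini-Hochberg adjusted within the catalog. Genes outside the
#' universe are ignored on both sides; terms with no universe genes are
#' skipped with a warning.
#'
#' @param cnv_genes Character vector of CNV-region gene ids.
#' @param catalog A `term_catalog` from [read_gmt()].
#' @param universe Character vector: the background gene set (non-empty).
#' @return Data frame sorted by p-value then term id: `term_id`, `catalog`,
#'   `description`, `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`,
#'   `p_adjusted`.
#' @export
fisher_enrichment <- function(cnv_genes, catalog, universe) {
  stopifnot(inherits(catalog, "term_catalog"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("enrichment universe is empty")
  cnv <- unique(intersect(as.character(cnv_genes), universe))
  N <- length(universe)
  rows <- list()
  skipped <- character(0)
  for (id in names(catalog$terms)) {
    term <- catalog$terms[[id]]
    tg <- intersect(term$genes, universe)
    if (length(tg) == 0L) {
      skipped <- c(skipped, id)
      next
    }
    a <- length(intersect(cnv, tg))
    b <- length(cnv) - a
    cc <- length(tg) - a
    d <- N - a - b - cc
    # upper tail P(X >= a) of the hypergeometric draw of |cnv| from N
    p <- stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
    or <- if (b * cc == 0) {
      if (a * d > 0) Inf else NA_real_
    } else (a * d) / (b * cc)
    rows[[length(rows) + 1L]] <- data.frame(
      term_id = id, catalog = catalog$name, description = term$description,
      a = a, b = b, c = cc, d = d, odds_ratio = or, p_value = p,
      stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0L) {
    warning(sprintf("catalog '%s': skipped %d term(s) with no genes in the universe: %s",
                    catalog$name, length(skipped),
                    paste(utils::head(skipped, 5L), collapse = ", ")))
  }
  if (length(rows) == 0L) {
    return(data.frame(term_id = character(0), catalog = character(0),
                      description = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}
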