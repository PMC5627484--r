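#' Read gene models from a BED4+ file
#'
#' Expects at least four tab-separated columns: chrom, start, end (0-based
#' half-open, preserved as-is) and a gene identifier. Gene identifiers must
#' be unique and intervals non-empty.
#'
#' @param path BED file path.
#' @return A `gene_models` data frame with columns `gene_id`, `chrom`,
#'   `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("gene BED not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#") &
    !grepl("^(track|browser)\\b", lines)
  lineno <- seq_along(lines)[keep]
  lines <- lines[keep]
  rows <- strsplit(lines, "\t")
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) < 4L) {
      stop(sprintf("%s line %d: gene BED needs >= 4 columns (missing the gene name column)",
                   path, lineno[i]))
    }
  }
  df <- data.frame(
    gene_id = vapply(rows, `[`, character(1), 4L),
    chrom = vapply(rows, `[`, character(1), 1L),
    start = as.numeric(vapply(rows, `[`, character(1), 2L)),
    end = as.numeric(vapply(rows, `[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$start) || anyNA(df$end)) stop(sprintf("%s: unparseable coordinates", path))
  if (any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)[1L]
    stop(sprintf("%s line %d: zero-length or inverted gene interval (%s)",
                 path, lineno[bad], df$gene_id[bad]))
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0L) {
    stop(sprintf("%s: duplicate gene id(s): %s", path,
                 paste(unique(dup), collapse = ", ")))
  }
  df <- sort_intervals(df)
  rownames(df) <- NULL
  structure(df, class = c("gene_models", "data.frame"))
}

#' Read a GMT gene-set catalog
#'
#' Standard GMT: one term per line, tab-separated as term id, description,
#' then one or more member gene ids. Lines for the same term are merged by
#' gene-set union with a warning.
#'
#' @param path GMT file path.
#' @param catalog_name Catalog label (e.g. "GO", "KEGG"); defaults to the
#'   file name without extension.
#' @return A `term_catalog`: list with `name` and `terms`, the latter a
#'   named list of `list(description, genes)`.
#' @export
read_gmt <- function(path, catalog_name = NULL) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path))
  catalog_name <- catalog_name %||% tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) == 0L) stop(sprintf("%s: empty GMT file", path))
  terms <- list()
  dups <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t")[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("%s line %d: GMT lines need >= 3 tab-separated fields (term, description, genes)",
                   path, lineno[i]))
    }
    id <- f[1L]
    genes <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(genes) == 0L) {
      stop(sprintf("%s line %d: term '%s' has an empty gene set", path, lineno[i], id))
    }
    if (id %in% names(terms)) {
      dups <- c(dups, id)
      terms[[id]]$genes <- sort(unique(c(terms[[id]]$genes, genes)))
    } else {
      terms[[id]] <- list(description = f[2L], genes = sort(genes))
    }
  }
  if (length(dups) > 0L) {
    warning(sprintf("%s: merged duplicate term(s) by gene-set union: %s",
                    path, paste(unique(dups), collapse = ", ")))
  }
  structure(list(name = catalog_name, terms = terms), class = "term_catalog")
}

#' @export
print.term_catalog <- function(x, ...) {
  sizes <- vapply(x$terms, function(t) length(t$genes), integer(1))
  cat(sprintf("Term catalog '%s': %d term(s), %d distinct gene(s)\n",
              x$name, length(x$terms),
              length(unique(unlist(lapply(x$terms, `[[`, "genes"))))))
  if (length(sizes) > 0L) {
    cat(sprintf("  gene-set sizes: min %d, median %s, max %d\n",
                min(sizes), format(stats::median(sizes)), max(sizes)))
  }
  invisible(x)
}

# All gene ids appearing in a catalog (used for the alternative universe).
catalog_genes <- function(catalog) {
  sort(unique(unlist(lapply(catalog$terms, `[[`, "genes"), use.names = FALSE)))
}
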