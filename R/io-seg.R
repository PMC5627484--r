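#' Describe a tab-separated CNV segment file layout
#'
#' A seg dialect names which columns carry the chromosome, start, end and
#' copy number, which coordinate convention the file uses, and whether a
#' header line and comment lines are present. Coordinates are converted on
#' read to the internal 0-based half-open convention: a 1-based inclusive
#' interval `[s, e]` becomes `[s - 1, e)`.
#'
#' @param name Dialect name.
#' @param chrom,start,end,copy_number 1-based column indices of the four
#'   required roles; must be distinct.
#' @param coordinate_base `"zero_half_open"` or `"one_inclusive"`.
#' @param has_header Logical; is the first non-comment line a header?
#' @param comment_prefix Lines starting with this prefix are skipped.
#' @return A `seg_dialect` object.
#' @examples
#' seg_dialect("custom", chrom = 1, start = 2, end = 3, copy_number = 5,
#'             coordinate_base = "one_inclusive", has_header = TRUE)
#' @export
seg_dialect <- function(name, chrom = 1L, start = 2L, end = 3L,
                        copy_number = 4L,
                        coordinate_base = c("zero_half_open", "one_inclusive"),
                        has_header = FALSE, comment_prefix = "#") {
  coordinate_base <- match.arg(coordinate_base)
  cols <- c(chrom = as.integer(chrom), start = as.integer(start),
            end = as.integer(end), copy_number = as.integer(copy_number))
  if (anyNA(cols) || any(cols < 1L)) stop("column indices must be positive integers")
  if (anyDuplicated(cols)) stop("column indices must be distinct")
  structure(list(name = name, columns = cols,
                 coordinate_base = coordinate_base,
                 has_header = isTRUE(has_header),
                 comment_prefix = comment_prefix),
            class = "seg_dialect")
}

#' Built-in seg dialect presets
#'
#' Five editable presets: `bed5` (the package's own output layout, 0-based
#' half-open, no header: chrom, start, end, copy number, direction label)
#' and plausible layouts named after four common exome CNV callers
#' (`freec`, `adtex`, `excavator`, `exomecnv`), all read as 1-based
#' inclusive. The caller-named presets are conventions of this package, not
#' authoritative descriptions of those tools' outputs; adjust with
#' [seg_dialect()] if your files differ.
#'
#' @return Named list of `seg_dialect` objects.
#' @export
seg_dialects <- function() {
  list(
    bed5 = seg_dialect("bed5", 1, 2, 3, 4, "zero_half_open",
                       has_header = FALSE),
    freec = seg_dialect("freec", 1, 2, 3, 4, "one_inclusive",
                        has_header = FALSE),
    adtex = seg_dialect("adtex", 1, 2, 3, 5, "one_inclusive",
                        has_header = TRUE),
    excavator = seg_dialect("excavator", 1, 2, 3, 5, "one_inclusive",
                            has_header = FALSE),
    exomecnv = seg_dialect("exomecnv", 1, 2, 3, 4, "one_inclusive",
                           has_header = TRUE)
  )
}

resolve_dialect <- function(dialect) {
  if (inherits(dialect, "seg_dialect")) return(dialect)
  if (is.character(dialect) && length(dialect) == 1L) {
    presets <- seg_dialects()
    if (!dialect %in% names(presets)) {
      stop(sprintf("unknown seg dialect '%s'; known: %s", dialect,
                   paste(names(presets), collapse = ", ")))
    }
    return(presets[[dialect]])
  }
  stop("dialect must be a seg_dialect object or a preset name")
}

#' Read one caller's CNV segment file
#'
#' Parses a tab/whitespace-separated segment file under a [seg_dialect()],
#' converts coordinates to 0-based half-open, derives gain/loss from the
#' copy number (diploid baseline 2), skips copy-number-2 rows with a
#' warning, and returns the normalized call set.
#'
#' @param path File path.
#' @param dialect A `seg_dialect` or preset name (see [seg_dialects()]).
#' @param caller,sample Identifiers attached to every call.
#' @return A normalized `cnv_callset`.
#' @export
read_seg <- function(path, dialect = "bed5", caller = "caller",
                     sample = "sample") {
  dialect <- resolve_dialect(dialect)
  if (!file.exists(path)) stop(sprintf("seg file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), dialect$comment_prefix) &
    nzchar(trimws(lines))
  lineno <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (dialect$has_header && length(lines) > 0L) {
    lines <- lines[-1L]
    lineno <- lineno[-1L]
  }
  if (length(lines) == 0L) {
    return(normalize_callset(cnv_calls(character(0), numeric(0), numeric(0),
                                       numeric(0), caller, sample)))
  }
  cols <- dialect$columns
  need <- max(cols)
  rows <- strsplit(trimws(lines), "[\t ]+")
  parsed <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < need) {
      stop(sprintf("%s line %d: expected >= %d fields under dialect '%s', got %d",
                   path, lineno[i], need, dialect$name, length(f)))
    }
    s <- suppressWarnings(as.numeric(f[cols["start"]]))
    e <- suppressWarnings(as.numeric(f[cols["end"]]))
    cn <- suppressWarnings(as.numeric(f[cols["copy_number"]]))
    if (is.na(s) || is.na(e) || is.na(cn) || cn != round(cn)) {
      stop(sprintf("%s line %d: unparseable coordinates or copy number", path, lineno[i]))
    }
    if (dialect$coordinate_base == "one_inclusive") s <- s - 1
    if (s < 0 || s >= e) {
      stop(sprintf("%s line %d: start >= end after coordinate conversion", path, lineno[i]))
    }
    parsed[[i]] <- c(s, e, cn, i)
  }
  m <- do.call(rbind, parsed)
  chrom <- vapply(rows, function(f) f[cols["chrom"]], character(1))
  is_dip <- m[, 3L] == 2
  if (any(is_dip)) {
    warning(sprintf("%s: skipped %d row(s) with copy number 2 (diploid baseline)",
                    path, sum(is_dip)))
  }
  keep <- !is_dip
  normalize_callset(cnv_calls(chrom[keep], m[keep, 1L], m[keep, 2L],
                              m[keep, 3L], caller, sample))
}

#' Write a call set as a bed5 seg file
#'
#' The inverse of [read_seg()] under the `bed5` dialect: chrom, start, end
#' (0-based half-open), copy number, direction.
#'
#' @param calls A `cnv_callset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(calls, path) {
  df <- as.data.frame(calls)[, c("chrom", "start", "end", "copy_number",
                                 "direction")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
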