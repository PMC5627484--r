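#' Read a pipeline configuration file
#'
#' Flat `key = value` text; keys are case-insensitive, `#` starts a
#' comment, unknown keys warn, missing required keys error. Recognised
#' keys:
#' \describe{
#'   \item{caller}{Repeatable. `name:path[:dialect]` — one caller's seg
#'     file; dialect defaults to `bed5` (see [seg_dialects()]).}
#'   \item{genes}{Gene-model BED path (optional; enables gene mapping).}
#'   \item{catalog}{Repeatable. GMT term-catalog path (optional).}
#'   \item{truth}{Truth-profile seg path (optional; enables evaluation).}
#'   \item{truth_dialect}{Dialect of the truth file (default `bed5`).}
#'   \item{assay}{BED3 path of the assayed space for evaluation
#'     (optional; default: per-chromosome span of all inputs).}
#'   \item{sample}{Sample identifier (default `sample01`).}
#'   \item{gene_coverage}{Gene coverage threshold in (0, 1]; default 0.7.}
#'   \item{min_callers}{Minimum supporting callers for a consensus CNV;
#'     default 1.}
#'   \item{min_segment_bp}{Minimum consensus segment length; default 1.}
#'   \item{universe}{`genes` (all genes in the BED; default) or `catalog`
#'     (all genes in each term catalog).}
#'   \item{output_dir}{Output directory (required).}
#'   \item{threads}{Worker processes; default 1. Outputs are identical
#'     for any value.}
#'   \item{seed}{Integer seed echoed into the report (default 1).}
#' }
#'
#' @param path Config file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) {
    stop(sprintf("config line not of the form key = value: '%s'", lines[bad][1L]))
  }
  keys <- tolower(trimws(vapply(kv, `[`, character(1), 2L)))
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  known <- c("caller", "genes", "catalog", "truth", "truth_dialect", "assay",
             "sample", "gene_coverage", "min_callers", "min_segment_bp",
             "universe", "output_dir", "threads", "seed")
  unknown <- setdiff(unique(keys), known)
  if (length(unknown) > 0L) {
    warning(sprintf("config: ignoring unknown key(s): %s",
                    paste(unknown, collapse = ", ")))
  }
  get1 <- function(key, default = NULL) {
    v <- vals[keys == key]
    if (length(v) == 0L) default else v[length(v)]
  }
  caller_specs <- vals[keys == "caller"]
  if (length(caller_specs) == 0L) stop("config: at least one 'caller = name:path[:dialect]' entry is required")
  callers <- lapply(caller_specs, function(sp) {
    f <- strsplit(sp, ":", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stop(sprintf("config: caller entry must be name:path[:dialect], got '%s'", sp))
    list(name = f[1L], path = f[2L],
         dialect = if (length(f) >= 3L) f[3L] else "bed5")
  })
  if (anyDuplicated(vapply(callers, `[[`, character(1), "name"))) {
    stop("config: duplicate caller names")
  }
  output_dir <- get1("output_dir")
  if (is.null(output_dir)) stop("config: 'output_dir' is required")
  cfg <- list(
    callers = callers,
    genes = get1("genes"),
    catalogs = vals[keys == "catalog"],
    truth = get1("truth"),
    truth_dialect = get1("truth_dialect", "bed5"),
    assay = get1("assay"),
    sample = get1("sample", "sample01"),
    gene_coverage = as.numeric(get1("gene_coverage", "0.7")),
    min_callers = as.integer(get1("min_callers", "1")),
    min_segment_bp = as.numeric(get1("min_segment_bp", "1")),
    universe = match.arg(tolower(get1("universe", "genes")), c("genes", "catalog")),
    output_dir = output_dir,
    threads = as.integer(get1("threads", "1")),
    seed = as.integer(get1("seed", "1"))
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (is.na(cfg$gene_coverage) || cfg$gene_coverage <= 0 || cfg$gene_coverage > 1) {
    stop("config: gene_coverage must be in (0, 1]")
  }
  if (is.na(cfg$min_callers) || cfg$min_callers < 1 ||
      cfg$min_callers > length(cfg$callers)) {
    stop(sprintf("config: min_callers must be between 1 and the number of callers (%d)",
                 length(cfg$callers)))
  }
  if (is.na(cfg$threads) || cfg$threads < 1) stop("config: threads must be >= 1")
  structure(cfg, class = "pipeline_config")
}
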