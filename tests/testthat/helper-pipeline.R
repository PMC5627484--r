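# Build a complete simulated run directory: seg files for 4 callers, truth,
# a gene BED, two GMT catalogs and a config file. Returns the config path.
make_run_dir <- function(dir, seed = 101, threads = 1, min_callers = 1) {
  g <- genome_spec()
  truth <- simulate_truth(g, truth_spec(n_samples = 1), seed = seed)[[1]]
  calls <- simulate_calls(truth, caller_noise_profiles(), g, seed = seed)
  for (nm in names(calls)) write_seg(calls[[nm]], file.path(dir, paste0(nm, ".seg")))
  write_seg(truth, file.path(dir, "truth.seg"))
  genes <- with_seed(seed, {
    n <- 400
    chrom <- sample(names(g), n, replace = TRUE)
    start <- floor(runif(n, 0, as.numeric(g[chrom]) - 6e4))
    data.frame(chrom = chrom, start = start,
               end = start + sample(5e3:5e4, n, replace = TRUE),
               gene_id = sprintf("GENE%03d", seq_len(n)))
  })
  genes <- genes[order(genes$chrom, genes$start), ]
  writeLines(sprintf("%s\t%d\t%d\t%s", genes$chrom, genes$start, genes$end,
                     genes$gene_id), file.path(dir, "genes.bed"))
  with_seed(seed + 1, {
    for (cat in c("go_like", "pathway_like")) {
      lines <- vapply(1:20, function(i) {
        paste(c(sprintf("%s_T%02d", toupper(cat), i), "synthetic term",
                sample(genes$gene_id, sample(5:40, 1))), collapse = "\t")
      }, character(1))
      writeLines(lines, file.path(dir, paste0(cat, ".gmt")))
    }
  })
  cfg <- file.path(dir, "run.cfg")
  writeLines(c(
    sprintf("caller = %s:%s", names(calls), file.path(dir, paste0(names(calls), ".seg"))),
    sprintf("genes = %s", file.path(dir, "genes.bed")),
    sprintf("catalog = %s", file.path(dir, "go_like.gmt")),
    sprintf("catalog = %s", file.path(dir, "pathway_like.gmt")),
    sprintf("truth = %s", file.path(dir, "truth.seg")),
    "sample = sample01",
    sprintf("min_callers = %d", min_callers),
    sprintf("threads = %d", threads),
    sprintf("seed = %d", seed),
    sprintf("output_dir = %s", file.path(dir, "out"))), cfg)
  cfg
}
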