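# The demo community and its pipeline run are used by several test files;
# build them once per test session.
demo_fixture <- local({
  cache <- NULL
  function(seed = 1) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    cm <- demo_community(seed = seed)
    dir <- tempfile("community")
    write_community(cm, dir)
    res <- run_pipeline(dir, file.path(dir, "out"))
    lens <- stats::setNames(cm$scaffold_truth$length,
                            cm$scaffold_truth$scaffold_id)
    cache <<- list(seed = seed, community = cm, dir = dir, result = res,
                   lengths = lens)
    cache
  }
})

# map each pipeline bin to the genome it best recovers
match_bins_to_genomes <- function(res, cm, lengths) {
  genomes <- setdiff(unique(cm$scaffold_truth$genome_id), "contam")
  out <- list()
  for (b in names(res$bins)) {
    f1 <- vapply(genomes, function(g) {
      bin_accuracy(res$bins[[b]], cm$scaffold_truth, g, lengths)$f1
    }, numeric(1))
    out[[b]] <- names(which.max(f1))
  }
  out
}
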