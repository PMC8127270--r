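# one shared end-to-end run on the default synthetic dataset, computed
# lazily and reused across test files to keep the suite fast
.run_cache <- new.env(parent = emptyenv())

default_pipeline <- function() {
  if (is.null(.run_cache$res)) {
    out <- file.path(tempdir(), "ltrdyn_default_run")
    .run_cache$elapsed <- system.time(
      .run_cache$res <- run_ltr_pipeline(synthetic_genome_spec(seed = 1),
                                         outdir = out))[["elapsed"]]
    .run_cache$outdir <- out
  }
  .run_cache$res
}

default_pipeline_outdir <- function() {
  default_pipeline()
  .run_cache$outdir
}

default_pipeline_elapsed <- function() {
  default_pipeline()
  .run_cache$elapsed
}
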