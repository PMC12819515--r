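# One synthetic dataset (seed 42, the package default) and one pipeline run
# are shared across test files; generating them once keeps the suite fast.
.shared <- new.env(parent = emptyenv())

shared_dataset <- function() {
  if (is.null(.shared$dir)) {
    dir <- file.path(tempdir(), "secircuitry_shared_ds")
    unlink(dir, recursive = TRUE)
    .shared$manifest <- simulate_dataset(synth_config(seed = 42L), dir)
    .shared$dir <- dir
  }
  list(dir = .shared$dir, manifest = .shared$manifest)
}

shared_run <- function() {
  ds <- shared_dataset()
  if (is.null(.shared$res)) {
    .shared$res <- suppressMessages(
      run_pipeline(ds$dir, file.path(ds$dir, "results")))
  }
  list(dir = ds$dir, manifest = ds$manifest, res = .shared$res)
}

# construct a minimal ranked_profile for consensus-level tests
make_profile <- function(sample_id, chrom, start, end, intensity,
                         is_super = TRUE) {
  regions <- tibble::tibble(chrom = chrom, start = as.integer(start),
                            end = as.integer(end),
                            net_signal = intensity,
                            normalized_intensity = intensity,
                            is_super = is_super)
  structure(list(sample_id = sample_id, regions = regions, cutoff_signal = 0),
            class = "ranked_profile")
}
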