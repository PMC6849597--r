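# Shared fixtures, built once per test run. The default scenario is the
# package's standard benchmark (25 genomes, 1% target, 3 bulk samples,
# 4 enriched wells, 100 markers, 14-bp insert); building it takes a few
# seconds, so it is memoised here.

.fixture_env <- new.env(parent = emptyenv())

paper_community <- function() {
  if (is.null(.fixture_env$comm)) {
    .fixture_env$comm <- simulate_community(seed = 1)
  }
  .fixture_env$comm
}

paper_features <- function() {
  if (is.null(.fixture_env$feats)) {
    comm <- paper_community()
    .fixture_env$feats <- build_features(comm$contigs, comm$coverage)
  }
  .fixture_env$feats
}

paper_run <- function() {
  if (is.null(.fixture_env$run)) {
    .fixture_env$run <- suppressMessages(run_all(list(seed = 1)))
  }
  .fixture_env$run
}

as_tibble_strip <- function(x) tibble::as_tibble(as.data.frame(x))

# A small two-genome community with well-separated composition and coverage,
# for focused binner/refiner tests.
small_community <- function(seed = 11) {
  key <- paste0("small_", seed)
  if (is.null(.fixture_env[[key]])) {
    genomes <- simulate_genomes(2, 6e4, seed = seed,
                                gc_range = c(0.35, 0.65))
    frag <- fragment_genomes(genomes, 2000, 6000, seed = seed + 1)
    ab <- simulate_abundances(genomes, 3, 0.3, seed = seed + 2)
    cov <- simulate_coverage(frag$truth, ab, 40, seed = seed + 3)
    feats <- build_features(frag$contigs, cov)
    .fixture_env[[key]] <- list(genomes = genomes, frag = frag, ab = ab,
                                cov = cov, features = feats)
  }
  .fixture_env[[key]]
}
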