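## Shared synthetic fixtures, generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

## full-size truth bundle (13 taxa, default study conditions) + annotation
shared_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    cfg <- sim_config(seed = 7L)
    .fixture_cache$bundle <- evolve_genomes(cfg = cfg)
  }
  .fixture_cache$bundle
}

shared_annotation <- function() {
  if (is.null(.fixture_cache$annotation)) {
    .fixture_cache$annotation <-
      suppressWarnings(annotate_genomes(shared_bundle()$segments))
  }
  .fixture_cache$annotation
}

## a small config with events valid for 2/2/2 clades + 2 outgroups
small_cfg <- function(seed = 5L, ...) {
  sim_config(
    clade_sizes = c(2L, 2L, 2L), n_outgroups = 2L, seed = seed,
    spacer_events = list(
      list(locus = "trnK-trnD", branch = "ingroup", seq = "ATTTA"),
      list(locus = "cob-trnS2", branch = "OG1", seq = "TTAATATTAATTTAAT")),
    loop_events = list(
      list(trna = "trnD", loop = "TPsiC", branch = "cladeC",
           motif = "ATTTAAT")),
    trait_spec = list(
      list(name = "host", states = c("x", "y"), root = "x",
           events = list(list(branch = "cladeBC", to = "y")))),
    ...)
}
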