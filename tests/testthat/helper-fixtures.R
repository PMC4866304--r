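# small deterministic references and simulation configs used across tests

# reference with an L-nt exon drawn reproducibly, flanks fixed
make_test_ref <- function(L = 6L, seed = 42L, flank5 = "ACGTA", flank3 = "TTGCA") {
  set.seed(seed)
  exon <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  load_reference(paste0(toupper(flank5), tolower(exon), toupper(flank3)))
}

# quick low-depth simulation config on a small exon
small_config <- function(L = 6L, seed = 1L, ...) {
  args <- list(...)
  defaults <- list(ref = make_test_ref(L), n_input = 2e4, n_output = 2e4,
                   replicates = 3L, seed = seed)
  defaults[names(args)] <- args
  do.call(simulation_config, defaults)
}

# full-depth FAS-design config (the study conditions)
fas_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(seed = seed)
  defaults[names(args)] <- args
  do.call(simulation_config, defaults)
}

# enrichment scores straight from a truth's expected (noise-free) counts
noiseless_scores <- function(truth, ...) {
  enrichment_scores(frequencies(expected_counts(truth)), ...)
}
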