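# Reduced-scale simulation configs for fast module tests; the default-scale
# study conditions are exercised in the acceptance suite.

small_sim_config <- function(seed = 1L, ...) {
  simulation_config(
    n_features = c(lncRNA = 40L, circRNA = 30L, miRNA = 20L, mRNA = 60L),
    n_planted_triplets = 4L, n_planted_cis_pairs = 5L,
    n_motifs = 2L, motif_sites = 2L,
    feature_spacing = 6000L, seed = seed, ...
  )
}

null_sim_config <- function(seed = 1L) {
  simulation_config(
    n_features = c(lncRNA = 30L, circRNA = 30L, miRNA = 30L, mRNA = 150L),
    de_fraction = 0, n_planted_triplets = 0L, n_planted_cis_pairs = 0L,
    n_motifs = 0L, motif_sites = 0L, feature_spacing = 1500L, seed = seed
  )
}

# one shared small dataset per test file, generated lazily
.fixture_env <- new.env(parent = emptyenv())
small_dataset <- function() {
  if (is.null(.fixture_env$ds)) .fixture_env$ds <- generate_dataset(small_sim_config(seed = 42L))
  .fixture_env$ds
}

# simple expression matrix builder for hand-constructed cases
toy_matrix <- function(values, species = "mRNA",
                       conditions = rep(c("c1", "c2", "c3"), each = 3)) {
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (is.null(rownames(values))) rownames(values) <- paste0("f", seq_len(nrow(values)))
  expression_matrix(values, species, setNames(conditions[seq_len(ncol(values))],
                                              colnames(values)))
}
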