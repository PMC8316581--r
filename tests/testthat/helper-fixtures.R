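# Small in-code fixtures shared across test files.

tiny_dataset <- function() {
  expression_dataset(
    matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE),
    gene_ids = c("g1", "g2"),
    sample_ids = c("s1", "s2", "s3"),
    group = c("patient", "patient", "control")
  )
}

# a fast, well-powered planted design for unit tests
small_design <- function(seed = 1L, effect_size = 2.0, ...) {
  simulation_design(n_genes = 240L, k_true = 3L, patients_per_cluster = 15L,
                    n_controls = 15L, effect_size = effect_size,
                    noise_sd = 0.5, module_size = 15L,
                    shared_candidate_size = 10L, seed = seed, ...)
}

# paired test-scale study: reference decoys scaled down with the design so
# the planted candidate signal keeps the power the full-size defaults have
small_study <- function(seedA, seedB, ...) {
  generate_paired_study(small_design(seed = seedA),
                        small_design(seed = seedB),
                        n_decoy_sets = 20L, ref_decoy_genes = 5L, ...)
}

random_dataset <- function(n_genes, n_samples, n_patients, seed = 1L) {
  set.seed(seed)
  expression_dataset(
    matrix(abs(rnorm(n_genes * n_samples, mean = 8)), n_genes, n_samples),
    gene_ids = sprintf("r%03d", seq_len(n_genes)),
    sample_ids = sprintf("s%03d", seq_len(n_samples)),
    group = rep(c("patient", "control"),
                c(n_patients, n_samples - n_patients))
  )
}

# map fitted cluster labels onto planted ones by majority vote
match_clusters <- function(fitted, truth) {
  k <- max(truth)
  map <- integer(k)
  for (i in seq_len(k)) {
    map[i] <- as.integer(names(which.max(table(truth[fitted == i]))))
  }
  map
}

fake_fit <- function(H = NULL, W = NULL) {
  structure(list(H = H, W = W), class = "convex_nmf_fit")
}
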