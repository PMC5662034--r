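# Small simulated fixtures shared across test files. All sizes are kept small
# on purpose; the heavier recovery simulations live in test-acceptance.R.

quick_sim <- function(n = 60, N = 120, h2 = 0.5, gamma_true = 0, seed = 42,
                      freq_model = freq_uniform(), mean_weight = 1,
                      weight_model = "constant") {
  simulate_dataset(
    n_individuals = n, n_snps = N, h2 = h2, gamma_true = gamma_true,
    mean_weight = mean_weight, weight_model = weight_model,
    freq_model = freq_model, seed = seed
  )
}

filtered_geno <- function(sim) {
  suppressMessages(apply_variant_filters(sim$genotypes))
}

# a fixed, well-behaved 5 x 3 toy system used by the dense-oracle tests
toy_system <- function() {
  X <- matrix(
    c(
      0L, 1L, 2L, 1L, 0L,
      1L, 1L, 0L, 2L, 1L,
      2L, 0L, 1L, 1L, 1L
    ),
    nrow = 5, ncol = 3,
    dimnames = list(paste0("i", 1:5), paste0("s", 1:3))
  )
  pheno <- tibble::tibble(
    id = paste0("i", 1:5),
    phenotype = c(1.2, -0.4, 0.8, 2.1, -1.0),
    weight = c(1, 2, 1, 3, 1)
  )
  list(X = X, pheno = pheno)
}
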