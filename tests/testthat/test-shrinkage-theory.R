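# Exact normalizing constant of the symmetrized harmonic sum, used as the
# independent oracle for cstar(): with 4*Ne*v = 0 the grid sum collapses to
# sum_p 1/(p(1-p)) = 4n * H_{2n-1} with H the harmonic number.
harmonic_constant <- function(n) {
  1 / (4 * n * sum(1 / seq_len(2 * n - 1)))
}

test_that("the closed-form C* matches the exact harmonic-sum constant", {
  expect_equal(cstar(1000), 3.057e-5, tolerance = 1e-3)
  for (n in c(50, 200, 1000, 5e4)) {
    expect_equal(cstar(n), harmonic_constant(n), tolerance = 1e-4)
    expect_equal(ushaped_constant_exact(n, Ne = 65, v = 1e-8), harmonic_constant(n),
      tolerance = 1e-4
    )
  }
})

test_that("expected heterozygosity matches brute-force grid summation", {
  expect_identical(expected_heterozygosity(freq_uniform(), 1000), 1 / 3)

  # oracle: direct sum of 2p(1-p) * phi(p) with the exact constant
  brute <- function(n, Ne = 65, v = 1e-8) {
    p <- seq_len(2 * n - 1) / (2 * n)
    a <- 4 * Ne * v
    w <- p^(a - 1) * (1 - p)^(a - 1)
    sum(2 * p * (1 - p) * w / sum(w))
  }
  expect_equal(expected_heterozygosity(freq_ushaped(), 1000), brute(1000),
    tolerance = 1e-3
  )
  expect_equal(expected_heterozygosity(freq_ushaped(), 1000), 0.1222,
    tolerance = 1e-3
  )
  for (n in c(100, 1e4, 1e6)) {
    appr <- expected_heterozygosity(freq_ushaped(), n, method = "approx")
    exact <- expected_heterozygosity(freq_ushaped(), n, method = "exact")
    expect_lt(abs(appr - exact) / exact, 1e-3)
  }
  # large mutation-drift compound falls back to the exact path with a warning
  expect_warning(
    expected_heterozygosity(freq_ushaped(Ne = 1e5, v = 1e-6), 100),
    "approximation"
  )
})

test_that("the general ratio obeys its structural identities", {
  # ratio is 1 where the locus heterozygosity equals the spectrum mean
  S <- 500 / 3
  p1 <- (1 - sqrt(1 - 2 * (S / 500))) / 2
  expect_equal(ratio_general(0.3, 1000, 500, p1, S), 1, tolerance = 1e-12)

  # shrinkage vanishes with infinite data
  expect_equal(ratio_general(0.3, 1e12, 500, 0.05, S), 1, tolerance = 1e-6)

  # symmetry under p <-> 1-p
  for (p in c(0.01, 0.2, 0.4)) {
    expect_equal(
      ratio_general(0.4, 2000, 800, p, 200),
      ratio_general(0.4, 2000, 800, 1 - p, 200)
    )
  }

  # for fixed low p the ratio decreases toward 1 as power grows
  rs <- sapply(c(500, 5000, 5e4, 5e5), function(n) ratio_general(0.5, n, 1000, 0.01, 1000 / 3))
  expect_true(all(diff(rs) < 0))
  expect_true(all(rs > 1))

  # weighted form reduces to the unweighted one at unit weights
  n <- 400
  expect_identical(
    ratio_general(0.3, sum(rep(1, n)), 900, 0.1, 300),
    ratio_general(0.3, n, 900, 0.1, 300)
  )

  expect_error(ratio_general(1, 100, 10, 0.5, 3), "h2")
  expect_error(ratio_general(0.5, 100, 10, 0, 3), "strictly between")
})

test_that("uniform-spectrum ratios reproduce the printed scenario endpoints", {
  expect_equal(round(ratio_uniform(0.2, 1000, 15e6, 0.5), 2), 0.67)
  expect_equal(round(ratio_uniform(0.8, 1e5, 5e4, 0.5), 2), 0.96)
  # crossing frequency is scenario independent
  for (h2 in c(0.2, 0.8)) {
    for (n in c(1000, 1e5)) {
      root <- (1 - sqrt(1 - 2 / 3)) / 2
      expect_equal(ratio_uniform(h2, n, 5e4, root), 1, tolerance = 1e-9)
    }
  }
  expect_equal(crossing_maf(freq_uniform(), 1000), (1 - sqrt(1 / 3)) / 2,
    tolerance = 1e-12
  )
})

test_that("U-shaped ratios reproduce the printed scenario endpoints", {
  expect_equal(round(ratio_ushaped(0.2, 1e5, 15e6, 0.5), 2), 0.16)
  expect_equal(round(ratio_ushaped(0.8, 1e5, 5e4, 0.5), 2), 0.91)
  six <- unlist(lapply(c(5e4, 8e5, 15e6), function(N) {
    lapply(c(0.2, 0.8), function(h2) ratio_ushaped(h2, 1000, N, 0.5))
  }))
  expect_equal(round(min(six), 2), 0.24)
  expect_equal(round(max(six), 2), 0.30)
  expect_equal(round(crossing_maf(freq_ushaped(), 1000), 3), 0.065)
  expect_equal(round(crossing_maf(freq_ushaped(), 1e5), 2), 0.04)
})

test_that("ratio curves are monotone, consistent with the crossing point, and ordered by spectrum", {
  scenarios <- expand.grid(
    h2 = c(0.2, 0.8), n = c(1000, 1e5), N = c(5e4, 8e5, 15e6)
  )
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    for (model in list(freq_uniform(), freq_ushaped())) {
      curve <- ratio_curve(sc$h2, sc$n, sc$N, model)
      expect_true(all(diff(curve$ratio) < 0))
      cm <- crossing_maf(model, sc$n)
      at_cross <- if (model$kind == "uniform") {
        ratio_uniform(sc$h2, sc$n, sc$N, cm)
      } else {
        ratio_ushaped(sc$h2, sc$n, sc$N, cm)
      }
      expect_equal(at_cross, 1, tolerance = 1e-9)
    }
    # the U-shaped spectrum gives lower ratios for rare variants
    p_low <- c(0.0005, 0.001, 0.005, 0.009)
    expect_true(all(
      ratio_ushaped(sc$h2, sc$n, sc$N, p_low) <
        ratio_uniform(sc$h2, sc$n, sc$N, p_low)
    ))
  }
})

test_that("empirical single-locus ridge ratios track the formula on HWE data", {
  # moderate-size version of the ridge-pair check (the full-size one is in
  # the acceptance suite): per-locus scalar ridge estimates under the two
  # codings are the oracle for the general ratio formula
  sim <- quick_sim(n = 500, N = 200, h2 = 0.5, seed = 31)
  geno <- filtered_geno(sim)
  p <- allele_frequency(geno)
  het <- 2 * p * (1 - p)
  y <- sim$phenotypes$phenotype - mean(sim$phenotypes$phenotype)
  h2 <- 0.5
  sigma_a2 <- 1
  sigma_e2 <- sigma_a2 * (1 - h2) / h2
  lam_c <- sigma_e2 / (sigma_a2 / sum(het))
  lam_cs <- sigma_e2 / (sigma_a2 / ncol(geno))
  Z <- unclass(code_genotypes(geno, gamma = 0))
  W <- unclass(code_genotypes(geno, gamma = -1))
  a_c <- colSums(Z * y) / (colSums(Z^2) + lam_c)
  a_cs <- (colSums(W * y) / (colSums(W^2) + lam_cs)) / sqrt(het)
  emp <- a_cs / a_c
  theo <- ratio_general(h2, nrow(geno), ncol(geno), p, sum(het))
  expect_lt(median(abs(emp - theo) / theo), 0.05)
})
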