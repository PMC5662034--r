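test_that("variance components derive h2, SNP variance and lambda", {
  vc <- variance_components(2, 6, scale_sum = 4)
  expect_equal(vc$h2, 0.25)
  expect_equal(vc$snp_variance, 0.5)
  expect_equal(vc$lambda, 12)
  expect_error(variance_components(-1, 1), "non-negative")
})

test_that("infinite shrinkage drives effects to zero and the mean to the weighted mean", {
  ts <- toy_system()
  M <- code_genotypes(ts$X, gamma = 0)
  # tiny additive variance => enormous lambda
  vc <- variance_components(1e-12, 1, scale_sum = attr(M, "scale_sum"))
  fit <- solve_snp_blup(M, ts$pheno, vc)
  expect_lt(max(abs(fit$b_hat)), 1e-8)
  wmean <- sum(ts$pheno$weight * ts$pheno$phenotype) / sum(ts$pheno$weight)
  expect_equal(fit$mu_hat, wmean, tolerance = 1e-6)
})

test_that("a single locus without intercept matches the scalar ridge formula", {
  set.seed(21)
  X <- cbind(s1 = sample(0:2, 30, replace = TRUE, prob = c(0.25, 0.5, 0.25)))
  rownames(X) <- sprintf("i%02d", 1:30)
  wt <- sample(1:5, 30, replace = TRUE)
  y <- rnorm(30)
  pheno <- tibble::tibble(id = rownames(X), phenotype = y, weight = wt)
  M <- code_genotypes(X, gamma = 0)
  vc <- variance_components(0.7, 1.3, scale_sum = attr(M, "scale_sum"))
  lambda <- vc$sigma_e2 / (vc$sigma_a2 / attr(M, "scale_sum"))
  z <- unclass(M)[, 1]
  expected <- sum(z * wt * y) / (sum(z * wt * z) + lambda)
  fit <- solve_snp_blup(M, pheno, vc, include_intercept = FALSE)
  expect_equal(unname(fit$b_hat), expected, tolerance = 1e-10)
})

test_that("the solver reproduces a dense brute-force mixed-model solve", {
  ts <- toy_system()
  M <- code_genotypes(ts$X, gamma = -0.5)
  s <- attr(M, "scale_sum")
  # choose variances so that lambda = 1
  vc <- variance_components(s, 1, scale_sum = s)
  expect_equal(vc$lambda, 1)
  fit <- solve_snp_blup(M, ts$pheno, vc, method = "mme")
  # independent dense solve of the full mixed-model equations
  Mv <- unclass(M)
  Dm1 <- diag(ts$pheno$weight)
  Xd <- cbind(1, Mv)
  C <- t(Xd) %*% Dm1 %*% Xd + diag(c(0, rep(1, ncol(Mv))))
  sol <- solve(C, t(Xd) %*% Dm1 %*% ts$pheno$phenotype)
  expect_equal(fit$mu_hat, sol[1], tolerance = 1e-8)
  expect_equal(unname(fit$b_hat), unname(sol[-1]), tolerance = 1e-8)
})

test_that("marker-level and individual-level solves give identical fits", {
  sim <- quick_sim(n = 40, N = 90, h2 = 0.5, seed = 22,
                   mean_weight = 8, weight_model = "poisson")
  geno <- filtered_geno(sim)
  for (g in c(0, -1)) {
    M <- code_genotypes(geno, gamma = g)
    vc <- variance_components(1.3, 0.9, scale_sum = attr(M, "scale_sum"))
    f_mme <- solve_snp_blup(M, sim$phenotypes, vc, method = "mme")
    f_gbl <- solve_snp_blup(M, sim$phenotypes, vc, method = "gblup")
    expect_equal(f_mme$mu_hat, f_gbl$mu_hat, tolerance = 1e-8)
    expect_equal(f_mme$dgv, f_gbl$dgv, tolerance = 1e-8)
    expect_equal(f_mme$ase, f_gbl$ase, tolerance = 1e-8)
  }
})

test_that("single-locus shrinkage is monotone in lambda", {
  set.seed(23)
  X <- cbind(s1 = sample(0:2, 40, replace = TRUE, prob = c(0.2, 0.5, 0.3)))
  rownames(X) <- sprintf("i%02d", 1:40)
  pheno <- tibble::tibble(
    id = rownames(X), phenotype = rnorm(40) + 0.5 * X[, 1], weight = 1
  )
  M <- code_genotypes(X, gamma = 0)
  s <- attr(M, "scale_sum")
  b_abs <- sapply(c(0.1, 1, 10, 100), function(lam) {
    vc <- variance_components(s / lam, 1, scale_sum = s)
    abs(unname(solve_snp_blup(M, pheno, vc)$b_hat))
  })
  expect_true(all(diff(b_abs) <= 1e-12))
})

test_that("REML recovers a null heritability on pure-noise phenotypes", {
  hits <- sapply(1:5, function(r) {
    sim <- quick_sim(n = 150, N = 250, h2 = 0.5, seed = 700 + r)
    pheno <- sim$phenotypes
    pheno$phenotype <- withr::with_seed(800 + r, rnorm(nrow(pheno)))
    G <- build_grm(code_genotypes(filtered_geno(sim), gamma = 0))
    fit_greml(G, pheno)$varcomp$h2
  })
  expect_gte(sum(hits < 0.1), 3)
})

test_that("the REML optimum dominates perturbed variance ratios", {
  sim <- quick_sim(n = 120, N = 200, h2 = 0.5, seed = 24)
  G <- build_grm(code_genotypes(filtered_geno(sim), gamma = 0))
  gf <- fit_greml(G, sim$phenotypes)
  vc <- gf$varcomp
  s2 <- vc$sigma_a2 + vc$sigma_e2
  for (h2 in c(0.05, 0.2, 0.35, 0.6, 0.8, 0.95)) {
    # profile the total variance at each perturbed ratio to compare optima
    prof <- optimize(
      function(s) reml_loglik(G, sim$phenotypes, variance_components(s * h2, s * (1 - h2))),
      c(s2 / 50, s2 * 50),
      maximum = TRUE
    )$objective
    expect_gte(gf$logL_reml, prof - 1e-6)
  }
})

test_that("non-PSD relationship matrices are rejected", {
  G <- diag(5)
  G[1, 2] <- G[2, 1] <- 2 # eigenvalue < 0
  pheno <- tibble::tibble(id = as.character(1:5), phenotype = rnorm(5), weight = 1)
  rownames(G) <- colnames(G) <- pheno$id
  expect_error(fit_greml(G, pheno), "positive semi-definite")
  expect_error(fit_greml(G[, 1:4], pheno), "square")
})

test_that("restricted log-likelihood is translation invariant and scale equivariant", {
  sim <- quick_sim(n = 30, N = 50, seed = 25, mean_weight = 6, weight_model = "poisson")
  geno <- filtered_geno(sim)
  G <- build_grm(code_genotypes(geno, gamma = -1))
  pheno <- sim$phenotypes
  vc <- variance_components(0.8, 1.1)
  base <- reml_loglik(G, pheno, vc)

  shifted <- pheno
  shifted$phenotype <- pheno$phenotype + 3.7
  expect_equal(reml_loglik(G, shifted, vc), base, tolerance = 1e-8)

  k <- 2.5
  scaled <- pheno
  scaled$phenotype <- k * pheno$phenotype
  vc_k <- variance_components(k^2 * 0.8, k^2 * 1.1)
  n <- nrow(G)
  expect_equal(reml_loglik(G, scaled, vc_k), base - (n - 1) * log(k),
    tolerance = 1e-8
  )
})

test_that("eigendecomposition and dense-determinant log-likelihoods agree", {
  sim <- quick_sim(n = 30, N = 50, seed = 26, mean_weight = 10, weight_model = "poisson")
  G <- build_grm(code_genotypes(filtered_geno(sim), gamma = 0))
  for (vc in list(variance_components(1, 1), variance_components(0.3, 2.2))) {
    expect_equal(
      reml_loglik(G, sim$phenotypes, vc, method = "eigen"),
      reml_loglik(G, sim$phenotypes, vc, method = "direct"),
      tolerance = 1e-6
    )
  }
})

test_that("back-solved ASE equals the direct SNP-BLUP ASE, and edge cases hold", {
  sim <- quick_sim(n = 35, N = 60, seed = 27)
  geno <- filtered_geno(sim)
  M0 <- code_genotypes(geno, gamma = 0)
  G0 <- build_grm(M0)
  vc <- variance_components(1.1, 0.7, scale_sum = attr(M0, "scale_sum"))
  fit <- solve_snp_blup(M0, sim$phenotypes, vc)
  bs <- backsolve_ase(M0, G0, fit$dgv)
  expect_equal(bs$ase, unname(fit$ase), tolerance = 1e-6)

  expect_true(all(backsolve_ase(M0, G0, rep(0, nrow(G0)))$ase == 0))

  M1 <- code_genotypes(geno, gamma = -1)
  expect_error(backsolve_ase(M1, G0, fit$dgv), "different scaling")
})

test_that("scaled coding shrinks low-MAF effects less while DGV stay close", {
  sim <- quick_sim(
    n = 250, N = 500, h2 = 0.5, gamma_true = -0.5, seed = 28,
    freq_model = freq_ushaped()
  )
  geno <- filtered_geno(sim)
  fit0 <- fit_ase(sim$phenotypes, geno, gamma = 0)
  fit1 <- fit_ase(sim$phenotypes, geno, gamma = -1)
  expect_gt(cor(fit0$dgv, fit1$dgv), 0.95)
  expect_lt(cor(fit0$ase, fit1$ase), cor(fit0$dgv, fit1$dgv))
  low <- fit0$maf < 0.05
  expect_gt(sum(low), 5)
  expect_gt(
    mean(abs(fit1$ase[low])) / mean(abs(fit0$ase[low])),
    1
  )
})

test_that("tidy, glance and augment expose the fit tables", {
  sim <- quick_sim(n = 40, N = 60, seed = 29)
  geno <- filtered_geno(sim)
  fit <- fit_ase(sim$phenotypes, geno, gamma = -1)
  td <- tidy(fit)
  expect_named(td, c("variant_id", "p", "maf", "b_hat", "ase"))
  expect_equal(nrow(td), ncol(geno))
  gl <- glance(fit)
  expect_equal(gl$gamma, -1)
  expect_equal(gl$n_individuals, nrow(geno))
  au <- augment(fit)
  expect_equal(au$predicted, au$dgv + gl$mu_hat)
  expect_equal(fit$dgv, drop(unclass(code_genotypes(geno, -1)) %*% fit$b_hat),
    tolerance = 1e-8
  )
})
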