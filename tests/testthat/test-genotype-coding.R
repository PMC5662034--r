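test_that("allele frequencies are half the mean allele count", {
  expect_equal(unname(allele_frequency(cbind(c(0, 1, 2)))), 0.5)
  expect_equal(unname(allele_frequency(cbind(c(2, 2, 2, 2)))), 1)
  expect_equal(unname(allele_frequency(cbind(c(0, 0, 1, 1)))), 0.25)
  expect_error(allele_frequency(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(allele_frequency(cbind(c(0, 3, 1))), "0, 1 or 2")
})

test_that("variant filters enforce minor-copy and genotype-class rules", {
  n <- 1000
  # 4 minor copies among 1000 individuals: below the default threshold
  g_low <- c(rep(1L, 4), rep(0L, n - 4))
  # 5 minor copies, all heterozygous: fails the genotype-class rule
  g_het <- c(rep(1L, 5), rep(0L, n - 5))
  # 6 minor copies incl. a minor homozygote: passes
  g_ok <- c(2L, rep(1L, 4), rep(0L, n - 5))
  X <- cbind(low = g_low, het_only = g_het, ok = g_ok)
  kept <- suppressMessages(apply_variant_filters(X))
  expect_identical(colnames(kept), "ok")
  rep_tab <- removal_report(kept)
  expect_setequal(rep_tab$variant_id, c("low", "het_only"))
  expect_match(rep_tab$reason[rep_tab$variant_id == "low"], "minor-allele copies")
  expect_match(rep_tab$reason[rep_tab$variant_id == "het_only"], "homozygote")

  # relaxing the genotype-class rule keeps the het-only locus
  kept2 <- suppressMessages(apply_variant_filters(X, require_all_genotypes = FALSE))
  expect_setequal(colnames(kept2), c("het_only", "ok"))

  # monomorphic loci are always removed
  X3 <- cbind(mono = rep(2L, 10), poly = c(2L, rep(1L, 5), rep(0L, 4)))
  kept3 <- suppressMessages(apply_variant_filters(X3, min_minor_copies = 1))
  expect_identical(removal_report(kept3)$reason, "monomorphic")
})

test_that("hand-enumerated toy matrix keeps exactly the passing locus", {
  # 6 individuals; with min_minor_copies = 3: locus a has 2 minor copies
  # (fails), locus b has 3 but no minor homozygote (fails), locus c passes
  X <- cbind(
    a = c(0L, 0L, 0L, 0L, 1L, 1L),
    b = c(0L, 0L, 0L, 1L, 1L, 1L),
    c = c(0L, 0L, 1L, 1L, 2L, 0L)
  )
  kept <- suppressMessages(apply_variant_filters(X, min_minor_copies = 3))
  expect_identical(colnames(kept), "c")
})

test_that("variant filters are idempotent", {
  sim <- quick_sim(n = 80, N = 200, seed = 13)
  once <- suppressMessages(apply_variant_filters(sim$genotypes))
  twice <- suppressMessages(apply_variant_filters(once))
  expect_equal(unclass(once)[, ], unclass(twice)[, ])
  expect_identical(nrow(removal_report(twice)), 0L)
})

test_that("coding centers, scales and records the scale sum", {
  # centering arithmetic at gamma = 0
  X <- cbind(s1 = c(2L, 0L, 0L, 0L))
  M <- code_genotypes(X, gamma = 0)
  expect_equal(unname(M[1, 1]), 2 - 2 * 0.25)
  # heterozygote at p = 0.5 centers to zero for any gamma
  X2 <- cbind(s1 = c(0L, 1L, 2L, 1L))
  expect_equal(unname(code_genotypes(X2, gamma = -1)[2, 1]), 0)

  sim <- quick_sim(n = 100, N = 60, seed = 14)
  geno <- filtered_geno(sim)
  p <- allele_frequency(geno)
  het <- 2 * p * (1 - p)
  for (g in c(0, -0.5, -1)) {
    M <- code_genotypes(geno, gamma = g)
    expect_lt(max(abs(colMeans(M))), 1e-10)
    expect_equal(attr(M, "scale_sum"), sum(het^(g + 1)))
    # definition identity: gamma coding equals centered coding rescaled
    Z <- code_genotypes(geno, gamma = 0)
    expect_equal(unclass(M)[, ], sweep(unclass(Z), 2, het^(g / 2), `*`)[, ],
      tolerance = 1e-12
    )
  }
  # scaled columns have ~unit variance under HWE
  W <- code_genotypes(geno, gamma = -1)
  expect_equal(mean(apply(W, 2, var)), 1, tolerance = 0.1)

  expect_error(code_genotypes(cbind(rep(2L, 4))), "monomorphic")
  expect_error(code_genotypes(geno, gamma = 0.5), "scaling parameter")
})

test_that("GRM matches independent VanRaden formulas at both endpoints", {
  sim <- quick_sim(n = 25, N = 40, seed = 15)
  geno <- filtered_geno(sim)
  p <- allele_frequency(geno)
  n <- nrow(geno)
  # independent elementwise construction
  Zo <- matrix(0, n, ncol(geno))
  Wo <- matrix(0, n, ncol(geno))
  for (j in seq_len(ncol(geno))) {
    Zo[, j] <- geno[, j] - 2 * p[j]
    Wo[, j] <- Zo[, j] / sqrt(2 * p[j] * (1 - p[j]))
  }
  G1o <- matrix(0, n, n)
  G2o <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      G1o[i, k] <- sum(Zo[i, ] * Zo[k, ]) / sum(2 * p * (1 - p))
      G2o[i, k] <- sum(Wo[i, ] * Wo[k, ]) / ncol(geno)
    }
  }
  G1 <- build_grm(code_genotypes(geno, gamma = 0))
  G2 <- build_grm(code_genotypes(geno, gamma = -1))
  expect_equal(unname(G1[, ]), G1o, tolerance = 1e-10)
  expect_equal(unname(G2[, ]), G2o, tolerance = 1e-10)
  expect_equal(attr(G2, "scale_sum"), ncol(geno))
  expect_equal(attr(G1, "scale_sum"), sum(2 * p * (1 - p)))
})

test_that("mean GRM diagonal is near 1 on HWE data for any gamma", {
  sim <- quick_sim(n = 150, N = 300, seed = 16)
  geno <- filtered_geno(sim)
  for (g in c(0, -0.5, -1)) {
    G <- build_grm(code_genotypes(geno, gamma = g))
    expect_equal(mean(diag(G)), 1, tolerance = 0.08)
  }
})

test_that("the ASE transformation and its inverse are exact", {
  expect_equal(ase_transform(c(1, -2), c(0.3, 0.4), 0), c(1, -2))
  expect_equal(ase_transform(1, 0.5, -1), 1 / sqrt(0.5))
  b <- rnorm(10)
  p <- runif(10, 0.05, 0.95)
  for (g in c(0, -0.3, -1)) {
    expect_equal(inverse_ase_transform(ase_transform(b, p, g), p, g), b,
      tolerance = 1e-12
    )
  }
})

test_that("DGV is identical computed from coded effects or from ASE on centered counts", {
  sim <- quick_sim(n = 40, N = 30, seed = 17)
  geno <- filtered_geno(sim)
  M <- code_genotypes(geno, gamma = -1)
  vc <- variance_components(1, 1, scale_sum = attr(M, "scale_sum"))
  fit <- solve_snp_blup(M, sim$phenotypes, vc)
  Z <- code_genotypes(geno, gamma = 0)
  expect_equal(unname(drop(unclass(Z) %*% fit$ase)), unname(fit$dgv),
    tolerance = 1e-8
  )
})
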