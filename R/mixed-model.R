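#' Variance components for the weighted genomic model
#'
#' Bundles the total additive variance, the residual variance per unit weight,
#' and derived quantities: heritability h2 = sigma_a2/(sigma_a2 + sigma_e2),
#' and, when the coding's scale sum is known, the per-locus SNP variance
#' sigma_a2 / s_gamma and the ridge penalty lambda = sigma_e2 / snp_variance.
#'
#' @param sigma_a2 Total additive genetic variance (>= 0).
#' @param sigma_e2 Residual variance for an observation of unit weight (>= 0).
#' @param scale_sum Optional coding scale sum \eqn{s_\gamma} used to derive
#'   the SNP variance and lambda.
#' @return An object of class `varcomp`.
#' @export
variance_components <- function(sigma_a2, sigma_e2, scale_sum = NULL) {
  if (!is.numeric(sigma_a2) || length(sigma_a2) != 1L || sigma_a2 < 0) {
    abort("`sigma_a2` must be a single non-negative value.")
  }
  if (!is.numeric(sigma_e2) || length(sigma_e2) != 1L || sigma_e2 < 0) {
    abort("`sigma_e2` must be a single non-negative value.")
  }
  snp_variance <- if (!is.null(scale_sum)) sigma_a2 / scale_sum else NA_real_
  lambda <- if (!is.null(scale_sum) && sigma_a2 > 0) sigma_e2 / snp_variance else NA_real_
  structure(
    list(
      sigma_a2 = sigma_a2,
      sigma_e2 = sigma_e2,
      h2 = sigma_a2 / (sigma_a2 + sigma_e2),
      snp_variance = snp_variance,
      lambda = lambda
    ),
    class = "varcomp"
  )
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf(
    "<varcomp> sigma_a2 = %.6g, sigma_e2 = %.6g, h2 = %.4f\n",
    x$sigma_a2, x$sigma_e2, x$h2
  ))
  invisible(x)
}

check_varcomp <- function(varcomp) {
  if (!inherits(varcomp, "varcomp")) {
    abort("`varcomp` must be created by `variance_components()` or `fit_greml()`.")
  }
  invisible(varcomp)
}

## Align a phenotype table to a set of row ids; returns list(y, wt, id).
check_phenotypes <- function(pheno, ids = NULL) {
  if (!is.data.frame(pheno) || !"phenotype" %in% names(pheno)) {
    abort("`pheno` must be a data frame with a `phenotype` column (and optionally `id`, `weight`).")
  }
  wt <- if ("weight" %in% names(pheno)) pheno$weight else rep(1, nrow(pheno))
  if (any(!is.finite(wt)) || any(wt <= 0)) {
    abort("All phenotype weights must be strictly positive.")
  }
  id <- if ("id" %in% names(pheno)) as.character(pheno$id) else NULL
  y <- pheno$phenotype
  if (!is.null(ids) && !is.null(id)) {
    if (!setequal(ids, id) || length(ids) != length(id)) {
      abort("Phenotype ids do not match the genotyped individuals.")
    }
    ord <- match(ids, id)
    y <- y[ord]
    wt <- wt[ord]
    id <- id[ord]
  } else if (!is.null(ids) && length(ids) != length(y)) {
    abort("Phenotype rows do not match the number of genotyped individuals.")
  }
  list(y = as.numeric(y), wt = as.numeric(wt), id = id)
}

#' Solve the weighted SNP-BLUP model at fixed variance components
#'
#' Jointly solves for the intercept (fixed) and the coded-scale marker
#' effects (random, ridge penalty \eqn{\lambda = \sigma_e^2 s_\gamma /
#' \sigma_a^2}) in
#' \deqn{y = 1\mu + M b + e, \quad b \sim N(0, I\sigma_a^2/s_\gamma), \quad
#'   e \sim N(0, D\sigma_e^2),}
#' where D is diagonal with elements 1/weight. When the number of loci
#' exceeds the number of individuals the equivalent n x n individual-level
#' (GBLUP) system is solved instead of the N x N marker equations; the two
#' routes give identical solutions.
#'
#' @param M Coded matrix from [code_genotypes()].
#' @param pheno Phenotype data frame with columns `id` (optional),
#'   `phenotype`, `weight` (optional, default 1).
#' @param varcomp A `varcomp` object with positive variances.
#' @param method `"auto"` (n x n route when N > n), `"gblup"` or `"mme"`.
#' @param include_intercept Fit the general mean (default TRUE; FALSE fits a
#'   pure ridge regression through the origin).
#' @return An object of class `ase_fit` with components `mu_hat`, `b_hat`
#'   (coded scale), `ase`, `dgv`, `fitted` (dgv + mu), `varcomp`,
#'   `logL_reml`, `gamma`, `p`, `maf`. Use [tidy()], [glance()] and
#'   [augment()] to extract tables.
#' @export
solve_snp_blup <- function(M, pheno, varcomp,
                           method = c("auto", "gblup", "mme"),
                           include_intercept = TRUE) {
  check_coded(M)
  check_varcomp(varcomp)
  method <- match.arg(method)
  if (varcomp$sigma_a2 <= 0 || varcomp$sigma_e2 <= 0) {
    abort("`solve_snp_blup()` requires strictly positive variance components.")
  }
  n <- nrow(M)
  N <- ncol(M)
  ph <- check_phenotypes(pheno, ids = rownames(M))
  y <- ph$y
  wt <- ph$wt
  s <- attr(M, "scale_sum")
  gamma <- attr(M, "gamma")
  p <- attr(M, "freq_used")
  sigma_b2 <- varcomp$sigma_a2 / s
  lambda <- varcomp$sigma_e2 / sigma_b2
  if (method == "auto") method <- if (N > n) "gblup" else "mme"

  Mv <- unclass(M)
  if (method == "gblup") {
    V <- varcomp$sigma_a2 * tcrossprod(Mv) / s
    diag(V) <- diag(V) + varcomp$sigma_e2 / wt
    ch <- tryCatch(chol(V), error = function(e) {
      abort("The phenotypic covariance matrix is singular; cannot solve the model.")
    })
    Viy <- backsolve(ch, forwardsolve(ch, y, upper.tri = TRUE, transpose = TRUE))
    if (include_intercept) {
      Vi1 <- backsolve(ch, forwardsolve(ch, rep(1, n), upper.tri = TRUE, transpose = TRUE))
      mu_hat <- sum(Vi1 * y) / sum(Vi1)
      Vir <- Viy - mu_hat * Vi1
    } else {
      mu_hat <- 0
      Vir <- Viy
    }
    b_hat <- drop(sigma_b2 * crossprod(Mv, Vir))
  } else {
    MtD <- t(Mv * wt) # t(M) %*% D^{-1}
    Cbb <- MtD %*% Mv
    diag(Cbb) <- diag(Cbb) + lambda
    if (include_intercept) {
      C <- rbind(
        c(sum(wt), colSums(Mv * wt)),
        cbind(rowSums(MtD), Cbb)
      )
      rhs <- c(sum(wt * y), drop(MtD %*% y))
      sol <- tryCatch(solve(C, rhs), error = function(e) {
        abort("The mixed-model equations are singular; cannot solve the model.")
      })
      mu_hat <- unname(sol[1])
      b_hat <- unname(sol[-1])
    } else {
      mu_hat <- 0
      b_hat <- drop(solve(Cbb, MtD %*% y))
    }
  }
  names(b_hat) <- colnames(M)
  dgv <- drop(Mv %*% b_hat)
  names(dgv) <- rownames(M)
  logL <- if (include_intercept) {
    reml_loglik(build_grm(M), pheno, varcomp)
  } else {
    NA_real_
  }
  new_ase_fit(
    mu_hat = mu_hat, b_hat = b_hat,
    ase = ase_transform(b_hat, p, gamma),
    dgv = dgv, varcomp = varcomp, logL_reml = logL,
    gamma = gamma, p = p, sample_ids = ph$id %||% rownames(M)
  )
}

new_ase_fit <- function(mu_hat, b_hat, ase, dgv, varcomp, logL_reml, gamma, p,
                        sample_ids = NULL) {
  structure(
    list(
      mu_hat = mu_hat,
      b_hat = b_hat,
      ase = ase,
      dgv = dgv,
      fitted = dgv + mu_hat,
      varcomp = varcomp,
      logL_reml = logL_reml,
      gamma = gamma,
      p = p,
      maf = minor_allele_frequency(p),
      sample_ids = sample_ids
    ),
    class = "ase_fit"
  )
}

#' @export
print.ase_fit <- function(x, ...) {
  cat(sprintf(
    "<ase_fit> gamma = %g, %d individuals, %d loci\n  mu_hat = %.4g, h2 = %.4f, logL(REML) = %.4f\n",
    x$gamma, length(x$dgv), length(x$ase), x$mu_hat, x$varcomp$h2, x$logL_reml
  ))
  invisible(x)
}

#' @export
tidy.ase_fit <- function(x, ...) {
  tibble::tibble(
    variant_id = names(x$b_hat) %||% as.character(seq_along(x$b_hat)),
    p = unname(x$p),
    maf = unname(x$maf),
    b_hat = unname(x$b_hat),
    ase = unname(x$ase)
  )
}

#' @export
glance.ase_fit <- function(x, ...) {
  tibble::tibble(
    mu_hat = x$mu_hat,
    sigma_a2 = x$varcomp$sigma_a2,
    sigma_e2 = x$varcomp$sigma_e2,
    h2 = x$varcomp$h2,
    lambda = x$varcomp$lambda,
    logL_reml = x$logL_reml,
    gamma = x$gamma,
    n_individuals = length(x$dgv),
    n_snps = length(x$ase)
  )
}

#' @export
augment.ase_fit <- function(x, ...) {
  tibble::tibble(
    id = x$sample_ids %||% as.character(seq_along(x$dgv)),
    dgv = unname(x$dgv),
    predicted = unname(x$fitted)
  )
}

## Orthonormal basis of the contrast space (orthogonal complement of x).
contrast_basis <- function(x) {
  qr.Q(qr(cbind(x)), complete = TRUE)[, -1, drop = FALSE]
}

#' Estimate variance components by REML for the weighted GBLUP model
#'
#' Restricted maximum likelihood for
#' \deqn{y = 1\mu + g + e, \quad g \sim N(0, G\sigma_a^2), \quad
#'   e \sim N(0, D\sigma_e^2),}
#' with D diagonal (1/weight). The weights are folded in by pre-multiplying
#' with the square-root weight diagonal, the intercept is projected out with
#' an explicit orthonormal contrast basis, and the restricted likelihood is
#' profiled down to a one-dimensional deterministic search over the log
#' variance ratio \eqn{\log(\sigma_e^2/\sigma_a^2)} on `[-10, 10]`
#' (Brent-type, tolerance 1e-8); no random initialization is used.
#'
#' @param G Symmetric positive semi-definite genomic relationship matrix.
#' @param pheno Phenotype data frame (`id`, `phenotype`, `weight`).
#' @param interval Search interval for the log variance ratio.
#' @param tol Convergence tolerance of the one-dimensional search.
#' @return An object of class `greml_fit`: a list with `varcomp`,
#'   `logL_reml` (restricted log-likelihood at the optimum, computed on the
#'   original data scale), `ratio` (sigma_e2/sigma_a2), and `boundary`
#'   (TRUE when the optimum lies at the edge of the search interval).
#' @export
fit_greml <- function(G, pheno, interval = c(-10, 10), tol = 1e-8) {
  if (!is.matrix(G) || nrow(G) != ncol(G)) {
    abort("`G` must be a square relationship matrix.")
  }
  if (max(abs(G - t(G))) > 1e-8 * max(1, max(abs(G)))) {
    abort("`G` must be symmetric.")
  }
  n <- nrow(G)
  ph <- check_phenotypes(pheno, ids = rownames(G))
  sw <- sqrt(ph$wt)
  yt <- sw * ph$y
  Gt <- G * tcrossprod(sw)
  K <- contrast_basis(sw)
  B <- crossprod(K, Gt %*% K)
  B <- (B + t(B)) / 2
  ee <- eigen(B, symmetric = TRUE)
  if (min(ee$values) < -1e-6 * max(1, max(ee$values))) {
    abort("`G` is not positive semi-definite (beyond tolerance).")
  }
  xi <- pmax(ee$values, 0)
  eta <- drop(crossprod(ee$vectors, crossprod(K, yt)))
  m <- n - 1L

  crit <- function(t) {
    delta <- exp(t)
    ss <- sum(eta^2 / (xi + delta))
    -0.5 * (m * log(ss) + sum(log(xi + delta)))
  }
  opt <- optimize(crit, interval = interval, maximum = TRUE, tol = tol)
  delta <- exp(opt$maximum)
  sigma_a2 <- sum(eta^2 / (xi + delta)) / m
  sigma_e2 <- delta * sigma_a2
  if (!is.finite(sigma_a2) || sigma_a2 <= 0) {
    abort("REML failed: profiled additive variance is not positive.")
  }
  vc <- variance_components(sigma_a2, sigma_e2)
  boundary <- min(abs(opt$maximum - interval)) < 1e-3
  structure(
    list(
      varcomp = vc,
      logL_reml = reml_loglik(G, pheno, vc),
      ratio = delta,
      boundary = boundary,
      n = n
    ),
    class = "greml_fit"
  )
}

#' @export
print.greml_fit <- function(x, ...) {
  cat(sprintf(
    "<greml_fit> sigma_a2 = %.5g, sigma_e2 = %.5g, h2 = %.4f, logL(REML) = %.4f%s\n",
    x$varcomp$sigma_a2, x$varcomp$sigma_e2, x$varcomp$h2, x$logL_reml,
    if (x$boundary) " [boundary]" else ""
  ))
  invisible(x)
}

#' @export
glance.greml_fit <- function(x, ...) {
  tibble::tibble(
    sigma_a2 = x$varcomp$sigma_a2,
    sigma_e2 = x$varcomp$sigma_e2,
    h2 = x$varcomp$h2,
    logL_reml = x$logL_reml,
    ratio = x$ratio,
    boundary = x$boundary,
    n_individuals = x$n
  )
}

#' Restricted log-likelihood of the weighted single-GRM model
#'
#' Evaluates the restricted log-likelihood of
#' \eqn{y = 1\mu + g + e} with \eqn{V = G\sigma_a^2 + D\sigma_e^2} at given
#' variance components:
#' \deqn{\ell_R = -\tfrac12\left[(n-1)\log 2\pi + \log|V| +
#'   \log(1'V^{-1}1) + y'Py\right].}
#' Comparable across scaling parameters because the fixed-effect design (an
#' intercept only) is unchanged. The `"eigen"` method evaluates the same
#' quantity through the contrast-space eigendecomposition used by
#' [fit_greml()]; both methods agree to numerical precision.
#'
#' @inheritParams fit_greml
#' @param varcomp Variance components with positive variances.
#' @param method `"direct"` (dense Cholesky) or `"eigen"`.
#' @return The restricted log-likelihood (a scalar).
#' @export
reml_loglik <- function(G, pheno, varcomp, method = c("direct", "eigen")) {
  check_varcomp(varcomp)
  method <- match.arg(method)
  if (varcomp$sigma_a2 < 0 || varcomp$sigma_e2 <= 0) {
    abort("`reml_loglik()` requires sigma_e2 > 0 and sigma_a2 >= 0.")
  }
  n <- nrow(G)
  ph <- check_phenotypes(pheno, ids = rownames(G))
  y <- ph$y
  wt <- ph$wt
  if (method == "direct") {
    V <- varcomp$sigma_a2 * G
    diag(V) <- diag(V) + varcomp$sigma_e2 / wt
    ch <- chol(V)
    logdetV <- 2 * sum(log(diag(ch)))
    Viy <- backsolve(ch, forwardsolve(ch, y, upper.tri = TRUE, transpose = TRUE))
    Vi1 <- backsolve(ch, forwardsolve(ch, rep(1, n), upper.tri = TRUE, transpose = TRUE))
    xvx <- sum(Vi1)
    ypy <- sum(y * Viy) - sum(Viy)^2 / xvx
    -0.5 * ((n - 1) * log(2 * pi) + logdetV + log(xvx) + ypy)
  } else {
    sw <- sqrt(wt)
    yt <- sw * y
    Gt <- G * tcrossprod(sw)
    K <- contrast_basis(sw)
    B <- crossprod(K, Gt %*% K)
    B <- (B + t(B)) / 2
    ee <- eigen(B, symmetric = TRUE)
    xi <- pmax(ee$values, 0)
    eta <- drop(crossprod(ee$vectors, crossprod(K, yt)))
    d <- varcomp$sigma_a2 * xi + varcomp$sigma_e2
    m <- n - 1L
    contrast <- -0.5 * (m * log(2 * pi) + sum(log(d)) + sum(eta^2 / d))
    # map from the weight-transformed contrast scale back to the data scale
    contrast + 0.5 * sum(log(wt)) - 0.5 * log(sum(wt))
  }
}

#' Back-solve allele substitution effects from direct genomic values
#'
#' Recovers the coded-scale marker effects from a GBLUP solution via
#' \eqn{\hat b = s_\gamma^{-1} M' G^{-} \hat g} (Moore-Penrose pseudo-inverse
#' with relative tolerance 1e-10 when G is singular) and transforms them to
#' ASE. Given matching inputs this equals the directly estimated SNP-BLUP
#' solution.
#'
#' @param M Coded matrix used to build `G`.
#' @param G Genomic relationship matrix built from `M` (same gamma).
#' @param dgv Direct genomic values \eqn{\hat g} for the same individuals.
#' @return A tibble with columns `variant_id`, `b_hat`, `ase`.
#' @export
backsolve_ase <- function(M, G, dgv) {
  check_coded(M)
  if (!isTRUE(all.equal(attr(M, "gamma"), attr(G, "gamma")))) {
    abort("`M` and `G` were built with different scaling parameters.")
  }
  if (length(dgv) != nrow(G)) {
    abort("`dgv` must have one value per individual.")
  }
  s <- attr(M, "scale_sum")
  ee <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- 1e-10 * max(ee$values)
  pos <- ee$values > tol
  Ginv_dgv <- ee$vectors[, pos, drop = FALSE] %*%
    (crossprod(ee$vectors[, pos, drop = FALSE], dgv) / ee$values[pos])
  b_hat <- unname(drop(crossprod(unclass(M), Ginv_dgv))) / s
  p <- attr(M, "freq_used")
  tibble::tibble(
    variant_id = colnames(M) %||% as.character(seq_along(b_hat)),
    b_hat = b_hat,
    ase = unname(ase_transform(b_hat, p, attr(M, "gamma")))
  )
}

#' Fit the full pipeline for one scaling parameter
#'
#' Convenience wrapper: codes the genotypes at `gamma`, builds the GRM,
#' estimates variance components by REML (unless `varcomp` is supplied) and
#' solves the SNP-BLUP model.
#'
#' @param pheno Phenotype data frame (`id`, `phenotype`, `weight`).
#' @param genotypes Genotype matrix (individuals x loci, values 0/1/2).
#' @param gamma Scaling parameter in `[-1, 0]`.
#' @param varcomp Optional fixed variance components; default is REML.
#' @param freq Optional allele frequencies for the coding.
#' @return An `ase_fit` object.
#' @examples
#' sim <- simulate_dataset(n_individuals = 80, n_snps = 120, h2 = 0.5, seed = 1)
#' geno <- apply_variant_filters(sim$genotypes)
#' fit <- fit_ase(sim$phenotypes, geno, gamma = -1)
#' glance(fit)
#' @export
fit_ase <- function(pheno, genotypes, gamma = 0, varcomp = NULL, freq = NULL) {
  M <- code_genotypes(genotypes, gamma = gamma, freq = freq)
  G <- build_grm(M)
  if (is.null(varcomp)) {
    gf <- fit_greml(G, pheno)
    varcomp <- variance_components(
      gf$varcomp$sigma_a2, gf$varcomp$sigma_e2,
      scale_sum = attr(M, "scale_sum")
    )
  } else {
    check_varcomp(varcomp)
    varcomp <- variance_components(varcomp$sigma_a2, varcomp$sigma_e2,
      scale_sum = attr(M, "scale_sum")
    )
  }
  solve_snp_blup(M, pheno, varcomp)
}
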