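#' Sample allele frequencies from a spectrum model
#'
#' Draws per-locus frequencies of the counted allele from the discrete grid
#' p = 1/2n, ..., (2n-1)/2n with probabilities given by the model's density,
#' so the simulated spectrum has exactly the support used by the closed-form
#' ratio theory.
#'
#' @param model A [freq_uniform()] or [freq_ushaped()] model.
#' @param n_snps Number of loci to draw.
#' @param n_individuals Number of diploid individuals (defines the grid).
#' @param seed Optional integer seed; when given, sampling is reproducible
#'   and the caller's random-number state is left untouched.
#' @return Numeric vector of `n_snps` frequencies, all strictly inside (0, 1).
#' @export
sample_allele_frequencies <- function(model, n_snps, n_individuals, seed = NULL) {
  check_freq_model(model)
  n_snps <- check_count(n_snps, "n_snps", min = 0)
  if (n_snps == 0L) return(numeric(0))
  d <- freq_density(model, n_individuals)
  with_optional_seed(seed, {
    sample(d$p, n_snps, replace = TRUE, prob = d$phi)
  })
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

#' Sample Hardy-Weinberg genotypes
#'
#' Each genotype is the sum of two independent allele draws at the locus
#' frequency, i.e. Binomial(2, p): genotype classes have the Hardy-Weinberg
#' proportions p^2, 2p(1-p), (1-p)^2.
#'
#' @param frequencies Per-locus counted-allele frequencies, strictly in (0, 1).
#' @param n_individuals Number of individuals to draw.
#' @param seed Optional integer seed.
#' @return Integer matrix (individuals x loci, values 0/1/2) with sample ids
#'   `ind0001, ...` and variant ids `snp0001, ...` (unless `frequencies` is
#'   named); the nominal frequencies are attached as attribute
#'   `"nominal_freq"`.
#' @export
sample_genotypes <- function(frequencies, n_individuals, seed = NULL) {
  if (length(frequencies) == 0L) {
    abort("`frequencies` must contain at least one locus.")
  }
  if (any(frequencies <= 0 | frequencies >= 1)) {
    abort("All `frequencies` must lie strictly between 0 and 1.")
  }
  n <- check_count(n_individuals, "n_individuals", min = 1)
  N <- length(frequencies)
  X <- with_optional_seed(seed, {
    matrix(
      rbinom(n * N, size = 2L, prob = rep(frequencies, each = n)),
      nrow = n, ncol = N
    )
  })
  dimnames(X) <- list(
    sprintf("ind%04d", seq_len(n)),
    names(frequencies) %||% sprintf("snp%04d", seq_len(N))
  )
  attr(X, "nominal_freq") <- unname(frequencies)
  X
}

#' Simulate true additive effects with MAF-dependent variance
#'
#' Draws zero-mean normal per-locus allele substitution effects with sampling
#' variance proportional to \eqn{(2p_j(1-p_j))^{\gamma_{true}}};
#' `gamma_true = 0` gives equal effect variances (the prior implied by
#' centered-only coding) and `gamma_true = -1` makes every locus contribute
#' equal expected genetic variance (the prior implied by centered-and-scaled
#' coding). The variances are then deterministically rescaled so that
#' \eqn{\sum_j 2p_j(1-p_j) Var(\alpha_j)} equals `total_additive_variance`.
#'
#' @param frequencies Per-locus frequencies, strictly in (0, 1).
#' @param total_additive_variance Target total additive variance (> 0).
#' @param gamma_true Architecture exponent in `[-1, 0]`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `variant_id`, `p`, `effect` (trait units per
#'   allele copy) and `effect_variance` (the sampling variance used), with
#'   `total_additive_variance` attached as an attribute.
#' @export
simulate_true_effects <- function(frequencies, total_additive_variance = 1,
                                  gamma_true = 0, seed = NULL) {
  if (any(frequencies <= 0 | frequencies >= 1)) {
    abort("All `frequencies` must lie strictly between 0 and 1.")
  }
  if (!is.numeric(total_additive_variance) || length(total_additive_variance) != 1L ||
      total_additive_variance <= 0) {
    abort("`total_additive_variance` must be a single positive value.")
  }
  check_gamma(gamma_true)
  het <- 2 * frequencies * (1 - frequencies)
  v <- het^gamma_true
  v <- v * total_additive_variance / sum(het * v)
  eff <- with_optional_seed(seed, rnorm(length(v), mean = 0, sd = sqrt(v)))
  out <- tibble::tibble(
    variant_id = names(frequencies) %||% sprintf("snp%04d", seq_along(v)),
    p = unname(frequencies),
    effect = eff,
    effect_variance = unname(v)
  )
  attr(out, "total_additive_variance") <- total_additive_variance
  out
}

#' Sample effective record counts (weights)
#'
#' Emulates per-individual information content such as the number of
#' daughters behind a bull's deviation phenotype. The `"constant"` model
#' gives every individual the (rounded) mean; the `"poisson"` model draws
#' 1 + Poisson(mean - 1), a shifted count with minimum 1 and the requested
#' mean.
#'
#' @param n_individuals Number of individuals (0 allowed, giving an empty
#'   vector).
#' @param mean_weight Expected effective record count (>= 1).
#' @param weight_model `"constant"` or `"poisson"`.
#' @param seed Optional integer seed.
#' @return Integer vector of strictly positive weights.
#' @export
sample_weights <- function(n_individuals, mean_weight = 1,
                           weight_model = c("constant", "poisson"),
                           seed = NULL) {
  n <- check_count(n_individuals, "n_individuals", min = 0)
  weight_model <- match.arg(weight_model)
  if (!is.numeric(mean_weight) || length(mean_weight) != 1L || mean_weight < 1) {
    abort("`mean_weight` must be a single value >= 1.")
  }
  if (n == 0L) return(integer(0))
  if (weight_model == "constant") {
    rep(as.integer(round(mean_weight)), n)
  } else {
    with_optional_seed(seed, 1L + rpois(n, mean_weight - 1))
  }
}

#' Simulate weighted phenotypes from true effects
#'
#' Phenotypes follow the weighted additive model
#' \deqn{y_i = \mu + \sum_j (x_{ij} - 2p_j)\,\alpha_j + e_i, \quad
#'   e_i \sim N(0, \sigma_e^2 / wt_i),}
#' where the centering uses the generative frequencies of `effects` and the
#' residual variance per unit weight is set from the heritability:
#' \eqn{\sigma_e^2 = \sigma_a^2 (1-h^2)/h^2}.
#'
#' @param X Genotype matrix from [sample_genotypes()].
#' @param effects Tibble from [simulate_true_effects()] (same loci as `X`).
#' @param h2 Heritability in (0, 1).
#' @param weights Strictly positive effective record counts (default all 1).
#' @param intercept General mean (default 0).
#' @param seed Optional integer seed.
#' @return A tibble with columns `id`, `phenotype`, `weight` and `true_gv`
#'   (the noiseless centered genetic value, kept for parameter-recovery
#'   checks).
#' @export
simulate_phenotypes <- function(X, effects, h2, weights = NULL, intercept = 0,
                                seed = NULL) {
  check_genotypes(X)
  check_h2(h2)
  if (!is.data.frame(effects) || !all(c("p", "effect") %in% names(effects))) {
    abort("`effects` must come from `simulate_true_effects()`.")
  }
  if (nrow(effects) != ncol(X)) {
    abort("`effects` must have one row per locus of `X`.")
  }
  n <- nrow(X)
  weights <- weights %||% rep(1, n)
  if (length(weights) != n || any(!is.finite(weights)) || any(weights <= 0)) {
    abort("`weights` must be strictly positive, one per individual.")
  }
  sigma_a2 <- attr(effects, "total_additive_variance") %||%
    sum(2 * effects$p * (1 - effects$p) * effects$effect_variance)
  sigma_e2 <- sigma_a2 * (1 - h2) / h2
  g <- unname(drop(sweep(X, 2, 2 * effects$p) %*% effects$effect))
  e <- with_optional_seed(seed, rnorm(n, 0, sqrt(sigma_e2 / weights)))
  tibble::tibble(
    id = rownames(X) %||% sprintf("ind%04d", seq_len(n)),
    phenotype = intercept + g + e,
    weight = weights,
    true_gv = g
  )
}

#' Simulate a complete genotype-phenotype dataset
#'
#' One-call generator tying together frequency sampling, Hardy-Weinberg
#' genotypes, a MAF-dependent additive architecture, effective record
#' weights and weighted phenotypes. Loci are simulated in linkage
#' equilibrium, matching the assumptions of the single-locus ratio theory.
#'
#' @param n_individuals,n_snps Dataset dimensions.
#' @param h2 Heritability in (0, 1).
#' @param gamma_true Architecture exponent in `[-1, 0]`; see
#'   [simulate_true_effects()].
#' @param total_additive_variance Total additive variance (default 1).
#' @param mean_weight,weight_model Effective record counts; see
#'   [sample_weights()].
#' @param intercept General mean of the phenotypes.
#' @param freq_model Frequency spectrum model (default uniform).
#' @param seed Optional integer seed controlling all five sampling stages.
#' @return A list of class `ase_sim` with elements `genotypes` (matrix),
#'   `phenotypes` (tibble), `effects` (tibble), `frequencies` (nominal
#'   per-locus frequencies) and `params`.
#' @examples
#' sim <- simulate_dataset(n_individuals = 100, n_snps = 200, h2 = 0.5, seed = 42)
#' str(sim$phenotypes)
#' @export
simulate_dataset <- function(n_individuals, n_snps, h2, gamma_true = 0,
                             total_additive_variance = 1,
                             mean_weight = 1, weight_model = "constant",
                             intercept = 0, freq_model = freq_uniform(),
                             seed = NULL) {
  n <- check_count(n_individuals, "n_individuals", min = 2)
  N <- check_count(n_snps, "n_snps", min = 1)
  check_h2(h2)
  seeds <- if (is.null(seed)) {
    vector("list", 5)
  } else {
    as.list(as.integer(seed) + 0:4)
  }
  freq <- sample_allele_frequencies(freq_model, N, n, seed = seeds[[1]])
  names(freq) <- sprintf("snp%04d", seq_len(N))
  X <- sample_genotypes(freq, n, seed = seeds[[2]])
  effects <- simulate_true_effects(freq, total_additive_variance, gamma_true,
    seed = seeds[[3]]
  )
  weights <- sample_weights(n, mean_weight, weight_model, seed = seeds[[4]])
  pheno <- simulate_phenotypes(X, effects, h2,
    weights = weights,
    intercept = intercept, seed = seeds[[5]]
  )
  structure(
    list(
      genotypes = X,
      phenotypes = pheno,
      effects = effects,
      frequencies = freq,
      params = list(
        n_individuals = n, n_snps = N, h2 = h2, gamma_true = gamma_true,
        total_additive_variance = total_additive_variance,
        mean_weight = mean_weight, weight_model = weight_model,
        intercept = intercept, freq_model = freq_model, seed = seed
      )
    ),
    class = "ase_sim"
  )
}

#' @export
print.ase_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<ase_sim> %d individuals x %d loci, h2 = %g, gamma_true = %g, %s spectrum\n",
    p$n_individuals, p$n_snps, p$h2, p$gamma_true, p$freq_model$kind
  ))
  invisible(x)
}
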