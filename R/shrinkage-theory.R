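# Euler-Mascheroni constant, hard-coded to 20 digits. Distinct from the
# allele-count scaling parameter, which is always called `gamma` here.
EULER_MASCHERONI <- 0.57721566490153286061

#' Closed-form approximation of the U-shaped normalizing constant
#'
#' The U-shaped (mutation-drift) allele-frequency density on the grid
#' p = 1/2n, ..., (2n-1)/2n has normalizing constant
#' \eqn{C = (\sum_p p^{a-1}(1-p)^{a-1})^{-1}} with \eqn{a = 4 N_e v}. When
#' \eqn{a \approx 0} the sum is close to a symmetrized harmonic sum, giving the
#' closed-form approximation
#' \deqn{C^* = \frac{1}{4n}\left(\ln(2n-1) + \frac{1}{4n-2} + \gamma_{EM}\right)^{-1},}
#' where \eqn{\gamma_{EM}} is the Euler-Mascheroni constant (not the allele-count
#' scaling parameter, which this package always calls `gamma` in the coding
#' sense).
#'
#' @param n_individuals Number of diploid individuals n (>= 2).
#' @return The approximate constant \eqn{C^*}.
#' @seealso [ushaped_constant_exact()] for the exact grid sum.
#' @examples
#' cstar(1000) # ~3.057e-5
#' @export
cstar <- function(n_individuals) {
  n <- check_count(n_individuals, "n_individuals", min = 2)
  (1 / (4 * n)) / (log(2 * n - 1) + 1 / (4 * n - 2) + EULER_MASCHERONI)
}

#' Exact normalizing constant of the U-shaped density on the grid
#'
#' Direct evaluation of \eqn{C = (\sum_p p^{a-1}(1-p)^{a-1})^{-1}} over
#' p = 1/2n, ..., (2n-1)/2n, with \eqn{a = 4 N_e v}. With `Ne * v = 0` this is
#' the inverse symmetrized harmonic sum \eqn{1/(4n H_{2n-1})} that [cstar()]
#' approximates.
#'
#' @inheritParams cstar
#' @param Ne Effective population size.
#' @param v Mutation rate.
#' @export
ushaped_constant_exact <- function(n_individuals, Ne = 65, v = 1e-8) {
  n <- check_count(n_individuals, "n_individuals", min = 2)
  p <- freq_grid(n)
  a <- 4 * Ne * v
  1 / sum(exp((a - 1) * (log(p) + log1p(-p))))
}

#' Expected heterozygosity E[2p(1-p)] under a frequency model
#'
#' The mean per-locus variance factor 2p(1-p) under the model's spectrum. For
#' the uniform spectrum this is exactly 1/3. For the U-shaped spectrum the
#' default is the closed-form approximation \eqn{2 C^* (2n-1)}, valid when
#' \eqn{4 N_e v \approx 0}; when \eqn{4 N_e v \ge 10^{-3}} the approximation is
#' unreliable and the exact grid summation is used instead, with a warning.
#'
#' @param model A [freq_uniform()] or [freq_ushaped()] model.
#' @param n_individuals Number of diploid individuals defining the grid.
#' @param method `"auto"` (default: approximation when valid, exact otherwise),
#'   `"approx"` (force \eqn{2C^*(2n-1)}), or `"exact"` (grid sum of
#'   \eqn{2p(1-p)\phi(p)}).
#' @return Expected heterozygosity, a value in (0, 0.5).
#' @examples
#' expected_heterozygosity(freq_uniform(), 1000) # 1/3
#' expected_heterozygosity(freq_ushaped(), 1000) # ~0.1222
#' @export
expected_heterozygosity <- function(model, n_individuals,
                                    method = c("auto", "approx", "exact")) {
  check_freq_model(model)
  method <- match.arg(method)
  n <- check_count(n_individuals, "n_individuals", min = 2)
  if (model$kind == "uniform") {
    return(1 / 3)
  }
  a <- 4 * model$Ne * model$v
  if (method == "auto") {
    if (a >= 1e-3) {
      warn(sprintf(
        "4*Ne*v = %g is not ~0; the closed-form C* approximation does not apply. Using exact grid summation.",
        a
      ))
      method <- "exact"
    } else {
      method <- "approx"
    }
  }
  if (method == "approx") {
    2 * cstar(n) * (2 * n - 1)
  } else {
    d <- freq_density(model, n)
    sum(2 * d$p * (1 - d$p) * d$phi)
  }
}

#' Theoretical ratio of ASE from scaled vs unscaled allele counts
#'
#' Single-locus ridge-regression theory for the ratio of the allele
#' substitution effect (ASE) estimated with centered-and-scaled allele counts
#' (RRcs) to the ASE estimated with centered-only counts (RRc):
#' \deqn{\frac{\hat\alpha_{RRcs,j}}{\hat\alpha_{RRc,j}} =
#'   \frac{c\,n + S / (2p_j(1-p_j))}{c\,n + N}, \qquad c = \frac{h^2}{1-h^2},}
#' where \eqn{S = \sum_k 2p_k(1-p_k)} over the N loci. The derivation assumes
#' linkage equilibrium (off-diagonal crossproducts ignored), Hardy-Weinberg
#' genotypes, and record weights independent of genotype; `n_records` is the
#' number of individuals when each has one own record, or the total effective
#' record count otherwise.
#'
#' `ratio_uniform()` substitutes \eqn{S = N/3} (uniform spectrum) and
#' `ratio_ushaped()` substitutes \eqn{S = N \cdot E[2p(1-p)]} with the
#' U-shaped expected heterozygosity.
#'
#' @param h2 Heritability of the trait, in (0, 1).
#' @param n_records Number of individuals (or total effective records).
#' @param n_snps Number of loci N.
#' @param p Allele frequency (vectorized), in (0, 1).
#' @param sum_2pq The spectrum sum \eqn{S = \sum_k 2p_k(1-p_k)} (> 0).
#' @return The ratio ASE(RRcs)/ASE(RRc), same length as `p`. Values above 1
#'   mean the scaled coding shrinks that locus less.
#' @examples
#' ratio_uniform(h2 = 0.2, n_individuals = 1000, n_snps = 15e6, p = 0.5) # ~0.67
#' @export
ratio_general <- function(h2, n_records, n_snps, p, sum_2pq) {
  check_h2(h2)
  if (!is.numeric(n_records) || length(n_records) != 1L || n_records <= 0) {
    abort("`n_records` must be a single positive value.")
  }
  if (!is.numeric(sum_2pq) || length(sum_2pq) != 1L || sum_2pq <= 0) {
    abort("`sum_2pq` must be a single positive value.")
  }
  check_count(n_snps, "n_snps", min = 1)
  if (any(p <= 0 | p >= 1)) {
    abort("`p` must lie strictly between 0 and 1.")
  }
  cn <- h2 / (1 - h2) * n_records
  (cn + sum_2pq / (2 * p * (1 - p))) / (cn + n_snps)
}

#' @rdname ratio_general
#' @param n_individuals Number of individuals n (defines the grid for the
#'   U-shaped spectrum).
#' @export
ratio_uniform <- function(h2, n_individuals, n_snps, p) {
  ratio_general(h2, n_individuals, n_snps, p, sum_2pq = n_snps / 3)
}

#' @rdname ratio_general
#' @param model A [freq_ushaped()] model giving Ne and v.
#' @param method Passed to [expected_heterozygosity()].
#' @export
ratio_ushaped <- function(h2, n_individuals, n_snps, p, model = freq_ushaped(),
                          method = c("auto", "approx", "exact")) {
  check_freq_model(model)
  if (model$kind != "ushaped") {
    abort("`model` must be a U-shaped frequency model; use `ratio_uniform()` for the uniform spectrum.")
  }
  ehet <- expected_heterozygosity(model, n_individuals, method = match.arg(method))
  ratio_general(h2, n_individuals, n_snps, p, sum_2pq = n_snps * ehet)
}

#' Allele frequency at which the scaled/unscaled ASE ratio equals 1
#'
#' The ratio crosses 1 exactly where the locus heterozygosity 2p(1-p) equals
#' the spectrum's expected heterozygosity E, i.e. at the root
#' \eqn{p = (1 - \sqrt{1 - 2E})/2} in (0, 0.5]. Loci rarer than this are
#' shrunk less by the scaled coding (ratio > 1), loci more common are shrunk
#' more (ratio < 1). Independent of h2 and the number of loci.
#'
#' @inheritParams expected_heterozygosity
#' @return The crossing allele frequency (equal to the crossing MAF).
#' @examples
#' crossing_maf(freq_uniform(), 1000)       # ~0.211
#' crossing_maf(freq_ushaped(), 1000)       # ~0.065
#' @export
crossing_maf <- function(model, n_individuals,
                         method = c("auto", "approx", "exact")) {
  ehet <- expected_heterozygosity(model, n_individuals, method = match.arg(method))
  if (ehet >= 0.5) {
    abort("Expected heterozygosity >= 0.5: the ratio never reaches 1 on (0, 0.5].")
  }
  (1 - sqrt(1 - 2 * ehet)) / 2
}

#' Tabulate a theoretical shrinkage-ratio curve for a scenario
#'
#' Evaluates the ASE(RRcs)/ASE(RRc) ratio over a grid of allele frequencies
#' for one scenario (heritability, number of individuals, number of loci,
#' frequency spectrum).
#'
#' @inheritParams ratio_general
#' @param n_individuals Number of individuals.
#' @param model A `freq_model` (uniform or U-shaped).
#' @param p_grid Allele frequencies in (0, 0.5]; defaults to a log-spaced grid
#'   from 1/(2n) to 0.5.
#' @return A tibble of class `ratio_curve` with columns `p`, `ratio` and the
#'   scenario descriptors `h2`, `n_individuals`, `n_snps`, `spectrum`.
#' @examples
#' rc <- ratio_curve(0.2, 1000, 5e4, freq_uniform())
#' head(rc)
#' @export
ratio_curve <- function(h2, n_individuals, n_snps, model = freq_uniform(),
                        p_grid = NULL) {
  check_freq_model(model)
  n <- check_count(n_individuals, "n_individuals", min = 2)
  if (is.null(p_grid)) {
    p_grid <- exp(seq(log(1 / (2 * n)), log(0.5), length.out = 200))
  }
  if (any(p_grid <= 0 | p_grid > 0.5)) {
    abort("`p_grid` must lie in (0, 0.5].")
  }
  ratio <- if (model$kind == "uniform") {
    ratio_uniform(h2, n, n_snps, p_grid)
  } else {
    ratio_ushaped(h2, n, n_snps, p_grid, model = model)
  }
  out <- tibble::tibble(
    p = p_grid,
    ratio = ratio,
    h2 = h2,
    n_individuals = n,
    n_snps = n_snps,
    spectrum = model$kind
  )
  class(out) <- c("ratio_curve", class(out))
  out
}
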