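#' Allele-frequency spectrum models
#'
#' Constructors for the two allele-frequency distributions used throughout the
#' package: a uniform spectrum (typical of medium-density SNP chips) and the
#' U-shaped stationary spectrum of mutation-drift equilibrium (typical of
#' whole-genome sequence variants). Both are defined on the discrete grid
#' p = 1/2n, 2/2n, ..., (2n-1)/2n set by the number of genotyped individuals n,
#' matching the summations used by the closed-form ratio theory.
#'
#' The U-shaped density is proportional to
#' \eqn{p^{4N_e v - 1} (1-p)^{4N_e v - 1}}, i.e. the Wright stationary density
#' with equal forward and backward mutation rates and selection coefficient
#' fixed at zero (a non-zero selection coefficient is not supported).
#'
#' @param Ne Effective population size (U-shaped model only).
#' @param v Per-generation mutation rate; forward and backward rates are
#'   assumed equal (U-shaped model only).
#' @param s Selection coefficient; must be 0. The argument exists only so the
#'   restriction is explicit.
#'
#' @return An object of class `freq_model`.
#' @examples
#' freq_uniform()
#' freq_ushaped(Ne = 65, v = 1e-8)
#' @export
freq_uniform <- function() {
  structure(list(kind = "uniform"), class = "freq_model")
}

#' @rdname freq_uniform
#' @export
freq_ushaped <- function(Ne = 65, v = 1e-8, s = 0) {
  if (!is.numeric(Ne) || length(Ne) != 1L || Ne < 1) {
    abort("`Ne` must be a single value >= 1.")
  }
  if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
    abort("`v` must be a single probability in (0, 1).")
  }
  if (!identical(as.numeric(s), 0)) {
    abort("The U-shaped model requires selection coefficient s = 0; the selection term is not supported.")
  }
  structure(list(kind = "ushaped", Ne = Ne, v = v, s = 0), class = "freq_model")
}

is_freq_model <- function(x) inherits(x, "freq_model")

check_freq_model <- function(model) {
  if (!is_freq_model(model)) {
    abort("`model` must be a frequency model created by `freq_uniform()` or `freq_ushaped()`.")
  }
  invisible(model)
}

#' @export
print.freq_model <- function(x, ...) {
  if (x$kind == "uniform") {
    cat("<freq_model> uniform allele-frequency spectrum\n")
  } else {
    cat(sprintf(
      "<freq_model> U-shaped allele-frequency spectrum (Ne = %g, v = %g, 4*Ne*v = %g)\n",
      x$Ne, x$v, 4 * x$Ne * x$v
    ))
  }
  invisible(x)
}

#' Discrete allele-frequency grid
#'
#' The support p = 1/2n, ..., (2n-1)/2n on which frequency densities and the
#' theory's expectations are evaluated.
#'
#' @param n_individuals Number of diploid individuals n.
#' @return Numeric vector of length 2n - 1.
#' @export
freq_grid <- function(n_individuals) {
  n_individuals <- check_count(n_individuals, "n_individuals", min = 2)
  seq_len(2L * n_individuals - 1L) / (2 * n_individuals)
}

#' Normalized density of a frequency model on the grid
#'
#' @param model A `freq_model`.
#' @inheritParams freq_grid
#' @return A tibble with columns `p` (grid frequency) and `phi` (probability
#'   mass), with `sum(phi) == 1`.
#' @export
freq_density <- function(model, n_individuals) {
  check_freq_model(model)
  p <- freq_grid(n_individuals)
  if (model$kind == "uniform") {
    phi <- rep(1 / length(p), length(p))
  } else {
    a <- 4 * model$Ne * model$v
    # work on the log scale: p^(a-1) spans many orders of magnitude near 0
    lw <- (a - 1) * (log(p) + log1p(-p))
    lw <- lw - max(lw)
    w <- exp(lw)
    phi <- w / sum(w)
  }
  tibble::tibble(p = p, phi = phi)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_h2 <- function(h2) {
  if (!is.numeric(h2) || length(h2) != 1L || is.na(h2) || h2 <= 0 || h2 >= 1) {
    abort("`h2` must be a single value strictly between 0 and 1.")
  }
  h2
}
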