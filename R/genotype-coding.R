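check_genotypes <- function(X, arg = "X") {
  if (!is.matrix(X) || nrow(X) == 0L || ncol(X) == 0L) {
    abort(sprintf("`%s` must be a non-empty individuals-by-loci matrix.", arg))
  }
  if (anyNA(X)) {
    abort(sprintf("`%s` contains missing genotypes; inputs must be complete.", arg))
  }
  if (!all(X %in% c(0, 1, 2))) {
    abort(sprintf("`%s` must contain allele counts 0, 1 or 2 only.", arg))
  }
  invisible(X)
}

#' Allele frequency of the counted allele
#'
#' The per-locus frequency of the allele whose homozygote is coded 2:
#' p_j = (column sum) / (2n), i.e. half the mean allele count.
#'
#' @param X Integer genotype matrix (individuals x loci, values 0/1/2).
#' @return Named numeric vector of frequencies in `[0, 1]`. Frequencies 0 or 1
#'   indicate monomorphic loci, which must be removed (see
#'   [apply_variant_filters()]) before coding.
#' @examples
#' allele_frequency(matrix(c(0, 1, 2, 0, 0, 1), nrow = 3))
#' @export
allele_frequency <- function(X) {
  check_genotypes(X)
  setNames(colMeans(X) / 2, colnames(X))
}

#' Minor allele frequency
#'
#' @param p Counted-allele frequencies.
#' @return min(p, 1 - p) per locus.
#' @export
minor_allele_frequency <- function(p) {
  pmin(p, 1 - p)
}

#' Variant filters on minor-allele copies and genotype classes
#'
#' Retains loci with at least `min_minor_copies` copies of the minor allele
#' and, when `require_all_genotypes` is set, with every genotype class
#' observed at least once (at least one heterozygote and one homozygote
#' carrying the minor allele). Monomorphic loci are always removed. The filter
#' is idempotent.
#'
#' @param X Genotype matrix (individuals x loci, values 0/1/2).
#' @param min_minor_copies Minimum number of minor-allele copies (default 5).
#' @param require_all_genotypes Require every genotype class to occur
#'   (default TRUE).
#' @return The filtered genotype matrix, with a tibble of removed loci
#'   (columns `variant_id`, `reason`) attached as attribute
#'   `"removal_report"`; retrieve it with [removal_report()].
#' @export
apply_variant_filters <- function(X, min_minor_copies = 5,
                                  require_all_genotypes = TRUE) {
  check_genotypes(X)
  n <- nrow(X)
  counts <- colSums(X)
  minor_copies <- pmin(counts, 2 * n - counts)
  p <- counts / (2 * n)
  minor_is_counted <- p <= 0.5
  minor_hom_code <- ifelse(minor_is_counted, 2, 0)
  has_het <- apply(X, 2, function(g) any(g == 1))
  has_minor_hom <- vapply(
    seq_len(ncol(X)),
    function(j) any(X[, j] == minor_hom_code[j]),
    logical(1)
  )

  reason <- rep(NA_character_, ncol(X))
  reason[minor_copies < min_minor_copies] <- sprintf("fewer than %d minor-allele copies", min_minor_copies)
  reason[p %in% c(0, 1)] <- "monomorphic"
  if (require_all_genotypes) {
    flag <- is.na(reason) & !has_het
    reason[flag] <- "no heterozygote observed"
    flag <- is.na(reason) & !has_minor_hom
    reason[flag] <- "no minor-allele homozygote observed"
  }

  ids <- colnames(X) %||% as.character(seq_len(ncol(X)))
  keep <- is.na(reason)
  removed <- tibble::tibble(variant_id = ids[!keep], reason = reason[!keep])
  out <- X[, keep, drop = FALSE]
  if (nrow(removed) > 0L) {
    inform(sprintf("Removed %d of %d loci by variant filters.", nrow(removed), ncol(X)))
  }
  attr(out, "removal_report") <- removed
  out
}

#' @rdname apply_variant_filters
#' @export
removal_report <- function(X) {
  attr(X, "removal_report") %||%
    tibble::tibble(variant_id = character(), reason = character())
}

#' Center and scale allele counts with a continuous scaling parameter
#'
#' Builds the coded design matrix with elements
#' \eqn{(x_{ij} - 2p_j) (2p_j(1-p_j))^{\gamma/2}}: `gamma = 0` gives centered
#' allele counts (the Z matrix of RRc), `gamma = -1` gives centered and scaled
#' counts with unit variance under Hardy-Weinberg equilibrium (the W matrix of
#' RRcs), and intermediate values interpolate. `gamma` here is always the
#' allele-count scaling exponent, never the Euler-Mascheroni constant.
#'
#' @param X Genotype matrix (individuals x loci, values 0/1/2).
#' @param gamma Scaling parameter in `[-1, 0]`.
#' @param freq Optional allele frequencies to use for centering/scaling;
#'   defaults to the observed sample frequencies of `X`. Must be strictly
#'   inside (0, 1).
#' @return A numeric matrix of class `coded_matrix` carrying attributes
#'   `gamma`, `freq_used` and `scale_sum` (the GRM divisor
#'   \eqn{s_\gamma = \sum_j (2p_j(1-p_j))^{\gamma+1}}).
#' @examples
#' X <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3, dimnames = list(NULL, c("a", "b")))
#' code_genotypes(X, gamma = -1)
#' @export
code_genotypes <- function(X, gamma = 0, freq = NULL) {
  check_genotypes(X)
  check_gamma(gamma)
  p <- freq %||% allele_frequency(X)
  if (length(p) != ncol(X)) {
    abort("`freq` must have one frequency per locus.")
  }
  if (any(p <= 0 | p >= 1)) {
    abort("Allele frequencies must be strictly inside (0, 1); remove monomorphic loci first (see `apply_variant_filters()`).")
  }
  het <- 2 * p * (1 - p)
  M <- sweep(X, 2, 2 * p)
  if (gamma != 0) {
    M <- sweep(M, 2, het^(gamma / 2), `*`)
  }
  structure(
    M,
    gamma = gamma,
    freq_used = p,
    scale_sum = sum(het^(gamma + 1)),
    class = c("coded_matrix", class(M))
  )
}

check_gamma <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < -1 || gamma > 0) {
    abort("`gamma` must be a single scaling parameter in [-1, 0].")
  }
  gamma
}

check_coded <- function(M, arg = "M") {
  if (!inherits(M, "coded_matrix")) {
    abort(sprintf("`%s` must be a coded matrix from `code_genotypes()`.", arg))
  }
  invisible(M)
}

#' Genomic relationship matrix from a coded matrix
#'
#' \eqn{G = M M' / s_\gamma} with \eqn{s_\gamma = \sum_j (2p_j(1-p_j))^{\gamma+1}}.
#' At `gamma = 0` the divisor is \eqn{\sum_j 2p_j(1-p_j)} (VanRaden method 1);
#' at `gamma = -1` it is the number of loci N (VanRaden method 2). This is the
#' unique divisor for which SNP-BLUP with per-locus variance
#' \eqn{\sigma_a^2 / s_\gamma} is equivalent to GBLUP with G at every gamma.
#'
#' @param M A `coded_matrix` from [code_genotypes()].
#' @return Symmetric n x n matrix with attributes `gamma` and `scale_sum`.
#' @export
build_grm <- function(M) {
  check_coded(M)
  s <- attr(M, "scale_sum")
  if (!is.numeric(s) || s <= 0) {
    abort("The coded matrix has a non-positive scale sum; cannot build a GRM.")
  }
  G <- tcrossprod(unclass(M)) / s
  attr(G, "gamma") <- attr(M, "gamma")
  attr(G, "scale_sum") <- s
  G
}

#' Transform coded-scale effects to allele substitution effects
#'
#' Effects estimated on the coded scale at scaling parameter gamma refer to
#' the transformed allele counts; the ASE on the raw 0/1/2 scale is
#' \eqn{\alpha_j = \hat b_j (2p_j(1-p_j))^{\gamma/2}}. At `gamma = 0` this is
#' the identity; at `gamma = -1` it divides by the Hardy-Weinberg standard
#' deviation (the diagonal U-matrix transformation).
#'
#' @param b_hat Coded-scale effect estimates.
#' @param p Allele frequencies of the counted allele.
#' @param gamma Scaling parameter used for the coding.
#' @return ASE vector, trait units per allele copy.
#' @export
ase_transform <- function(b_hat, p, gamma) {
  check_gamma(gamma)
  if (length(b_hat) != length(p)) {
    abort("`b_hat` and `p` must have the same length.")
  }
  b_hat * (2 * p * (1 - p))^(gamma / 2)
}

#' @rdname ase_transform
#' @param ase ASE vector to map back to the coded scale.
#' @export
inverse_ase_transform <- function(ase, p, gamma) {
  check_gamma(gamma)
  if (length(ase) != length(p)) {
    abort("`ase` and `p` must have the same length.")
  }
  ase / (2 * p * (1 - p))^(gamma / 2)
}
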