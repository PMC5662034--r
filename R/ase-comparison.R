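#' Per-MAF comparison statistics between two ASE vectors
#'
#' Groups loci by minor allele frequency and, within each group, computes the
#' Pearson correlation between the two ASE sets, the mean and median of the
#' per-locus ratios `ase_b / ase_a`, and the least-squares slope of the
#' regression of `ase_b` on `ase_a` (intercept included). By default grouping
#' is by exact sample MAF (discrete on the 1/2n grid); `bin_width` switches to
#' interval bins for small datasets. Groups smaller than `min_bin_size` are
#' reported with statistics marked unavailable rather than dropped. Loci where
#' `ase_a` is exactly zero have an undefined ratio; they are excluded from the
#' ratio mean/median and counted in `n_ratio_excluded`.
#'
#' @param ase_a Reference ASE vector (e.g. from the centered-only fit).
#' @param ase_b Comparison ASE vector (e.g. from the centered-and-scaled fit).
#' @param maf Minor allele frequencies, in (0, 0.5].
#' @param min_bin_size Minimum group size for correlation/slope (default 2).
#' @param bin_width Optional MAF bin width; `NULL` groups by exact MAF.
#' @return A tibble with one row per MAF group: `maf` (group value or bin
#'   midpoint), `n_snps`, `correlation`, `mean_ratio`, `median_ratio`,
#'   `regression_slope`, `n_ratio_excluded`, `flagged`.
#' @export
per_maf_stats <- function(ase_a, ase_b, maf, min_bin_size = 2, bin_width = NULL) {
  if (length(ase_a) != length(ase_b) || length(ase_a) != length(maf)) {
    abort("`ase_a`, `ase_b` and `maf` must have the same length.")
  }
  if (any(maf <= 0 | maf > 0.5)) {
    abort("`maf` must lie in (0, 0.5].")
  }
  group <- maf_bin_mid(maf, bin_width)
  n_excluded <- sum(ase_a == 0)
  if (n_excluded > 0L) {
    inform(sprintf("%d loci with ASE exactly 0 in the reference fit excluded from ratio summaries.", n_excluded))
  }
  tibble::tibble(maf = group, ase_a = ase_a, ase_b = ase_b) |>
    dplyr::group_by(.data$maf) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      correlation = if (dplyr::n() >= min_bin_size && stats::sd(.data$ase_a) > 0 && stats::sd(.data$ase_b) > 0) {
        stats::cor(.data$ase_a, .data$ase_b)
      } else {
        NA_real_
      },
      mean_ratio = mean((.data$ase_b / .data$ase_a)[.data$ase_a != 0]),
      median_ratio = median((.data$ase_b / .data$ase_a)[.data$ase_a != 0]),
      regression_slope = if (dplyr::n() >= min_bin_size && stats::var(.data$ase_a) > 0) {
        stats::cov(.data$ase_a, .data$ase_b) / stats::var(.data$ase_a)
      } else {
        NA_real_
      },
      n_ratio_excluded = sum(.data$ase_a == 0),
      flagged = dplyr::n() < min_bin_size,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$maf)
}

## right-closed bins (k*w, (k+1)*w], labelled by midpoint, so MAF = 0.5 stays
## inside the top bin
maf_bin_mid <- function(maf, bin_width) {
  if (is.null(bin_width)) return(maf)
  (ceiling(maf / bin_width) - 0.5) * bin_width
}

#' Compare two fits of the same data at different scaling parameters
#'
#' Overall and per-MAF comparison of two [fit_ase()] results on the same
#' individuals and loci: correlation, regression slope (fit_b on fit_a) and
#' variances of the direct genomic values; overall correlation of the ASE;
#' and the per-MAF group table of [per_maf_stats()].
#'
#' @param fit_a,fit_b `ase_fit` objects on identical individuals and loci
#'   (conventionally `fit_a` is the centered-only fit, gamma = 0).
#' @inheritParams per_maf_stats
#' @return An object of class `ase_comparison`: list with `overall` (one-row
#'   tibble) and `by_maf` (tibble). `glance()` returns the overall row,
#'   `tidy()` the per-MAF table.
#' @export
compare_fits <- function(fit_a, fit_b, min_bin_size = 2, bin_width = NULL) {
  if (!inherits(fit_a, "ase_fit") || !inherits(fit_b, "ase_fit")) {
    abort("`fit_a` and `fit_b` must be `ase_fit` objects.")
  }
  ids_a <- names(fit_a$dgv)
  ids_b <- names(fit_b$dgv)
  if (length(fit_a$dgv) != length(fit_b$dgv) ||
      length(fit_a$ase) != length(fit_b$ase) ||
      (!is.null(ids_a) && !is.null(ids_b) && !identical(ids_a, ids_b)) ||
      (!is.null(names(fit_a$ase)) && !is.null(names(fit_b$ase)) &&
       !identical(names(fit_a$ase), names(fit_b$ase)))) {
    abort("`fit_a` and `fit_b` must be fits of the same individuals and loci.")
  }
  overall <- tibble::tibble(
    gamma_a = fit_a$gamma,
    gamma_b = fit_b$gamma,
    dgv_correlation = cor(fit_a$dgv, fit_b$dgv),
    dgv_regression = stats::cov(fit_a$dgv, fit_b$dgv) / var(fit_a$dgv),
    dgv_variance_a = var(fit_a$dgv),
    dgv_variance_b = var(fit_b$dgv),
    ase_correlation = cor(fit_a$ase, fit_b$ase)
  )
  by_maf <- per_maf_stats(fit_a$ase, fit_b$ase, fit_a$maf,
    min_bin_size = min_bin_size, bin_width = bin_width
  )
  structure(list(overall = overall, by_maf = by_maf), class = "ase_comparison")
}

#' @export
print.ase_comparison <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "<ase_comparison> gamma %g vs %g\n  DGV: cor = %.4f, slope = %.4f; ASE: cor = %.4f; %d MAF groups\n",
    o$gamma_a, o$gamma_b, o$dgv_correlation, o$dgv_regression,
    o$ase_correlation, nrow(x$by_maf)
  ))
  invisible(x)
}

#' @export
glance.ase_comparison <- function(x, ...) x$overall

#' @export
tidy.ase_comparison <- function(x, ...) x$by_maf

#' Join theoretical shrinkage ratios onto an empirical per-MAF table
#'
#' Evaluates the closed-form ratio (uniform or U-shaped spectrum) at each MAF
#' group of a [per_maf_stats()] table for a scenario matching the fitted
#' dataset, for overlaying on the empirical mean ratios.
#'
#' @param bins Per-MAF table from [per_maf_stats()] or
#'   `tidy(<ase_comparison>)`.
#' @param h2 Heritability of the scenario.
#' @param n_individuals,n_snps Scenario dimensions (should match the fitted
#'   data).
#' @param model Frequency model (default uniform).
#' @return `bins` with a `theoretical_ratio` column appended.
#' @export
theory_overlay <- function(bins, h2, n_individuals, n_snps,
                           model = freq_uniform()) {
  if (!is.data.frame(bins) || !"maf" %in% names(bins)) {
    abort("`bins` must be a per-MAF table with a `maf` column.")
  }
  check_freq_model(model)
  th <- if (model$kind == "uniform") {
    ratio_uniform(h2, n_individuals, n_snps, bins$maf)
  } else {
    ratio_ushaped(h2, n_individuals, n_snps, bins$maf, model = model)
  }
  dplyr::mutate(bins, theoretical_ratio = unname(th))
}

#' Genetic-variance-weighted mean of per-MAF ratios
#'
#' Averages the per-MAF mean ratios weighting each group by its share of the
#' genetic variance explained by the reference ASE
#' (\eqn{\sum_j 2 maf_j (1-maf_j) \alpha_{a,j}^2} within the group). Because
#' the total variance captured by all loci together is preserved across
#' codings, this weighted mean hovers near 1 even though low-MAF groups sit
#' well above 1.
#'
#' @inheritParams per_maf_stats
#' @return A single number.
#' @export
variance_weighted_mean_ratio <- function(ase_a, ase_b, maf, bin_width = NULL) {
  bins <- tibble::tibble(
    maf = maf_bin_mid(maf, bin_width),
    share = 2 * maf * (1 - maf) * ase_a^2,
    ratio = ifelse(ase_a == 0, NA_real_, ase_b / ase_a)
  ) |>
    dplyr::group_by(.data$maf) |>
    dplyr::summarise(
      share = sum(.data$share),
      mean_ratio = mean(.data$ratio, na.rm = TRUE),
      .groups = "drop"
    )
  sum(bins$share * bins$mean_ratio) / sum(bins$share)
}
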