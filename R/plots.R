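#' Plot a theoretical shrinkage-ratio curve
#'
#' @param object A `ratio_curve` from [ratio_curve()], or several row-bound
#'   together.
#' @param ... Unused.
#' @return A ggplot: ratio against allele frequency (log scale) with the
#'   ratio = 1 reference line.
#' @export
autoplot.ratio_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$p, y = .data$ratio,
    colour = interaction(.data$h2, .data$n_individuals, .data$n_snps, .data$spectrum)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "allele frequency",
      y = "ASE ratio (scaled / unscaled)",
      colour = "scenario (h2.n.N.spectrum)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a scaling-parameter scan
#'
#' @param object A `gamma_scan` tibble from [scan_gamma()], [scan_loglik()]
#'   or [scan_msep()].
#' @param ... Unused.
#' @return A ggplot with one panel per available criterion (restricted
#'   log-likelihood and/or weighted MSEP) against gamma.
#' @export
autoplot.gamma_scan <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select(dplyr::any_of(c("gamma", "logL_reml", "msep"))) |>
    tidyr::pivot_longer(-"gamma", names_to = "criterion", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gamma, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "scaling parameter gamma", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-MAF comparison statistics between two fits
#'
#' @param object An `ase_comparison` from [compare_fits()].
#' @param ... Unused.
#' @return A ggplot of the per-MAF mean ratio (and the theoretical overlay
#'   when present) against MAF, with the ratio = 1 reference line.
#' @export
autoplot.ase_comparison <- function(object, ...) {
  bins <- object$by_maf
  gg <- ggplot2::ggplot(bins, ggplot2::aes(x = .data$maf, y = .data$mean_ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "minor allele frequency",
      y = "mean ASE ratio (fit_b / fit_a)"
    ) +
    ggplot2::theme_minimal()
  if ("theoretical_ratio" %in% names(bins)) {
    gg <- gg + ggplot2::geom_line(
      ggplot2::aes(y = .data$theoretical_ratio),
      colour = "red", linetype = "dashed"
    )
  }
  gg
}

#' Plot estimated ASE against MAF for one fit
#'
#' @param object An `ase_fit`.
#' @param ... Unused.
#' @return A ggplot of |ASE| against MAF.
#' @export
autoplot.ase_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$maf, y = abs(.data$ase))) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(
      x = "minor allele frequency",
      y = "|allele substitution effect|",
      title = sprintf("gamma = %g", object$gamma)
    ) +
    ggplot2::theme_minimal()
}
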