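clean_gamma_grid <- function(gamma_grid) {
  if (!is.numeric(gamma_grid) || length(gamma_grid) == 0L) {
    abort("`gamma_grid` must be a non-empty numeric vector.")
  }
  if (any(gamma_grid < -1 | gamma_grid > 0)) {
    abort("All grid values must lie in [-1, 0].")
  }
  sort(unique(gamma_grid))
}

## ties on the grid are broken toward the more negative gamma
pick_best <- function(gamma, value, maximize) {
  ok <- is.finite(value)
  if (!any(ok)) return(NA_real_)
  target <- if (maximize) max(value[ok]) else min(value[ok])
  cand <- gamma[ok][value[ok] == target]
  if (length(cand) > 1L) {
    inform(sprintf(
      "Ties at %s; choosing the more negative gamma.",
      paste(format(cand), collapse = ", ")
    ))
  }
  min(cand)
}

#' Restricted log-likelihood profile over the scaling parameter
#'
#' For each gamma on the grid: codes the genotypes, builds the GRM,
#' re-estimates the variance components by REML and records the restricted
#' log-likelihood. The profiles are comparable across gamma because the
#' fixed-effect design (intercept only) is unchanged. A REML failure at one
#' grid point is flagged (NA row) and the scan continues.
#'
#' @param pheno Phenotype data frame (`id`, `phenotype`, `weight`).
#' @param genotypes Genotype matrix (individuals x loci, values 0/1/2).
#' @param gamma_grid Scaling parameters in `[-1, 0]` (default -1 to 0 in
#'   steps of 0.1); duplicates are removed and the grid is sorted.
#' @param freq Optional allele frequencies for the coding (default: observed).
#' @return A tibble of class `gamma_scan` with columns `gamma`, `logL_reml`,
#'   `sigma_a2`, `sigma_e2`, `h2`, `converged`; the gamma maximizing the
#'   log-likelihood is attached as attribute `"best_gamma_logL"` (ties broken
#'   toward the more negative gamma).
#' @export
scan_loglik <- function(pheno, genotypes, gamma_grid = seq(-1, 0, by = 0.1),
                        freq = NULL) {
  grid <- clean_gamma_grid(gamma_grid)
  rows <- purrr::map(grid, function(g) {
    res <- tryCatch(
      {
        M <- code_genotypes(genotypes, gamma = g, freq = freq)
        gf <- fit_greml(build_grm(M), pheno)
        tibble::tibble(
          gamma = g, logL_reml = gf$logL_reml,
          sigma_a2 = gf$varcomp$sigma_a2, sigma_e2 = gf$varcomp$sigma_e2,
          h2 = gf$varcomp$h2, converged = !gf$boundary
        )
      },
      error = function(e) {
        warn(sprintf("REML failed at gamma = %g: %s", g, conditionMessage(e)))
        tibble::tibble(
          gamma = g, logL_reml = NA_real_, sigma_a2 = NA_real_,
          sigma_e2 = NA_real_, h2 = NA_real_, converged = FALSE
        )
      }
    )
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "best_gamma_logL") <- pick_best(out$gamma, out$logL_reml, maximize = TRUE)
  class(out) <- c("gamma_scan", class(out))
  out
}

#' Split individuals into training and validation sets
#'
#' `"by_order"` uses the input order as the age proxy (the first fraction are
#' the training "older" individuals); `"by_id_list"` uses explicit id lists.
#' The two sets are disjoint and together cover all individuals.
#'
#' @param pheno Phenotype data frame with an `id` column.
#' @param rule `"by_order"` or `"by_id_list"`.
#' @param train_fraction Fraction assigned to training under `"by_order"`
#'   (the training size is `round(n * train_fraction)`).
#' @param train_ids Ids of the training individuals under `"by_id_list"`;
#'   all remaining individuals form the validation set.
#' @return A list of class `split_spec` with character vectors `train` and
#'   `validation`.
#' @export
split_phenotypes <- function(pheno, rule = c("by_order", "by_id_list"),
                             train_fraction = NULL, train_ids = NULL) {
  rule <- match.arg(rule)
  if (!is.data.frame(pheno) || !"id" %in% names(pheno)) {
    abort("`pheno` must be a data frame with an `id` column.")
  }
  ids <- as.character(pheno$id)
  if (rule == "by_order") {
    if (is.null(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
      abort("`train_fraction` must lie strictly between 0 and 1 (both sets must be non-empty).")
    }
    n_train <- round(length(ids) * train_fraction)
    if (n_train < 1 || n_train >= length(ids)) {
      abort("The split leaves the training or validation set empty.")
    }
    train <- ids[seq_len(n_train)]
    validation <- ids[-seq_len(n_train)]
  } else {
    if (is.null(train_ids)) abort("`train_ids` is required for rule 'by_id_list'.")
    train_ids <- as.character(train_ids)
    if (!all(train_ids %in% ids)) {
      abort("Some `train_ids` are not present in the phenotype table.")
    }
    train <- ids[ids %in% train_ids]
    validation <- setdiff(ids, train)
    if (length(train) == 0L || length(validation) == 0L) {
      abort("The split leaves the training or validation set empty.")
    }
  }
  structure(list(train = train, validation = validation), class = "split_spec")
}

#' Weighted mean squared error of prediction
#'
#' \eqn{MSEP = \sum_i wt_i (pred_i - obs_i)^2 / \sum_i wt_i}, the weighted
#' prediction-error criterion (predictions are DGV + intercept).
#'
#' @param predicted Predicted phenotypes.
#' @param observed Observed phenotypes.
#' @param weights Positive weights (default all 1, giving the ordinary MSE).
#' @return A single number.
#' @export
msep <- function(predicted, observed, weights = NULL) {
  if (length(predicted) != length(observed)) {
    abort("`predicted` and `observed` must have the same length.")
  }
  weights <- weights %||% rep(1, length(predicted))
  if (length(weights) != length(predicted) || any(weights <= 0)) {
    abort("`weights` must be strictly positive, one per observation.")
  }
  if (sum(weights) <= 0) abort("Total weight must be positive.")
  sum(weights * (predicted - observed)^2) / sum(weights)
}

#' Prediction-error profile over the scaling parameter
#'
#' For each gamma: codes the genotypes (allele frequencies from the full data
#' by default, or from the training set), estimates variance components by
#' REML on the training block only, predicts validation phenotypes through
#' the train-validation genomic relationships (DGV plus the training
#' intercept) and computes the weighted MSEP on the validation set.
#'
#' @inheritParams scan_loglik
#' @param split A `split_spec` from [split_phenotypes()].
#' @param freq_from `"all"` (default) computes coding frequencies on the full
#'   dataset, `"train"` on the training individuals only.
#' @return A tibble of class `gamma_scan` with columns `gamma`, `msep`,
#'   `sigma_a2`, `sigma_e2`, `h2`, `converged`; the gamma minimizing MSEP is
#'   attached as attribute `"best_gamma_msep"` (ties toward the more negative
#'   gamma). The frequency convention is recorded as attribute `"freq_from"`.
#' @export
scan_msep <- function(pheno, genotypes, split,
                      gamma_grid = seq(-1, 0, by = 0.1),
                      freq_from = c("all", "train")) {
  grid <- clean_gamma_grid(gamma_grid)
  freq_from <- match.arg(freq_from)
  if (!inherits(split, "split_spec")) {
    abort("`split` must come from `split_phenotypes()`.")
  }
  ids <- rownames(genotypes)
  if (is.null(ids)) abort("`genotypes` must have row names (individual ids).")
  if (!setequal(c(split$train, split$validation), ids)) {
    abort("The split must cover exactly the genotyped individuals.")
  }
  tr <- match(split$train, ids)
  va <- match(split$validation, ids)
  ph <- check_phenotypes(pheno, ids = ids)
  freq <- if (freq_from == "all") {
    allele_frequency(genotypes)
  } else {
    allele_frequency(genotypes[tr, , drop = FALSE])
  }
  if (any(freq <= 0 | freq >= 1)) {
    abort("Some loci are monomorphic under the requested frequency convention; filter first.")
  }
  pheno_tr <- tibble::tibble(
    id = ids[tr], phenotype = ph$y[tr], weight = ph$wt[tr]
  )
  rows <- purrr::map(grid, function(g) {
    tryCatch(
      {
        M <- code_genotypes(genotypes, gamma = g, freq = freq)
        G <- build_grm(M)
        G_tt <- G[tr, tr, drop = FALSE]
        gf <- fit_greml(G_tt, pheno_tr)
        vc <- gf$varcomp
        V <- vc$sigma_a2 * G_tt
        diag(V) <- diag(V) + vc$sigma_e2 / ph$wt[tr]
        ch <- chol(V)
        Viy <- backsolve(ch, forwardsolve(ch, ph$y[tr], upper.tri = TRUE, transpose = TRUE))
        Vi1 <- backsolve(ch, forwardsolve(ch, rep(1, length(tr)), upper.tri = TRUE, transpose = TRUE))
        mu_hat <- sum(Vi1 * ph$y[tr]) / sum(Vi1)
        Vir <- Viy - mu_hat * Vi1
        dgv_val <- drop(vc$sigma_a2 * G[va, tr, drop = FALSE] %*% Vir)
        tibble::tibble(
          gamma = g,
          msep = msep(dgv_val + mu_hat, ph$y[va], ph$wt[va]),
          sigma_a2 = vc$sigma_a2, sigma_e2 = vc$sigma_e2, h2 = vc$h2,
          converged = !gf$boundary
        )
      },
      error = function(e) {
        warn(sprintf("Prediction failed at gamma = %g: %s", g, conditionMessage(e)))
        tibble::tibble(
          gamma = g, msep = NA_real_, sigma_a2 = NA_real_,
          sigma_e2 = NA_real_, h2 = NA_real_, converged = FALSE
        )
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "best_gamma_msep") <- pick_best(out$gamma, out$msep, maximize = FALSE)
  attr(out, "freq_from") <- freq_from
  class(out) <- c("gamma_scan", class(out))
  out
}

#' Scan the scaling parameter by model fit and predictive performance
#'
#' Umbrella over [scan_loglik()] and [scan_msep()]: runs either or both
#' criteria over the gamma grid and reports the optimum of each (highest
#' restricted log-likelihood; lowest weighted MSEP).
#'
#' @inheritParams scan_msep
#' @param criterion `"both"`, `"loglik"` or `"msep"`.
#' @param split Required when MSEP is scanned.
#' @return A tibble of class `gamma_scan` joining the per-gamma results,
#'   with attributes `"best_gamma_logL"` and/or `"best_gamma_msep"`;
#'   retrieve them with [best_gamma()].
#' @examples
#' sim <- simulate_dataset(n_individuals = 80, n_snps = 150, h2 = 0.5, seed = 7)
#' geno <- apply_variant_filters(sim$genotypes)
#' sc <- scan_gamma(sim$phenotypes, geno, gamma_grid = c(-1, -0.5, 0),
#'                  criterion = "loglik")
#' best_gamma(sc, "loglik")
#' @export
scan_gamma <- function(pheno, genotypes, gamma_grid = seq(-1, 0, by = 0.1),
                       criterion = c("both", "loglik", "msep"),
                       split = NULL, freq = NULL,
                       freq_from = c("all", "train")) {
  criterion <- match.arg(criterion)
  out <- NULL
  if (criterion %in% c("both", "loglik")) {
    out <- scan_loglik(pheno, genotypes, gamma_grid, freq = freq)
  }
  if (criterion %in% c("both", "msep")) {
    if (is.null(split)) abort("`split` is required when scanning MSEP.")
    ms <- scan_msep(pheno, genotypes, split, gamma_grid, freq_from = freq_from)
    if (is.null(out)) {
      out <- ms
    } else {
      merged <- dplyr::left_join(
        tibble::as_tibble(out),
        dplyr::select(tibble::as_tibble(ms), "gamma", "msep"),
        by = "gamma"
      )
      attr(merged, "best_gamma_logL") <- attr(out, "best_gamma_logL")
      attr(merged, "best_gamma_msep") <- attr(ms, "best_gamma_msep")
      attr(merged, "freq_from") <- attr(ms, "freq_from")
      class(merged) <- c("gamma_scan", class(merged))
      out <- merged
    }
  }
  out
}

#' @rdname scan_gamma
#' @param x A `gamma_scan` result.
#' @param which `"loglik"` or `"msep"`.
#' @export
best_gamma <- function(x, which = c("loglik", "msep")) {
  which <- match.arg(which)
  attr(x, if (which == "loglik") "best_gamma_logL" else "best_gamma_msep") %||%
    NA_real_
}
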