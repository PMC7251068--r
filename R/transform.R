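# SUVR -> ESM-ready value transformations: confound regression, the
# cross-validated mixture-probability transform, min-max and
# reference-bootstrap ECDF alternatives, and region-set selection.

#' Regress confounding signals out of regional SUVR values
#'
#' Three strategies for removing age, sex and choroid-plexus off-target
#' signal before transformation:
#' \describe{
#'   \item{none}{identity.}
#'   \item{residualize}{per-region ordinary least squares on age, sex and
#'     mean choroid-plexus signal across all subjects; output is the
#'     residual plus the regional grand mean, keeping values on the SUVR
#'     scale for mixture fitting.}
#'   \item{wscore}{per-region model fit on a reference group only
#'     (amyloid-negative cognitively normal); output is
#'     (observed - predicted) / SD of reference residuals.}
#' }
#'
#' @param suvr A `regional_matrix` of SUVR values.
#' @param covariates Data frame aligned to subjects with numeric columns
#'   `age`, `sex` (coded 0/1) and `choroid_plexus`.
#' @param strategy `"none"`, `"residualize"` or `"wscore"`.
#' @param reference_group Logical subject mask defining the w-score
#'   reference group; required for `"wscore"`.
#' @return A `regional_matrix` with updated provenance.
#' @export
regress_confounds <- function(suvr, covariates,
                              strategy = c("none", "residualize", "wscore"),
                              reference_group = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(suvr, "regional_matrix"))
  if (strategy == "none") {
    return(set_values(suvr, suvr$values, confound_strategy = "none"))
  }
  need <- c("age", "sex", "choroid_plexus")
  if (!all(need %in% names(covariates))) {
    stopf("covariates must contain: %s", paste(need, collapse = ", "))
  }
  cv <- covariates[, need]
  if (anyNA(cv)) stopf("covariates incomplete")
  if (nrow(cv) != nrow(suvr$values)) stopf("covariates misaligned to subjects")
  X <- stats::model.matrix(~ age + sex + choroid_plexus, data = cv)
  if (qr(X)$rank < ncol(X)) stopf("rank-deficient covariates")
  Y <- suvr$values

  if (strategy == "residualize") {
    fit <- stats::lm.fit(X, Y)
    out <- fit$residuals + matrix(colMeans(Y), nrow(Y), ncol(Y),
                                  byrow = TRUE)
    dimnames(out) <- dimnames(Y)
    return(set_values(suvr, out, confound_strategy = "residualize"))
  }

  # wscore
  if (is.null(reference_group) || !any(reference_group)) {
    stopf("wscore requires a non-empty reference group")
  }
  stopifnot(length(reference_group) == nrow(Y))
  Xr <- X[reference_group, , drop = FALSE]
  if (qr(Xr)$rank < ncol(Xr)) stopf("rank-deficient covariates in reference group")
  fit <- stats::lm.fit(Xr, Y[reference_group, , drop = FALSE])
  pred <- X %*% fit$coefficients
  ref_sd <- apply(fit$residuals, 2, stats::sd)
  if (any(ref_sd == 0)) stopf("zero residual variance in reference group")
  out <- (Y - pred) / matrix(ref_sd, nrow(Y), ncol(Y), byrow = TRUE)
  dimnames(out) <- dimnames(Y)
  set_values(suvr, out, confound_strategy = "wscore")
}

#' Convert SUVR values to tau-positive probabilities by mixture modelling
#'
#' For each region, one- and two-component Gaussian mixtures are fit
#' across the population ([fit_region_mixture]); bimodality is decided on
#' the full-sample fit. Each subject's tau-positive probability is the
#' posterior probability of the upper component, evaluated out-of-sample
#' by repeated fivefold cross-validation: per repeat, subjects are
#' shuffled into five folds, the mixture is refit on the four training
#' folds (warm-started from the full-sample fit) and evaluated on the
#' held-out fold, and the subject value is the mean over repeats.
#'
#' @param suvr A `regional_matrix` of (possibly confound-regressed) SUVR
#'   values.
#' @param folds Number of CV folds.
#' @param repeats Number of CV repeats.
#' @param seed Integer seed controlling fold shuffles and EM restarts.
#' @param n_restarts Restarts for the full-sample EM fits.
#' @param cv_restarts Restarts for each training-fold refit (each is also
#'   warm-started from the full-sample solution).
#' @return A list with `matrix` (probability `regional_matrix`), `fits`
#'   (per-region `mixture_fit`s, full sample), and `failed` (named list of
#'   per-region fit errors, empty when all regions fit).
#' @export
mixture_probability_transform <- function(suvr, folds = 5L, repeats = 10L,
                                          seed = 1L, n_restarts = 10L,
                                          cv_restarts = 2L) {
  stopifnot(inherits(suvr, "regional_matrix"))
  Y <- suvr$values
  n <- nrow(Y)
  if (n < folds) stopf("need at least %d subjects for %d folds", folds, folds)
  fits <- vector("list", ncol(Y))
  names(fits) <- colnames(Y)
  failed <- list()
  out <- matrix(NA_real_, n, ncol(Y), dimnames = dimnames(Y))

  for (j in seq_len(ncol(Y))) {
    region <- colnames(Y)[j]
    x <- Y[, j]
    full <- tryCatch(
      fit_region_mixture(x, seed = child_seed(seed, j), region = region,
                         n_restarts = n_restarts, min_n = min(50L, n)),
      error = function(e) e)
    if (inherits(full, "error")) {
      failed[[region]] <- conditionMessage(full)
      next
    }
    fits[[j]] <- full

    acc <- numeric(n)
    for (r in seq_len(repeats)) {
      fold_of <- with_seed(child_seed(seed, j * 1000L + r), {
        sample(rep_len(seq_len(folds), n))
      })
      for (f in seq_len(folds)) {
        test <- fold_of == f
        train <- x[!test]
        cvfit <- .refit_warm(train, full,
                             seed = child_seed(seed, j * 100000L + r * 100L + f),
                             n_restarts = cv_restarts)
        acc[test] <- acc[test] + posterior_upper(cvfit, x[test])
      }
    }
    out[, j] <- acc / repeats
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stopf("mixture fitting failed for every region")
  out <- out[, ok, drop = FALSE]
  mat <- regional_matrix(out, suvr$subjects, colnames(out),
                         utils::modifyList(suvr$provenance,
                                           list(transformation = "mixture_probability")))
  list(matrix = mat, fits = fits[ok], failed = failed)
}

# Refit the 2-component mixture on a training split, warm-starting from
# the full-sample fit plus a couple of fresh restarts.
.refit_warm <- function(train, full, seed, n_restarts = 2L) {
  best <- with_seed(seed, {
    best <- .em2(train, full$means, full$sds, full$weights)
    for (r in seq_len(n_restarts)) {
      mu <- sort(sample(train, 2L))
      if (diff(mu) == 0) mu <- mu + c(-1, 1) * stats::sd(train) / 4
      cand <- .em2(train, mu, rep(stats::sd(train) / 2, 2), c(0.5, 0.5))
      if (!is.null(cand) && (is.null(best) || cand$loglik > best$loglik)) {
        best <- cand
      }
    }
    best
  })
  if (is.null(best)) return(full)  # fall back to the full-sample fit
  ord <- order(best$mu)
  structure(list(region = full$region, n_components = 2L,
                 means = best$mu[ord], sds = best$sigma[ord],
                 weights = best$w[ord], upper_component_index = 2L),
            class = "mixture_fit")
}

#' Alternative SUVR transformations
#'
#' Two comparison transformations onto the \[0, 1\] scale the spreading
#' model expects:
#' \describe{
#'   \item{minmax}{per-region (x - min) / (max - min), i.e. SUVR values
#'     used essentially as-is.}
#'   \item{reference_ecdf}{a null distribution is built by taking the
#'     maximum of `n_boot` bootstrap resamples of the trimmed (5th-95th
#'     percentile) reference-region values; its empirical cumulative
#'     distribution function is applied to every regional value, giving
#'     the probability of exceeding reference-region signal.}
#' }
#'
#' @param suvr A `regional_matrix`.
#' @param mode `"minmax"` or `"reference_ecdf"`.
#' @param reference_values Numeric vector of reference-region values
#'   (required for `"reference_ecdf"`).
#' @param n_boot Number of bootstrap maxima.
#' @param boot_range Quantile range of reference values resampled.
#' @param seed Integer seed for the bootstrap.
#' @return A probability `regional_matrix`.
#' @export
alternative_transform <- function(suvr, mode = c("minmax", "reference_ecdf"),
                                  reference_values = NULL, n_boot = 40000L,
                                  boot_range = c(0.05, 0.95), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(suvr, "regional_matrix"))
  Y <- suvr$values
  if (mode == "minmax") {
    out <- apply(Y, 2, minmax01, what = "a region")
    dimnames(out) <- dimnames(Y)
    return(set_values(suvr, out, transformation = "minmax"))
  }
  if (is.null(reference_values) || !length(reference_values)) {
    stopf("reference_ecdf requires reference_values")
  }
  q <- stats::quantile(reference_values, boot_range, names = FALSE)
  trimmed <- reference_values[reference_values >= q[1] &
                                reference_values <= q[2]]
  if (!length(trimmed)) stopf("no reference values in the trimmed range")
  maxima <- with_seed(seed, {
    nref <- length(trimmed)
    vapply(seq_len(n_boot), function(i) {
      max(trimmed[sample.int(nref, nref, replace = TRUE)])
    }, numeric(1))
  })
  fn <- stats::ecdf(maxima)
  out <- matrix(fn(Y), nrow(Y), ncol(Y), dimnames = dimnames(Y))
  set_values(suvr, out, transformation = "reference_ecdf")
}

#' Restrict a regional matrix to a region set
#'
#' @param matrix A `regional_matrix`.
#' @param regions The region table the matrix columns belong to.
#' @param mode `"full78"` (all regions present), `"cortical66"` (cortical
#'   set incl. hippocampus and amygdala) or `"bimodal_only"` (regions whose
#'   full-sample mixture fit was bimodal).
#' @param fits Per-region `mixture_fit` list (required for
#'   `"bimodal_only"`).
#' @return A `regional_matrix` with columns restricted and provenance
#'   updated.
#' @export
select_region_set <- function(matrix, regions,
                              mode = c("full78", "cortical66", "bimodal_only"),
                              fits = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "regional_matrix"),
            inherits(regions, "region_table"))
  keep <- switch(mode,
    full78 = matrix$regions,
    cortical66 = {
      cort <- regions$name[regions$tissue_class == "cortical" |
                             regions$base_name %in% c("hippocampus", "amygdala")]
      intersect(matrix$regions, cort)
    },
    bimodal_only = {
      if (is.null(fits)) stopf("bimodal_only requires mixture fits")
      bi <- names(fits)[vapply(fits, function(f) isTRUE(f$bimodal), logical(1))]
      intersect(matrix$regions, bi)
    })
  if (!length(keep)) stopf("region-set selection left no regions")
  vals <- matrix$values[, keep, drop = FALSE]
  set_values(matrix, vals, region_set = mode)
}
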