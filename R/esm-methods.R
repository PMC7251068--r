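# Methods for the fitted spreading model.

#' @export
print.esm_fit <- function(x, ...) {
  cat("Epidemic spreading model fit\n")
  cat(sprintf("  epicenter: %s\n", paste(x$epicenter, collapse = " + ")))
  cat(sprintf("  subjects: %d, regions: %d (%s connectome)\n",
              nrow(x$observed), ncol(x$observed), x$connectome_modality))
  cat(sprintf("  global r^2: %.3f   mean individual r^2: %.3f\n",
              x$global_r2, x$mean_individual_r2))
  if (x$n_undefined_r2 > 0) {
    cat(sprintf("  (%d subject(s) with undefined r^2 counted as 0)\n",
                x$n_undefined_r2))
  }
  invisible(x)
}

#' @export
summary.esm_fit <- function(object, ...) {
  pars <- object$parameters
  out <- list(
    global_r2 = object$global_r2,
    mean_individual_r2 = object$mean_individual_r2,
    sd_individual_r2 = stats::sd(pars$r_squared, na.rm = TRUE),
    n_undefined_r2 = object$n_undefined_r2,
    epicenter = object$epicenter,
    parameter_summary = rbind(
      beta = summary(pars$beta),
      delta = summary(pars$delta),
      t_eff = summary(pars$t_eff))
  )
  class(out) <- "summary.esm_fit"
  out
}

#' @export
print.summary.esm_fit <- function(x, ...) {
  cat(sprintf("ESM fit summary (epicenter %s)\n",
              paste(x$epicenter, collapse = " + ")))
  cat(sprintf("  global r^2 %.3f; individual r^2 mean %.3f (SD %.3f), %d undefined\n",
              x$global_r2, x$mean_individual_r2, x$sd_individual_r2,
              x$n_undefined_r2))
  cat("  fitted parameters:\n")
  print(round(x$parameter_summary, 3))
  invisible(x)
}

#' @export
coef.esm_fit <- function(object, ...) {
  m <- as.matrix(object$parameters[, c("beta", "delta", "t_eff")])
  rownames(m) <- object$parameters$subject
  m
}

#' @export
fitted.esm_fit <- function(object, ...) object$predicted

#' @export
residuals.esm_fit <- function(object, ...) {
  object$observed - object$predicted
}

#' Predict regional probabilities from a fitted spreading model
#'
#' Re-simulates each subject's fitted trajectory, optionally on a
#' different connectome or at different effective durations — e.g. to
#' forecast spread beyond the scan (`t_eff` larger than fitted).
#'
#' @param object An `esm_fit`.
#' @param connectome Connectome to simulate over; defaults to refusing if
#'   omitted since the fit does not store the weights (pass the one used
#'   to fit, or an alternative).
#' @param t_eff Optional vector (length 1 or n subjects) overriding the
#'   fitted durations.
#' @param dt Euler step.
#' @param ... Unused.
#' @return Subjects x regions matrix of predicted probabilities.
#' @export
predict.esm_fit <- function(object, connectome, t_eff = NULL, dt = NULL,
                            ...) {
  if (missing(connectome)) stopf("predict.esm_fit needs the connectome")
  dt <- dt %||% object$dt
  pars <- object$parameters
  te <- if (is.null(t_eff)) pars$t_eff else rep_len(t_eff, nrow(pars))
  out <- matrix(NA_real_, nrow(pars), ncol(object$observed),
                dimnames = dimnames(object$observed))
  for (i in seq_len(nrow(pars))) {
    out[i, ] <- esm_forward(connectome, object$epicenter,
                            list(beta = pars$beta[i], delta = pars$delta[i],
                                 t_eff = te[i], x0 = object$x0), dt = dt)
  }
  out
}

#' Simulate replicate cohorts from a fitted spreading model
#'
#' Draws `nsim` noisy replicates of the fitted predictions (Gaussian
#' regional noise, truncated to \[0, 1\]), the parametric-bootstrap
#' counterpart of the fit.
#'
#' @param object An `esm_fit`.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param noise_sd Regional noise SD on the probability scale.
#' @param ... Unused.
#' @return A list of `nsim` subjects x regions matrices.
#' @export
simulate.esm_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = 0.05, ...) {
  pred <- object$predicted
  with_seed(seed, {
    lapply(seq_len(nsim), function(k) {
      noisy <- pred + stats::rnorm(length(pred), sd = noise_sd)
      matrix(pmin(pmax(noisy, 0), 1), nrow(pred), ncol(pred),
             dimnames = dimnames(pred))
    })
  })
}

#' Plot predicted against observed mean regional tau probabilities
#'
#' Each point is a region; the x-axis is the cohort-mean predicted
#' tau-positive probability and the y-axis the cohort-mean observed
#' probability, with the identity line and the global r-squared annotated.
#'
#' @param x An `esm_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.esm_fit <- function(x, ...) {
  mp <- colMeans(x$predicted)
  mo <- colMeans(x$observed)
  lim <- range(0, mp, mo)
  graphics::plot(mp, mo, xlab = "mean predicted tau probability",
                 ylab = "mean observed tau probability",
                 xlim = lim, ylim = lim, pch = 19,
                 col = grDevices::grey(0.3, 0.7), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("global r2 = %.3f", x$global_r2))
  invisible(x)
}

#' Search for the best-fitting epicenter
#'
#' Refits the spreading model with alternative epicenters and ranks them.
#' Three modes:
#' \describe{
#'   \item{homotopic_pairs}{the model is refit seeding each left-right
#'     pair of regions; pairs are ranked by global r^2 (ties: higher mean
#'     individual r^2, then lower region index).}
#'   \item{single_regions}{as above with every single region as the sole
#'     epicenter.}
#'   \item{per_subject}{each subject is assigned the single-region
#'     epicenter minimizing that subject's SSE, and classified
#'     `left-limbic` / `right-limbic` / `other` from the region table's
#'     hemisphere and limbic flags.}
#' }
#'
#' @param matrix A probability `regional_matrix`.
#' @param connectome A `connectome` (its region table supplies pairing
#'   and limbic annotations).
#' @param mode Search mode.
#' @param grid An [esm_grid()]; epicenter searches typically use
#'   [esm_grid_coarse()].
#' @param dt Euler step.
#' @return For `homotopic_pairs` / `single_regions`: a data frame ranked
#'   by fit with columns `epicenter`, `global_r2`, `mean_individual_r2`,
#'   `rank`. For `per_subject`: a data frame with per-subject `epicenter`,
#'   `class`, `r_squared`, `sse`.
#' @export
epicenter_search <- function(matrix, connectome,
                             mode = c("homotopic_pairs", "single_regions",
                                      "per_subject"),
                             grid = esm_grid_coarse(), dt = 0.01) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "regional_matrix"),
            inherits(connectome, "connectome"))
  regions <- connectome$regions
  w <- connectome$weights[matrix$regions, matrix$regions]
  rsub <- regions[match(matrix$regions, regions$name), ]

  if (mode == "homotopic_pairs") {
    pairs <- homotopic_pairs(regions, cortical_only = FALSE)
    pairs <- pairs[regions$name[pairs$left_id] %in% matrix$regions &
                     regions$name[pairs$right_id] %in% matrix$regions, ]
    res <- lapply(seq_len(nrow(pairs)), function(i) {
      epi <- c(regions$name[pairs$left_id[i]],
               regions$name[pairs$right_id[i]])
      fit <- esm_fit(matrix, connectome, epi, grid = grid, dt = dt)
      data.frame(epicenter = pairs$base_name[i],
                 global_r2 = fit$global_r2,
                 mean_individual_r2 = fit$mean_individual_r2)
    })
    out <- do.call(rbind, res)
    ord <- order(-out$global_r2, -out$mean_individual_r2,
                 seq_len(nrow(out)))
    out <- out[ord, ]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    return(out)
  }

  # single-region machinery shared by the remaining two modes
  Y <- t(matrix$values)
  region_names <- matrix$regions
  per_region <- lapply(region_names, function(rn) {
    pre <- esm_precompute(w, rn, grid, dt = dt)
    P <- pre$predictions
    sse <- matrix(colSums(P^2), ncol(P), ncol(Y)) - 2 * crossprod(P, Y) +
      matrix(colSums(Y^2), ncol(P), ncol(Y), byrow = TRUE)
    best <- apply(sse, 2, which.min)
    list(sse = sse[cbind(best, seq_len(ncol(Y)))],
         best = best, P = P)
  })

  if (mode == "single_regions") {
    res <- lapply(seq_along(region_names), function(j) {
      pr <- per_region[[j]]
      pred <- pr$P[, pr$best, drop = FALSE]
      g <- r_squared(rowMeans(pred), rowMeans(Y))
      ind <- vapply(seq_len(ncol(Y)), function(k) {
        if (stats::sd(Y[, k]) == 0 || stats::sd(pred[, k]) == 0) 0
        else stats::cor(pred[, k], Y[, k])^2
      }, numeric(1))
      data.frame(epicenter = region_names[j],
                 global_r2 = if (is.na(g)) 0 else g,
                 mean_individual_r2 = mean(ind))
    })
    out <- do.call(rbind, res)
    ord <- order(-out$global_r2, -out$mean_individual_r2,
                 seq_len(nrow(out)))
    out <- out[ord, ]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    return(out)
  }

  # per_subject: best single-region epicenter for each subject
  sse_mat <- do.call(rbind, lapply(per_region, `[[`, "sse"))
  best_region <- apply(sse_mat, 2, which.min)
  epi_names <- region_names[best_region]
  info <- rsub[best_region, ]
  cls <- ifelse(info$limbic & info$hemisphere == "L", "left-limbic",
                ifelse(info$limbic & info$hemisphere == "R",
                       "right-limbic", "other"))
  r2 <- vapply(seq_len(ncol(Y)), function(k) {
    pr <- per_region[[best_region[k]]]
    pred <- pr$P[, pr$best[k]]
    if (stats::sd(Y[, k]) == 0 || stats::sd(pred) == 0) NA_real_
    else stats::cor(pred, Y[, k])^2
  }, numeric(1))
  data.frame(subject = matrix$subjects, epicenter = epi_names,
             class = cls, r_squared = r2,
             sse = sse_mat[cbind(best_region, seq_len(ncol(Y)))],
             stringsAsFactors = FALSE)
}
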