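# The epidemic spreading model (ESM).
#
# Regional tau-positive probability X_i(t) evolves on the row-normalized
# connectome C-hat according to
#
#   dX_i/dt = beta * (1 - X_i) * sum_j C-hat_ij X_j  -  delta * X_i
#
# i.e. production proportional to connectivity-weighted neighbour burden
# and remaining regional capacity, with first-order clearance. The signal
# is seeded at amplitude x0 on the epicenter region(s) and integrated for
# an effective duration t_eff (years) by explicit Euler with post-step
# clamping to [0, 1]. Subject-level parameters (beta, delta, t_eff) are
# fit by exhaustive grid search minimizing the sum of squared errors
# between simulated and observed probabilities; fit quality is the
# squared Pearson correlation (r^2).

# Row-normalize a connectome weight matrix: rows sum to 1 where nonzero.
row_normalize <- function(w) {
  rs <- rowSums(w)
  rs[rs == 0] <- 1
  w / rs
}

#' ESM parameter grid
#'
#' The candidate parameter sets searched when fitting the spreading model
#' to a subject. Defaults: production (`beta`) and clearance (`delta`)
#' rates each take 20 log-spaced values in \[0.01, 3\] per year plus 0;
#' effective durations 5, 10, ..., 50 years; the epicenter seed amplitude
#' `x0` is fixed at 0.1 and not fit.
#'
#' @param beta,delta Numeric vectors of candidate rates (1/year).
#' @param t_eff Numeric vector of candidate effective durations (years).
#' @param x0 Seed amplitude in (0, 1].
#' @return An `esm_grid` list.
#' @export
esm_grid <- function(beta = c(0, exp(seq(log(0.01), log(3), length.out = 20))),
                     delta = c(0, exp(seq(log(0.01), log(3), length.out = 20))),
                     t_eff = seq(5, 50, by = 5),
                     x0 = 0.1) {
  stopifnot(length(beta) > 0, length(delta) > 0, length(t_eff) > 0,
            all(beta >= 0), all(delta >= 0), all(t_eff > 0),
            x0 > 0, x0 <= 1)
  structure(list(beta = sort(unique(beta)), delta = sort(unique(delta)),
                 t_eff = sort(unique(t_eff)), x0 = x0),
            class = "esm_grid")
}

# A small grid for expensive ensemble work (null models, large searches).
#' @rdname esm_grid
#' @export
esm_grid_coarse <- function(beta = exp(seq(log(0.05), log(3), length.out = 8)),
                            delta = exp(seq(log(0.05), log(3), length.out = 8)),
                            t_eff = seq(5, 35, by = 10),
                            x0 = 0.1) {
  esm_grid(beta, delta, t_eff, x0)
}

#' Forward-simulate the epidemic spreading model
#'
#' Integrates the spreading dynamics from a seed at the epicenter
#' region(s) for `t_eff` years and returns the terminal regional
#' probability vector (optionally the whole trajectory).
#'
#' @param connectome A `connectome` (or bare symmetric weight matrix).
#' @param epicenter Integer region indices (or region names) seeded at
#'   amplitude `x0`; bilateral epicenters seed both regions equally.
#' @param params List with `beta`, `delta`, `t_eff`, `x0` (see
#'   [esm_grid()] for meanings and units).
#' @param dt Euler step in years. A step producing a state change larger
#'   than 0.5 anywhere aborts with a stability error.
#' @param trajectory If `TRUE`, also return the regions x steps matrix of
#'   states.
#' @return Named probability vector (or list with `final` and
#'   `trajectory`).
#' @examples
#' reg <- build_region_table("cortical66")
#' con <- simulate_connectome(reg, seed = 1)
#' p <- esm_forward(con, epicenter = c(4, 37),
#'                  params = list(beta = 0.5, delta = 0.2, t_eff = 20,
#'                                x0 = 0.1))
#' range(p)  # within [0, 1]
#' @export
esm_forward <- function(connectome, epicenter, params, dt = 0.01,
                        trajectory = FALSE) {
  w <- if (inherits(connectome, "connectome")) connectome$weights else connectome
  n <- nrow(w)
  epicenter <- .resolve_regions(epicenter, w)
  if (!length(epicenter)) stopf("epicenter must be non-empty")
  if (dt <= 0) stopf("dt must be positive")
  beta <- params$beta; delta <- params$delta
  t_eff <- params$t_eff; x0 <- params$x0 %||% 0.1
  stopifnot(beta >= 0, delta >= 0, t_eff > 0, x0 > 0, x0 <= 1)
  ch <- row_normalize(w)
  x <- numeric(n)
  x[epicenter] <- x0
  steps <- max(1L, as.integer(round(t_eff / dt)))
  traj <- if (trajectory) matrix(NA_real_, n, steps + 1L) else NULL
  if (trajectory) traj[, 1L] <- x
  for (s in seq_len(steps)) {
    dx <- dt * (beta * (1 - x) * as.numeric(ch %*% x) - delta * x)
    if (max(abs(dx)) > 0.5) {
      stopf("integration unstable: step change %.3f > 0.5 at dt=%g; reduce dt",
            max(abs(dx)), dt)
    }
    x <- pmin(pmax(x + dx, 0), 1)
    if (trajectory) traj[, s + 1L] <- x
  }
  names(x) <- rownames(w)
  if (trajectory) list(final = x, trajectory = traj) else x
}

.resolve_regions <- function(epicenter, w) {
  if (is.character(epicenter)) {
    idx <- match(epicenter, rownames(w))
    if (anyNA(idx)) {
      stopf("epicenter region(s) not found: %s",
            paste(epicenter[is.na(idx)], collapse = ", "))
    }
    idx
  } else {
    idx <- as.integer(epicenter)
    if (any(idx < 1 | idx > nrow(w))) stopf("epicenter index out of range")
    idx
  }
}

# Precompute the predicted probability vector for every grid parameter
# set at a fixed epicenter. Because the predictions are
# subject-independent, one integration sweep serves the whole cohort:
# states for all (beta, delta) combinations advance together as matrix
# columns and are snapshotted at each candidate t_eff.
esm_precompute <- function(connectome, epicenter, grid, dt = 0.01) {
  w <- if (inherits(connectome, "connectome")) connectome$weights else connectome
  n <- nrow(w)
  epicenter <- .resolve_regions(epicenter, w)
  ch <- row_normalize(w)
  bd <- expand.grid(beta = grid$beta, delta = grid$delta,
                    KEEP.OUT.ATTRS = FALSE)
  m <- nrow(bd)
  betas <- matrix(bd$beta, n, m, byrow = TRUE)
  deltas <- matrix(bd$delta, n, m, byrow = TRUE)
  X <- matrix(0, n, m)
  X[epicenter, ] <- grid$x0
  t_eff <- grid$t_eff
  snap_steps <- as.integer(round(t_eff / dt))
  total <- max(snap_steps)
  P <- matrix(NA_real_, n, m * length(t_eff))
  params <- data.frame(beta = rep(bd$beta, times = length(t_eff)),
                       delta = rep(bd$delta, times = length(t_eff)),
                       t_eff = rep(t_eff, each = m))
  for (s in seq_len(total)) {
    dX <- dt * (betas * (1 - X) * (ch %*% X) - deltas * X)
    mx <- max(abs(dX))
    if (mx > 0.5) {
      stopf("integration unstable: step change %.3f > 0.5 at dt=%g; reduce dt",
            mx, dt)
    }
    X <- pmin(pmax(X + dX, 0), 1)
    hit <- which(snap_steps == s)
    for (h in hit) P[, (h - 1L) * m + seq_len(m)] <- X
  }
  rownames(P) <- rownames(w)
  list(predictions = P, params = params, x0 = grid$x0,
       epicenter = epicenter)
}

#' Fit the spreading model to a single subject
#'
#' Exhaustive search over the parameter grid for the (beta, delta, t_eff)
#' set whose forward simulation is closest (minimal sum of squared
#' errors) to the observed regional probability vector.
#'
#' @param connectome A `connectome`.
#' @param epicenter Region indices or names seeded by the model.
#' @param observed Observed probability vector (one value per region, in
#'   \[0, 1\]).
#' @param grid An [esm_grid()].
#' @param dt Euler step (years).
#' @return A list with `params` (beta, delta, t_eff, x0), `predicted`,
#'   `r_squared` (`NA` when undefined), `sse`.
#' @export
fit_subject <- function(connectome, epicenter, observed,
                        grid = esm_grid(), dt = 0.01) {
  if (any(observed < 0 | observed > 1)) {
    stopf("observed values must lie in [0, 1]")
  }
  pre <- esm_precompute(connectome, epicenter, grid, dt = dt)
  sse <- colSums((pre$predictions - observed)^2)
  best <- which.min(sse)
  pred <- pre$predictions[, best]
  r2 <- if (stats::sd(observed) == 0 || stats::sd(pred) == 0) {
    NA_real_
  } else {
    stats::cor(pred, observed)^2
  }
  list(params = c(as.list(pre$params[best, ]), x0 = pre$x0),
       predicted = pred, r_squared = r2, sse = sse[best])
}

#' Fit the epidemic spreading model to a cohort
#'
#' The package's central fitting function. Each subject is fit
#' independently by grid search ([fit_subject()]'s procedure, implemented
#' jointly for speed: the candidate predictions are integrated once and
#' compared to every subject). Individual fit is the squared Pearson
#' correlation between predicted and observed regional probabilities;
#' global fit is the squared correlation between the subject-mean
#' predicted and subject-mean observed regional vectors.
#'
#' @param matrix A probability `regional_matrix` (subjects x regions).
#' @param connectome A `connectome` aligned to the matrix columns.
#' @param epicenter Region indices or names used as the model epicenter
#'   (a homotopic pair seeds both members at amplitude `x0`).
#' @param grid An [esm_grid()].
#' @param dt Euler step in years.
#' @return An object of class `esm_fit` with components `parameters`
#'   (per-subject data frame: beta, delta, t_eff, sse, r_squared),
#'   `predicted` (subjects x regions matrix), `observed`, `global_r2`,
#'   `mean_individual_r2` (undefined individual fits counted as 0),
#'   `epicenter`, `grid`, `connectome_modality`.
#' @seealso [epicenter_search()], [summarize_fit()], [null_significance()]
#' @export
esm_fit <- function(matrix, connectome, epicenter, grid = esm_grid(),
                    dt = 0.01) {
  stopifnot(inherits(matrix, "regional_matrix"))
  w <- if (inherits(connectome, "connectome")) connectome$weights else connectome
  if (!identical(matrix$regions, rownames(w))) {
    if (!all(matrix$regions %in% rownames(w))) {
      stopf("matrix regions missing from connectome")
    }
    w <- w[matrix$regions, matrix$regions]
  }
  Y <- t(matrix$values)                      # regions x subjects
  if (any(Y < 0 | Y > 1)) stopf("matrix must contain probabilities in [0, 1]")
  pre <- esm_precompute(w, .resolve_regions(epicenter, w), grid, dt = dt)
  P <- pre$predictions
  # SSE between every grid column and every subject in one crossproduct.
  sse <- matrix(colSums(P^2), ncol(P), ncol(Y)) - 2 * crossprod(P, Y) +
    matrix(colSums(Y^2), ncol(P), ncol(Y), byrow = TRUE)
  best <- apply(sse, 2, which.min)
  pred <- P[, best, drop = FALSE]
  sds_y <- apply(Y, 2, stats::sd)
  sds_p <- apply(pred, 2, stats::sd)
  r2 <- rep(NA_real_, ncol(Y))
  ok <- sds_y > 0 & sds_p > 0
  if (any(ok)) {
    r2[ok] <- vapply(which(ok), function(k) {
      stats::cor(pred[, k], Y[, k])^2
    }, numeric(1))
  }
  pars <- data.frame(subject = matrix$subjects,
                     pre$params[best, , drop = FALSE],
                     sse = sse[cbind(best, seq_len(ncol(Y)))],
                     r_squared = r2, row.names = NULL)
  global_r2 <- r_squared(rowMeans(pred), rowMeans(Y))
  pm <- t(pred)
  dimnames(pm) <- dimnames(matrix$values)
  structure(list(parameters = pars,
                 predicted = pm,
                 observed = matrix$values,
                 global_r2 = if (is.na(global_r2)) NA_real_ else global_r2,
                 mean_individual_r2 = mean(ifelse(is.na(r2), 0, r2)),
                 n_undefined_r2 = sum(is.na(r2)),
                 epicenter = rownames(w)[pre$epicenter],
                 grid = grid, x0 = pre$x0,
                 connectome_modality = if (inherits(connectome, "connectome"))
                   connectome$modality else "matrix",
                 dt = dt),
            class = "esm_fit")
}
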