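# Downstream statistics: fit summaries, null-model significance,
# Braak-stage summaries and cohort matching.

#' Squared Pearson correlation
#'
#' The package's fit statistic: the squared Pearson correlation between
#' two vectors. Note that perfect anticorrelation also yields 1 — this is
#' the documented behaviour of squared correlation, not a bug. Zero
#' variance in either vector makes the statistic undefined and returns
#' `NA`.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return A single value in \[0, 1\], or `NA` when undefined.
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch: %d vs %d",
                                    length(x), length(y))
  if (length(x) < 3) stopf("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Summarize a spreading-model fit, optionally by stratum
#'
#' Computes the global r^2 (squared correlation between subject-mean
#' predicted and observed regional vectors) and the mean/SD of individual
#' r^2 overall, plus the same quantities recomputed within each stratum
#' (e.g. amyloid status, diagnosis or cohort label) from the stratum-mean
#' vectors. Undefined individual r^2 values are excluded from means with
#' their count logged. Strata with fewer than 3 subjects are flagged.
#'
#' @param fit An [esm_fit()] object.
#' @param strata Optional vector of subject labels partitioning the
#'   cohort.
#' @return A `fit_summary`: list with `global_r2`, `mean_individual_r2`,
#'   `sd_individual_r2`, `n_undefined_r2`, and `strata` (data frame with
#'   per-stratum n, global and mean/SD individual r^2, `flagged`).
#' @export
summarize_fit <- function(fit, strata = NULL) {
  stopifnot(inherits(fit, "esm_fit"))
  r2 <- fit$parameters$r_squared
  out <- list(global_r2 = fit$global_r2,
              mean_individual_r2 = mean(r2, na.rm = TRUE),
              sd_individual_r2 = stats::sd(r2, na.rm = TRUE),
              n_undefined_r2 = sum(is.na(r2)),
              strata = NULL)
  if (!is.null(strata)) {
    stopifnot(length(strata) == nrow(fit$observed))
    levs <- unique(as.character(strata))
    rows <- lapply(levs, function(lv) {
      idx <- which(as.character(strata) == lv)
      g <- if (length(idx) >= 3) {
        r_squared(colMeans(fit$predicted[idx, , drop = FALSE]),
                  colMeans(fit$observed[idx, , drop = FALSE]))
      } else NA_real_
      data.frame(stratum = lv, n = length(idx),
                 global_r2 = g,
                 mean_individual_r2 = mean(r2[idx], na.rm = TRUE),
                 sd_individual_r2 = stats::sd(r2[idx], na.rm = TRUE),
                 flagged = length(idx) < 3)
    })
    out$strata <- do.call(rbind, rows)
  }
  class(out) <- "fit_summary"
  out
}

#' @export
print.fit_summary <- function(x, ...) {
  cat(sprintf("Fit summary: global r^2 %.3f; individual r^2 %.3f (SD %.3f), %d undefined\n",
              x$global_r2, x$mean_individual_r2, x$sd_individual_r2,
              x$n_undefined_r2))
  if (!is.null(x$strata)) {
    print(transform(x$strata,
                    global_r2 = round(global_r2, 3),
                    mean_individual_r2 = round(mean_individual_r2, 3),
                    sd_individual_r2 = round(sd_individual_r2, 3)))
  }
  invisible(x)
}

#' Significance of a fit statistic against connectome null models
#'
#' Refits the spreading model once per null connectome and compares the
#' observed statistic (global r^2 by default) with the null distribution.
#' The one-sided p-value is the exceedance count over the number of
#' nulls, floored at 1/n_null — with 100 nulls the smallest attainable p
#' is 0.01.
#'
#' @param observed Observed statistic (e.g. `fit$global_r2`).
#' @param matrix The probability `regional_matrix` the observed fit used.
#' @param nulls A [generate_nulls()] ensemble.
#' @param epicenter Epicenter used for the observed fit.
#' @param grid An [esm_grid()]; null refits typically use
#'   [esm_grid_coarse()].
#' @param statistic `"global_r2"` or `"mean_individual_r2"`.
#' @param dt Euler step.
#' @return A `null_significance`: list with `observed`, `null_values`,
#'   `null_mean`, `null_ci` (percentile 95% interval), `p_value`,
#'   `n_null` (after excluding failed refits), `n_failed`.
#' @export
null_significance <- function(observed, matrix, nulls, epicenter,
                              grid = esm_grid_coarse(),
                              statistic = c("global_r2",
                                            "mean_individual_r2"),
                              dt = 0.01) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(nulls, "null_ensemble"),
            inherits(matrix, "regional_matrix"))
  vals <- vapply(nulls$nulls, function(nw) {
    dimnames(nw) <- list(nulls$regions$name, nulls$regions$name)
    tryCatch({
      fit <- esm_fit(matrix,
                     new_connectome(nw, nulls$regions, nulls$modality),
                     epicenter, grid = grid, dt = dt)
      v <- fit[[statistic]]
      if (is.na(v)) 0 else v
    }, error = function(e) NA_real_)
  }, numeric(1))
  failed <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stopf("all null refits failed")
  n <- length(vals)
  p <- max(sum(vals >= observed) / n, 1 / n)
  structure(list(observed = observed, null_values = vals,
                 null_mean = mean(vals),
                 null_ci = unname(stats::quantile(vals, c(0.025, 0.975))),
                 p_value = p, n_null = n, n_failed = failed,
                 statistic = statistic),
            class = "null_significance")
}

#' @export
print.null_significance <- function(x, ...) {
  cat(sprintf("Null significance (%s): observed %.3f vs null mean %.3f [95%% CI %.3f, %.3f]\n",
              x$statistic, x$observed, x$null_mean,
              x$null_ci[1], x$null_ci[2]))
  cat(sprintf("  p = %.3g (%d nulls%s)\n", x$p_value, x$n_null,
              if (x$n_failed) sprintf(", %d failed refits excluded",
                                      x$n_failed) else ""))
  invisible(x)
}

#' Braak-stage summary of a regional probability matrix
#'
#' Summarizes a subject x region probability matrix over the six
#' Braak-stage ROIs: per-subject stage means, subjects ordered by total
#' tau, and nested stage maps obtained by binarizing the population-mean
#' regional vector at a decreasing sequence of thresholds.
#'
#' @param matrix A probability `regional_matrix`.
#' @param regions Region table with `braak_stage` defined for every
#'   included region.
#' @param thresholds Strictly decreasing threshold sequence.
#' @return A list with `stage_means` (subjects x 6), `population_stage_means`,
#'   `subject_order` (indices, least to most total tau), `threshold_maps`
#'   (regions x thresholds logical matrix; lower thresholds give
#'   supersets).
#' @export
braak_stage_summary <- function(matrix, regions,
                                thresholds = c(0.35, 0.25, 0.15, 0.05)) {
  stopifnot(inherits(matrix, "regional_matrix"),
            inherits(regions, "region_table"))
  if (any(diff(thresholds) >= 0)) {
    stopf("thresholds must be strictly decreasing")
  }
  stage <- regions$braak_stage[match(matrix$regions, regions$name)]
  if (anyNA(stage)) {
    stopf("braak_stage undefined for: %s",
          paste(matrix$regions[is.na(stage)], collapse = ", "))
  }
  V <- matrix$values
  stages <- sort(unique(stage))
  stage_means <- vapply(stages, function(s) {
    rowMeans(V[, stage == s, drop = FALSE])
  }, numeric(nrow(V)))
  colnames(stage_means) <- paste0("stage", stages)
  pop_mean <- colMeans(V)
  maps <- vapply(thresholds, function(th) pop_mean >= th,
                 logical(ncol(V)))
  colnames(maps) <- paste0("thr", thresholds)
  rownames(maps) <- matrix$regions
  list(stage_means = stage_means,
       population_stage_means = colMeans(stage_means),
       subject_order = order(rowSums(V)),
       threshold_maps = maps,
       thresholds = thresholds)
}

#' Match a pool of subjects to a reference sample
#'
#' Greedy nearest-neighbour matching without replacement on z-scored
#' features under Euclidean (Minkowski p = 2) distance: reference
#' subjects are processed in order and each takes the closest unused pool
#' subject. Used to subsample one cohort to resemble another on
#' demographics or tau load.
#'
#' @param reference,pool Data frames of subjects.
#' @param features Numeric columns to match on (must exist in both).
#' @return Integer vector (length `nrow(reference)`) of matched pool row
#'   indices, unique.
#' @export
match_cohorts <- function(reference, pool, features) {
  stopifnot(all(features %in% names(reference)),
            all(features %in% names(pool)))
  if (nrow(pool) < nrow(reference)) stopf("pool smaller than reference")
  R <- as.matrix(reference[, features, drop = FALSE])
  P <- as.matrix(pool[, features, drop = FALSE])
  if (!is.numeric(R) || !is.numeric(P)) stopf("features must be numeric")
  all_v <- rbind(R, P)
  mu <- colMeans(all_v)
  sdv <- apply(all_v, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Rz <- sweep(sweep(R, 2, mu), 2, sdv, "/")
  Pz <- sweep(sweep(P, 2, mu), 2, sdv, "/")
  used <- rep(FALSE, nrow(Pz))
  out <- integer(nrow(Rz))
  for (i in seq_len(nrow(Rz))) {
    d <- sqrt(colSums((t(Pz) - Rz[i, ])^2))
    d[used] <- Inf
    out[i] <- which.min(d)
    used[out[i]] <- TRUE
  }
  out
}
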