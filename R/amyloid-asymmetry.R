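# Regional amyloid-residual coupling and hemispheric asymmetry analyses.

#' Regional amyloid vs model residual report
#'
#' Regions the spreading model underestimates (observed > predicted mean
#' tau probability) are the candidates for amyloid-facilitated tau
#' expression: the report classifies regions by residual sign, compares
#' region-mean amyloid burden between the classes (Welch two-sample
#' t-test, underestimated minus overestimated), correlates regional
#' residuals with regional amyloid (Pearson), and fits an ordinary
#' least-squares model of residual on amyloid plus regional tau to check
#' the amyloid association is not driven by tau level itself.
#'
#' @param fit An [esm_fit()].
#' @param amyloid A `regional_matrix` of amyloid-positive probabilities
#'   over the same regions (obtained with the same regional
#'   mixture-modelling transform as tau).
#' @param tau_means Optional regional mean tau vector for the partial
#'   model; defaults to the fit's observed regional means.
#' @return An `amyloid_residual_report`: list with `table` (per-region
#'   residual, amyloid, tau, class), `t_test` (statistic, p, df),
#'   `correlation` (r, p), `partial_model` (coefficient table for amyloid
#'   and tau), `degenerate` flag.
#' @export
amyloid_residual_report <- function(fit, amyloid, tau_means = NULL) {
  stopifnot(inherits(fit, "esm_fit"), inherits(amyloid, "regional_matrix"))
  regs <- colnames(fit$observed)
  if (!all(regs %in% amyloid$regions)) {
    stopf("amyloid matrix missing regions used by the fit")
  }
  resid <- colMeans(fit$observed) - colMeans(fit$predicted)
  amy <- colMeans(amyloid$values[, regs, drop = FALSE])
  tau <- tau_means %||% colMeans(fit$observed)
  if (all(abs(resid) < 1e-12)) {
    return(structure(list(table = NULL, t_test = NULL, correlation = NULL,
                          partial_model = NULL, degenerate = TRUE),
                     class = "amyloid_residual_report"))
  }
  cls <- ifelse(resid > 0, "underestimated", "overestimated")
  tab <- data.frame(region = regs, residual = resid, amyloid = amy,
                    tau = tau, class = cls, row.names = NULL)

  tt <- NULL
  if (length(unique(cls)) == 2 && min(table(cls)) >= 2) {
    ht <- stats::t.test(amy[cls == "underestimated"],
                        amy[cls == "overestimated"])
    tt <- list(statistic = unname(ht$statistic), p_value = ht$p.value,
               df = unname(ht$parameter),
               mean_underestimated = mean(amy[cls == "underestimated"]),
               mean_overestimated = mean(amy[cls == "overestimated"]))
  }
  ct <- stats::cor.test(resid, amy)
  lm_fit <- stats::lm(resid ~ amy + tau)
  cf <- summary(lm_fit)$coefficients
  partial <- data.frame(term = rownames(cf), estimate = cf[, 1],
                        se = cf[, 2], t = cf[, 3], p = cf[, 4],
                        row.names = NULL)
  structure(list(table = tab, t_test = tt,
                 correlation = list(r = unname(ct$estimate),
                                    p_value = ct$p.value),
                 partial_model = partial, degenerate = FALSE),
            class = "amyloid_residual_report")
}

#' @export
print.amyloid_residual_report <- function(x, ...) {
  if (x$degenerate) {
    cat("Amyloid residual report: degenerate (all residuals zero)\n")
    return(invisible(x))
  }
  n_under <- sum(x$table$class == "underestimated")
  cat(sprintf("Amyloid residual report: %d underestimated / %d overestimated regions\n",
              n_under, nrow(x$table) - n_under))
  if (!is.null(x$t_test)) {
    cat(sprintf("  amyloid under vs over: t = %.2f, p = %.3g\n",
                x$t_test$statistic, x$t_test$p_value))
  }
  cat(sprintf("  residual-amyloid correlation r = %.3f, p = %.3g\n",
              x$correlation$r, x$correlation$p_value))
  invisible(x)
}

#' Per-subject laterality index
#'
#' Mean left-hemisphere minus mean right-hemisphere value across cortical
#' regions present in the matrix.
#'
#' @param matrix A `regional_matrix`.
#' @param regions Region table.
#' @return Numeric vector, one value per subject.
#' @export
laterality_index <- function(matrix, regions) {
  stopifnot(inherits(matrix, "regional_matrix"))
  info <- regions[match(matrix$regions, regions$name), ]
  cort <- info$tissue_class == "cortical"
  lt <- cort & info$hemisphere == "L"
  rt <- cort & info$hemisphere == "R"
  if (!any(lt) || !any(rt)) stopf("need cortical regions in both hemispheres")
  rowMeans(matrix$values[, lt, drop = FALSE]) -
    rowMeans(matrix$values[, rt, drop = FALSE])
}

#' Hemispheric asymmetry report
#'
#' Summarizes per-subject best-fitting epicenter classes (left-limbic /
#' right-limbic / other) and their association with tau asymmetry and
#' demographics: class proportions overall and per disease stage; GLMs of
#' the laterality index and of each covariate on epicenter class
#' adjusting for disease status; and per-region GLMs of tau on epicenter
#' hemisphere (left- vs right-limbic subjects) adjusting for disease
#' status, age and sex, with Benjamini-Hochberg FDR correction across
#' regions.
#'
#' @param per_subject_epicenters Data frame from
#'   [epicenter_search()] with `mode = "per_subject"` (columns `subject`,
#'   `class`).
#' @param matrix The probability `regional_matrix` (tau values).
#' @param regions Region table.
#' @param covariates Subject data frame with `diagnosis`, `age`, `sex`
#'   (and optionally `education`, `apoe4`).
#' @param q_threshold FDR threshold used for the discovery flag.
#' @return An `asymmetry_report`: list with `classes`, `proportions`,
#'   `proportions_by_stage`, `laterality` (per-subject index),
#'   `laterality_glm` (class coefficients), `covariate_glms`,
#'   `regional_glm` (per-region estimate/SE/t/p/q for the left-vs-right
#'   contrast), `underpowered` flag.
#' @export
asymmetry_report <- function(per_subject_epicenters, matrix, regions,
                             covariates, q_threshold = 0.05) {
  stopifnot(inherits(matrix, "regional_matrix"))
  cls <- factor(per_subject_epicenters$class,
                levels = c("left-limbic", "right-limbic", "other"))
  stopifnot(length(cls) == nrow(matrix$values))
  if (!all(c("diagnosis", "age", "sex") %in% names(covariates))) {
    stopf("covariates must include diagnosis, age, sex")
  }
  dx <- factor(covariates$diagnosis)

  prop <- prop.table(table(class = cls))
  prop_stage <- prop.table(table(stage = dx, class = cls), margin = 1)
  underpowered <- any(table(cls) < 5)

  lat <- laterality_index(matrix, regions)

  # laterality ~ class + disease status
  lat_glm <- .class_glm(lat, cls, dx)

  cov_glms <- list()
  for (v in intersect(c("age", "education", "apoe4", "sex"),
                      names(covariates))) {
    cov_glms[[v]] <- .class_glm(as.numeric(covariates[[v]]), cls, dx)
  }

  # per-region tau ~ hemisphere-of-epicenter among limbic-epicenter
  # subjects, adjusting for disease status, age, sex
  limb <- cls %in% c("left-limbic", "right-limbic")
  regional <- NULL
  if (sum(limb) >= 10 && length(unique(cls[limb])) == 2) {
    sub_cls <- droplevels(cls[limb])
    df0 <- data.frame(cls = sub_cls, dx = droplevels(dx[limb]),
                      age = covariates$age[limb],
                      sex = covariates$sex[limb])
    rows <- lapply(seq_len(ncol(matrix$values)), function(j) {
      df0$y <- matrix$values[limb, j]
      fit <- stats::lm(y ~ cls + dx + age + sex, data = df0)
      cf <- summary(fit)$coefficients
      row <- cf[grep("^cls", rownames(cf))[1], , drop = FALSE]
      data.frame(region = matrix$regions[j], estimate = row[1, 1],
                 se = row[1, 2], t = row[1, 3], p = row[1, 4])
    })
    regional <- do.call(rbind, rows)
    regional$q <- stats::p.adjust(regional$p, method = "BH")
    regional$significant <- regional$q < q_threshold
  }

  structure(list(classes = cls, proportions = prop,
                 proportions_by_stage = prop_stage,
                 laterality = lat, laterality_glm = lat_glm,
                 covariate_glms = cov_glms, regional_glm = regional,
                 underpowered = underpowered),
            class = "asymmetry_report")
}

# GLM of outcome on epicenter class adjusting for disease status;
# returns the class coefficient table and an overall class F-test p.
.class_glm <- function(y, cls, dx) {
  keep <- !is.na(y)
  df <- data.frame(y = y[keep], cls = droplevels(cls[keep]),
                   dx = droplevels(dx[keep]))
  if (nlevels(df$cls) < 2) return(NULL)
  fit <- stats::lm(y ~ cls + dx, data = df)
  null_fit <- stats::lm(y ~ dx, data = df)
  an <- stats::anova(null_fit, fit)
  cf <- summary(fit)$coefficients
  cls_rows <- grep("^cls", rownames(cf))
  list(coefficients = data.frame(term = rownames(cf)[cls_rows],
                                 estimate = cf[cls_rows, 1],
                                 se = cf[cls_rows, 2],
                                 t = cf[cls_rows, 3],
                                 p = cf[cls_rows, 4], row.names = NULL),
       class_f_p = an[["Pr(>F)"]][2])
}

#' @export
print.asymmetry_report <- function(x, ...) {
  cat("Asymmetry report\n  epicenter classes: ")
  cat(paste(names(x$proportions),
            sprintf("%.1f%%", 100 * as.numeric(x$proportions)),
            sep = " ", collapse = ", "), "\n")
  if (!is.null(x$laterality_glm)) {
    cat(sprintf("  laterality ~ class (adj. disease): F-test p = %.3g\n",
                x$laterality_glm$class_f_p))
  }
  if (!is.null(x$regional_glm)) {
    cat(sprintf("  regional GLMs: %d/%d regions significant at q < 0.05\n",
                sum(x$regional_glm$significant), nrow(x$regional_glm)))
  }
  if (x$underpowered) cat("  note: some classes have < 5 subjects\n")
  invisible(x)
}
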