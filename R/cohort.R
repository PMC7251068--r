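# Synthetic cohorts with known ground-truth spreading.
#
# The generator emulates the structure of the tau-PET study populations
# this package targets: ~312 subjects across the CN/MCI/AD spectrum with
# the demographic marginals of the combined discovery cohorts, regional
# tau-positive probabilities produced by the epidemic spreading model
# itself from a (default bilateral entorhinal) epicenter with
# subject-varying production/clearance/duration, an additive tau boost in
# amyloid-prone regions for amyloid-positive subjects, and SUVR emission
# through a per-region two-component measurement model with age/sex/
# choroid-plexus confound effects.

# Cortical regions with early, high-volume amyloid in typical disease:
# default target set of the amyloid boost.
.amyloid_vulnerable <- c(
  "precuneus", "posterior cingulate", "isthmus cingulate",
  "inferior parietal", "supramarginal", "medial orbitofrontal",
  "lateral orbitofrontal", "rostral middle frontal", "superior frontal"
)

#' Default synthetic cohort specification
#'
#' Returns the generator's study conditions: sample size and diagnostic
#' mix matching the combined discovery cohorts (162 CN / 89 MCI / 61 AD of
#' 312), demographic marginals (age 71.7 (7.1); 53.1% women; education
#' 14.6 (3.8); 51.7% APOE4; amyloid positivity 42.6% CN, 64.0% MCI, 100%
#' AD), and the spreading-parameter distributions. Clearance rates are
#' log-normal and production is clearance times a log-normal
#' production/clearance ratio whose median grows with disease stage, so
#' subjects are mid-course spreaders rather than fully saturated or
#' fully balanced; effective durations are uniform on 8-18 years and the
#' default epicenter is the bilateral entorhinal cortex.
#'
#' @param n Number of subjects.
#' @param epicenter_side `"bilateral"` seeds both epicenter regions;
#'   `"random"` seeds the left or right alone with equal probability per
#'   subject; `"left"`/`"right"` seed one side for every subject.
#' @param amyloid_boost Additive increment to terminal tau probability in
#'   the amyloid-vulnerable region set for amyloid-positive subjects
#'   (clamped at 1); 0 disables the tau-amyloid coupling.
#' @param noise_sd Observation noise SD added on the probability scale
#'   (truncated to \[0, 1\]).
#' @return A list of generator parameters accepted by
#'   [simulate_cohort()].
#' @export
cohort_spec <- function(n = 312L,
                        epicenter_side = c("bilateral", "random", "left",
                                           "right"),
                        amyloid_boost = 0.15, noise_sd = 0.05) {
  epicenter_side <- match.arg(epicenter_side)
  list(
    n = as.integer(n),
    diagnosis_probs = c(CN = 162, MCI = 89, AD = 61) / 312,
    age_mean = 71.7, age_sd = 7.1,
    prop_women = 0.531,
    education_mean = 14.6, education_sd = 3.8,
    prop_apoe4 = 0.517,
    amyloid_pos_by_dx = c(CN = 0.426, MCI = 0.640, AD = 1.0),
    cohort_labels = c("ADNI", "BioFINDER"),
    choroid_plexus_mean = 1.2, choroid_plexus_sd = 0.15,
    # spreading parameters: production/clearance balance grows with stage
    delta_meanlog = log(0.2), delta_sdlog = 0.20,
    ratio_meanlog = log(2.4), ratio_sdlog = 0.20,
    dx_ratio_multiplier = c(CN = 1.0, MCI = 1.3, AD = 1.6),
    beta_scale = 1.0,
    t_eff_range = c(8, 18),
    x0 = 0.1,
    epicenter_base = "entorhinal",
    epicenter_side = epicenter_side,
    amyloid_boost = amyloid_boost,
    amyloid_vulnerable = .amyloid_vulnerable,
    noise_sd = noise_sd
  )
}

#' Default SUVR emission specification
#'
#' Measurement model mapping tau-positive probabilities back to SUVR:
#' per region, a subject draws membership of the upper (abnormal)
#' component with its tau probability and an SUVR from the corresponding
#' Gaussian — lower component N(1.0, 0.10), upper N(1.6, 0.15), with a
#' small seeded per-region jitter on the means — after which linear age,
#' sex and choroid-plexus effects are added. Defaults give clearly
#' separated but overlapping modes, mimicking off-target background vs
#' abnormal binding.
#'
#' @param lower_mean,lower_sd,upper_mean,upper_sd Component parameters.
#' @param region_jitter_sd SD of the per-region jitter on both means.
#' @param age_coef,sex_coef,cp_coef Confound slopes (per year of age
#'   centred at 70; for sex coded 0/1; per unit of choroid-plexus signal
#'   centred at its mean).
#' @return A list of emission parameters for [suvr_emission()].
#' @export
emission_spec <- function(lower_mean = 1.0, lower_sd = 0.10,
                          upper_mean = 1.6, upper_sd = 0.15,
                          region_jitter_sd = 0.01,
                          age_coef = 0.002, sex_coef = 0.02,
                          cp_coef = 0.05) {
  if (lower_sd <= 0 || upper_sd <= 0) stopf("emission SDs must be positive")
  as.list(environment())
}

#' Emit SUVR values from tau-positive probabilities
#'
#' The generative counterpart of the mixture-probability transform: for
#' each subject x region cell, upper-component membership is drawn
#' Bernoulli(p) and the SUVR from the corresponding Gaussian; age, sex and
#' choroid-plexus effects are then added (when `covariates` is supplied).
#'
#' @param probabilities A probability `regional_matrix` (values in
#'   \[0, 1\]).
#' @param spec An [emission_spec()].
#' @param seed Integer seed.
#' @param covariates Optional data frame with `age`, `sex`,
#'   `choroid_plexus`; omit for pure mixture draws.
#' @return A `regional_matrix` of SUVR values (positive).
#' @export
suvr_emission <- function(probabilities, spec = emission_spec(), seed = 1L,
                          covariates = NULL) {
  stopifnot(inherits(probabilities, "regional_matrix"))
  P <- probabilities$values
  if (any(P < 0 | P > 1)) stopf("probabilities must lie in [0, 1]")
  if (spec$lower_sd <= 0 || spec$upper_sd <= 0) {
    stopf("emission SDs must be positive")
  }
  n <- nrow(P); k <- ncol(P)
  out <- with_seed(seed, {
    jit <- stats::rnorm(k, sd = spec$region_jitter_sd)
    lower_mu <- spec$lower_mean + jit
    upper_mu <- spec$upper_mean + jit
    member <- matrix(stats::rbinom(n * k, 1L, as.vector(P)), n, k)
    mu <- matrix(lower_mu, n, k, byrow = TRUE) * (1 - member) +
      matrix(upper_mu, n, k, byrow = TRUE) * member
    sd <- spec$lower_sd * (1 - member) + spec$upper_sd * member
    matrix(stats::rnorm(n * k, mean = mu, sd = sd), n, k)
  })
  if (!is.null(covariates)) {
    eff <- spec$age_coef * (covariates$age - 70) +
      spec$sex_coef * covariates$sex +
      spec$cp_coef * (covariates$choroid_plexus - mean(covariates$choroid_plexus))
    out <- out + eff  # recycled down columns: per-subject offset
  }
  out <- pmax(out, 0.05)  # SUVR is a positive ratio
  dimnames(out) <- dimnames(P)
  regional_matrix(out, probabilities$subjects, probabilities$regions,
                  list(transformation = "raw_suvr"))
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Draws subject demographics and spreading parameters from
#' [cohort_spec()], forward-simulates each subject's terminal tau
#' probabilities with the epidemic spreading model on the supplied
#' connectome, applies the amyloid tau boost to amyloid-positive
#' subjects, adds truncated Gaussian observation noise, and emits tau and
#' amyloid SUVR matrices through the measurement model. All ground-truth
#' quantities are recorded.
#'
#' @param regions A region table.
#' @param connectome A `connectome` aligned to `regions`.
#' @param spec A [cohort_spec()].
#' @param emission An [emission_spec()].
#' @param seed Master integer seed; regeneration is bit-identical.
#' @param dt Euler step for the forward simulations.
#' @return A `synthetic_cohort`: list with `subjects` (demographics
#'   data frame), `tau_probability` (noiseless-free observed probability
#'   `regional_matrix`, i.e. truth + noise + boost), `tau_suvr`,
#'   `amyloid_probability`, `amyloid_suvr`, `ground_truth` (per-subject
#'   beta/delta/t_eff/epicenter and the terminal probability matrix before
#'   noise), `regions`, `seed`.
#' @export
simulate_cohort <- function(regions, connectome, spec = cohort_spec(),
                            emission = emission_spec(), seed = 1L,
                            dt = 0.02) {
  stopifnot(inherits(regions, "region_table"),
            inherits(connectome, "connectome"))
  if (!identical(rownames(connectome$weights), regions$name)) {
    stopf("connectome misaligned to region table")
  }
  if (any(spec$diagnosis_probs < 0) ||
      abs(sum(spec$diagnosis_probs) - 1) > 1e-8) {
    stopf("invalid diagnosis distribution")
  }
  n <- spec$n
  subjects <- with_seed(child_seed(seed, 1L), {
    dx <- sample(names(spec$diagnosis_probs), n, replace = TRUE,
                 prob = spec$diagnosis_probs)
    data.frame(
      subject = sprintf("sub%04d", seq_len(n)),
      age = round(stats::rnorm(n, spec$age_mean, spec$age_sd), 1),
      sex = stats::rbinom(n, 1L, spec$prop_women),
      education = pmax(6, round(stats::rnorm(n, spec$education_mean,
                                             spec$education_sd))),
      diagnosis = factor(dx, levels = c("CN", "MCI", "AD")),
      apoe4 = stats::rbinom(n, 1L, spec$prop_apoe4),
      amyloid_status = stats::rbinom(n, 1L, spec$amyloid_pos_by_dx[dx]),
      cohort = sample(spec$cohort_labels, n, replace = TRUE),
      choroid_plexus = stats::rnorm(n, spec$choroid_plexus_mean,
                                    spec$choroid_plexus_sd),
      stringsAsFactors = FALSE
    )
  })

  gt <- with_seed(child_seed(seed, 2L), {
    mult <- spec$dx_ratio_multiplier[as.character(subjects$diagnosis)]
    delta <- stats::rlnorm(n, spec$delta_meanlog, spec$delta_sdlog)
    ratio <- stats::rlnorm(n, spec$ratio_meanlog, spec$ratio_sdlog) * mult
    beta <- delta * ratio * spec$beta_scale
    t_eff <- stats::runif(n, spec$t_eff_range[1], spec$t_eff_range[2])
    side <- switch(spec$epicenter_side,
                   bilateral = rep("both", n),
                   random = sample(c("L", "R"), n, replace = TRUE),
                   left = rep("L", n),
                   right = rep("R", n))
    list(beta = beta, delta = delta, t_eff = t_eff, side = side)
  })

  epi_left <- regions$name[regions$base_name == spec$epicenter_base &
                             regions$hemisphere == "L"]
  epi_right <- regions$name[regions$base_name == spec$epicenter_base &
                              regions$hemisphere == "R"]
  if (!length(epi_left) || !length(epi_right)) {
    stopf("epicenter base label '%s' not in region table",
          spec$epicenter_base)
  }
  epi_of <- function(side) switch(side, L = epi_left, R = epi_right,
                                  both = c(epi_left, epi_right))

  # Forward-simulate all subjects jointly (columns advance together; each
  # subject's state is snapshotted at its own duration).
  ch <- row_normalize(connectome$weights)
  nr <- nrow(ch)
  X <- matrix(0, nr, n)
  for (i in seq_len(n)) {
    X[match(epi_of(gt$side[i]), regions$name), i] <- spec$x0
  }
  betas <- matrix(gt$beta, nr, n, byrow = TRUE)
  deltas <- matrix(gt$delta, nr, n, byrow = TRUE)
  steps_of <- pmax(1L, as.integer(round(gt$t_eff / dt)))
  terminal <- matrix(NA_real_, nr, n)
  for (s in seq_len(max(steps_of))) {
    dX <- dt * (betas * (1 - X) * (ch %*% X) - deltas * X)
    if (max(abs(dX)) > 0.5) stopf("generator integration unstable at dt=%g", dt)
    X <- pmin(pmax(X + dX, 0), 1)
    done <- which(steps_of == s)
    if (length(done)) terminal[, done] <- X[, done]
  }
  truth_prob <- t(terminal)
  dimnames(truth_prob) <- list(subjects$subject, regions$name)

  # Amyloid boost: extra terminal tau probability in vulnerable regions
  # for amyloid-positive subjects.
  vuln_cols <- which(regions$base_name %in% spec$amyloid_vulnerable |
                       regions$name %in% spec$amyloid_vulnerable)
  observed <- truth_prob
  if (spec$amyloid_boost > 0 && length(vuln_cols)) {
    pos <- subjects$amyloid_status == 1L
    observed[pos, vuln_cols] <- pmin(observed[pos, vuln_cols] +
                                       spec$amyloid_boost, 1)
  }
  observed <- with_seed(child_seed(seed, 3L), {
    pmin(pmax(observed + stats::rnorm(length(observed),
                                      sd = spec$noise_sd), 0), 1)
  })
  tau_prob <- regional_matrix(observed, subjects$subject, regions$name,
                              list(transformation = "mixture_probability"))

  # Amyloid probabilities: high in vulnerable regions for positives, low
  # background elsewhere.
  amyp <- matrix(0.05, n, nr, dimnames = dimnames(observed))
  amyp[, vuln_cols] <- 0.10
  pos <- subjects$amyloid_status == 1L
  amyp[pos, ] <- 0.25
  amyp[pos, vuln_cols] <- 0.85
  amyp <- with_seed(child_seed(seed, 4L), {
    pmin(pmax(amyp + stats::rnorm(length(amyp), sd = 0.05), 0), 1)
  })
  amyloid_prob <- regional_matrix(amyp, subjects$subject, regions$name,
                                  list(transformation = "mixture_probability"))

  tau_suvr <- suvr_emission(tau_prob, emission,
                            seed = child_seed(seed, 5L),
                            covariates = subjects)
  amyloid_suvr <- suvr_emission(amyloid_prob, emission,
                                seed = child_seed(seed, 6L),
                                covariates = subjects)

  structure(list(
    subjects = subjects,
    tau_probability = tau_prob,
    tau_suvr = tau_suvr,
    amyloid_probability = amyloid_prob,
    amyloid_suvr = amyloid_suvr,
    ground_truth = list(beta = gt$beta, delta = gt$delta,
                        t_eff = gt$t_eff, epicenter_side = gt$side,
                        epicenter_regions = lapply(gt$side, epi_of),
                        terminal_probability = truth_prob,
                        x0 = spec$x0),
    regions = regions, spec = spec, emission = emission, seed = seed
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$subjects$diagnosis)
  cat(sprintf("Synthetic cohort: %d subjects (%s), %d regions, seed %s\n",
              nrow(x$subjects),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              ncol(x$tau_probability$values), format(x$seed)))
  cat(sprintf("  amyloid positive: %d; epicenter: %s (%s)\n",
              sum(x$subjects$amyloid_status),
              x$spec$epicenter_base, x$spec$epicenter_side))
  invisible(x)
}
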