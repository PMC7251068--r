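# Configuration and orchestration: the methodological decision axes, the
# full configuration grid, and the end-to-end pipeline over a (synthetic
# or file-based) cohort.

.config_axes <- list(
  transformation = c("mixture_probability", "minmax", "reference_ecdf"),
  region_set = c("full78", "cortical66", "bimodal_only"),
  confound_strategy = c("none", "residualize", "wscore"),
  pvc = c(FALSE, TRUE),
  include_abneg_mci = c(TRUE, FALSE),
  connectome_template = c("structural_young", "structural_old",
                          "functional_young", "functional_old")
)

#' Pipeline configuration
#'
#' One cell of the methodological decision grid: tau transformation,
#' region set, confound strategy, partial-volume-correction flag (an
#' input-provenance selector only — PVC itself happens at image level,
#' upstream of this package), inclusion of amyloid-negative MCI subjects,
#' and connectome template. The Euclidean-distance baseline is not an
#' axis of the grid; request it with `distance_baseline = TRUE`.
#'
#' @param transformation,region_set,confound_strategy,connectome_template
#'   One value from each axis (see [enumerate_grid()] for the option
#'   sets).
#' @param pvc,include_abneg_mci Logical flags.
#' @param distance_baseline If `TRUE`, diffuse over the
#'   centroid-distance similarity matrix instead of a connectome.
#' @param epicenter Base label of the (bilateral) model epicenter.
#' @param seed Master seed for every stochastic step.
#' @return An `esm_config` list.
#' @export
esm_config <- function(transformation = "mixture_probability",
                       region_set = "cortical66",
                       confound_strategy = "none",
                       pvc = FALSE,
                       include_abneg_mci = TRUE,
                       connectome_template = "structural_young",
                       distance_baseline = FALSE,
                       epicenter = "entorhinal",
                       seed = 1L) {
  cfg <- list(transformation = transformation, region_set = region_set,
              confound_strategy = confound_strategy, pvc = pvc,
              include_abneg_mci = include_abneg_mci,
              connectome_template = connectome_template,
              distance_baseline = distance_baseline,
              epicenter = epicenter, seed = as.integer(seed))
  for (ax in names(.config_axes)) {
    if (!cfg[[ax]] %in% .config_axes[[ax]]) {
      stopf("invalid %s: %s", ax, format(cfg[[ax]]))
    }
  }
  structure(cfg, class = "esm_config")
}

#' Enumerate the configuration grid
#'
#' Full Cartesian product of the supplied option sets (defaults: the six
#' methodological decision axes at their standard option counts, giving
#' 3 x 3 x 3 x 2 x 2 x 4 = 432 configurations), in deterministic order
#' (first axis varying fastest).
#'
#' @param axes Named list of option vectors; defaults to the standard
#'   axes.
#' @param seed Seed stored in every configuration.
#' @return A list of `esm_config` objects.
#' @export
enumerate_grid <- function(axes = .config_axes, seed = 1L) {
  stopifnot(length(axes) > 0, all(lengths(axes) > 0))
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    args <- as.list(grid[i, , drop = FALSE])
    args <- utils::modifyList(args, list(seed = seed))
    do.call(esm_config, args)
  })
}

#' Read / write a pipeline configuration
#'
#' YAML on disk (JSON also accepted on read, by extension); the
#' configuration round-trips unchanged.
#'
#' @param config An `esm_config`.
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `read_config()` returns an `esm_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "esm_config"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE)
  } else {
    yaml::write_yaml(unclass(config), path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(esm_config, lst)
}

#' @export
print.esm_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  for (f in names(unclass(x))) cat(sprintf("  %s: %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Run the end-to-end pipeline on a cohort
#'
#' Executes, under one configuration: subject filtering (optionally
#' excluding amyloid-negative MCI subjects), confound regression, the
#' SUVR-to-probability transformation, region-set selection, the
#' epidemic spreading model fit, and the fit summary stratified by
#' amyloid status, diagnosis and cohort. Fully determined by the
#' configuration's seed.
#'
#' @param config An [esm_config()].
#' @param cohort A [simulate_cohort()] object, or a list with elements
#'   `tau_suvr` (`regional_matrix`), `subjects` (data frame with
#'   `diagnosis`, `amyloid_status`, `age`, `sex`, `choroid_plexus`,
#'   `cohort`) and `regions` (`region_table`).
#' @param connectomes Named list of `connectome` objects; the
#'   configuration's `connectome_template` selects one (any name is
#'   accepted if the list has a single entry). Ignored when
#'   `distance_baseline` is set.
#' @param grid An [esm_grid()].
#' @param repeats CV repeats for the mixture transform.
#' @param dt Euler step.
#' @return An `esm_results` bundle: list with `config`, `fit`
#'   (`esm_fit`), `summary` (`fit_summary`), `matrix` (transformed
#'   probability matrix), `mixture_fits` (when applicable), `n_subjects`,
#'   `version`.
#' @export
run_pipeline <- function(config, cohort, connectomes, grid = esm_grid(),
                         repeats = 10L, dt = 0.01) {
  stopifnot(inherits(config, "esm_config"))
  regions <- cohort$regions
  suvr <- cohort$tau_suvr
  subjects <- cohort$subjects

  keep <- rep(TRUE, nrow(subjects))
  if (!config$include_abneg_mci) {
    keep <- !(subjects$diagnosis == "MCI" & subjects$amyloid_status == 0)
  }
  subjects <- subjects[keep, , drop = FALSE]
  suvr <- regional_matrix(suvr$values[keep, , drop = FALSE],
                          suvr$subjects[keep], suvr$regions,
                          utils::modifyList(suvr$provenance,
                                            list(pvc = config$pvc)))

  reference <- subjects$diagnosis == "CN" & subjects$amyloid_status == 0
  suvr <- regress_confounds(suvr, subjects,
                            strategy = config$confound_strategy,
                            reference_group = reference)

  mixfits <- NULL
  if (config$transformation == "mixture_probability" ||
      config$region_set == "bimodal_only") {
    tr <- mixture_probability_transform(
      suvr, repeats = repeats, seed = child_seed(config$seed, 11L))
    mixfits <- tr$fits
    prob <- tr$matrix
  }
  if (config$transformation == "minmax") {
    prob <- alternative_transform(suvr, "minmax")
  } else if (config$transformation == "reference_ecdf") {
    # reference signal: pooled choroid-plexus values stand in for the
    # reference-region sample
    prob <- alternative_transform(suvr, "reference_ecdf",
                                  reference_values = subjects$choroid_plexus,
                                  seed = child_seed(config$seed, 12L))
  }
  prob <- select_region_set(prob, regions, config$region_set,
                            fits = mixfits)

  con <- if (config$distance_baseline) {
    distance_similarity(regions)
  } else if (inherits(connectomes, "connectome")) {
    connectomes
  } else if (config$connectome_template %in% names(connectomes)) {
    connectomes[[config$connectome_template]]
  } else if (length(connectomes) == 1L) {
    connectomes[[1L]]
  } else {
    stopf("no connectome named '%s' supplied", config$connectome_template)
  }

  epi <- regions$name[regions$base_name == config$epicenter]
  epi <- intersect(epi, prob$regions)
  if (!length(epi)) stopf("epicenter '%s' absent from selected region set",
                          config$epicenter)
  fit <- esm_fit(prob, con, epi, grid = grid, dt = dt)
  summ <- summarize_fit(fit, strata = ifelse(subjects$amyloid_status == 1,
                                             "Abeta+", "Abeta-"))
  structure(list(config = config, fit = fit, summary = summ,
                 matrix = prob, mixture_fits = mixfits,
                 subjects = subjects,
                 n_subjects = nrow(subjects),
                 version = as.character(utils::packageVersion("tauspread"))),
            class = "esm_results")
}

#' @export
print.esm_results <- function(x, ...) {
  cat(sprintf("Pipeline results (%s / %s / %s, %d subjects)\n",
              x$config$transformation, x$config$region_set,
              x$config$confound_strategy, x$n_subjects))
  print(x$fit)
  invisible(x)
}
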