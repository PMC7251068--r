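test_that("the fit statistic is squared Pearson correlation with an undefined flag", {
  expect_equal(r_squared(c(1, 2, 3), c(2, 4, 6)), 1)
  # documented behaviour: perfect anticorrelation also scores 1
  expect_equal(r_squared(c(1, 2, 3), c(3, 2, 1)), 1)
  expect_true(is.na(r_squared(c(1, 1, 1), c(1, 2, 3))))
  expect_error(r_squared(1:4, 1:3), "length")
  expect_error(r_squared(1:2, 1:2), "at least 3")
})

test_that("fit summaries recompute stratum statistics from the raw stratum matrices", {
  coh <- fx_cohort()
  con <- fx_connectome()
  fit <- esm_fit(coh$tau_probability, con,
                 c("left entorhinal", "right entorhinal"),
                 grid = fx_grid_small(), dt = 0.02)
  strata <- rep(c("a", "b"), length.out = 40)
  s <- summarize_fit(fit, strata)
  expect_equal(nrow(s$strata), 2)
  for (lv in c("a", "b")) {
    idx <- strata == lv
    direct <- r_squared(colMeans(fit$predicted[idx, ]),
                        colMeans(fit$observed[idx, ]))
    expect_equal(s$strata$global_r2[s$strata$stratum == lv], direct)
    expect_equal(s$strata$mean_individual_r2[s$strata$stratum == lv],
                 mean(fit$parameters$r_squared[idx], na.rm = TRUE))
  }
  # identical strata produce identical summaries
  s2 <- summarize_fit(fit, rep(c("a", "b"), each = 20))
  coh2 <- fx_cohort()
  expect_equal(s$global_r2, s2$global_r2)
  # tiny stratum flagged
  s3 <- summarize_fit(fit, c("x", rep("y", 39)))
  expect_true(s3$strata$flagged[s3$strata$stratum == "x"])
})

test_that("null significance applies the exceedance count with its floor and ceiling", {
  reg <- fx_regions()
  con <- fx_connectome()
  coh <- simulate_cohort(reg, con, cohort_spec(n = 15, amyloid_boost = 0),
                         seed = 2)
  ne <- generate_nulls(con, n = 20, seed = 3)
  mini <- esm_grid(beta = c(0.2, 0.6, 1.5), delta = c(0.1, 0.3),
                   t_eff = c(10, 16))
  fit <- esm_fit(coh$tau_probability, con,
                 c("left entorhinal", "right entorhinal"),
                 grid = mini, dt = 0.05)
  ns <- null_significance(fit$global_r2, coh$tau_probability, ne,
                          c("left entorhinal", "right entorhinal"),
                          grid = mini, dt = 0.05)
  expect_equal(ns$n_null, 20)
  expect_equal(ns$p_value, 1 / 20)     # observed beats every null: floor
  expect_true(all(ns$null_values < ns$observed))
  expect_true(ns$null_ci[1] <= ns$null_mean, ns$null_ci[2] >= ns$null_mean)
  # an observed value below every null hits the ceiling
  ns0 <- null_significance(-1, coh$tau_probability, ne,
                           c("left entorhinal", "right entorhinal"),
                           grid = mini, dt = 0.05)
  expect_equal(ns0$p_value, 1)
  # counting rule at the null median (constructed check on the same nulls)
  med <- stats::median(ns$null_values)
  ns_med <- null_significance(med, coh$tau_probability, ne,
                              c("left entorhinal", "right entorhinal"),
                              grid = mini, dt = 0.05)
  expect_equal(ns_med$p_value, sum(ns$null_values >= med) / 20)
})

test_that("Braak stage summaries are monotone for entorhinal-first spread and nested across thresholds", {
  reg <- fx_regions()
  con <- fx_connectome()
  coh <- simulate_cohort(reg, con, cohort_spec(n = 120, amyloid_boost = 0),
                         seed = 12)
  bs <- braak_stage_summary(coh$tau_probability, reg)
  expect_true(all(diff(bs$population_stage_means) < 0))
  expect_equal(dim(bs$stage_means), c(120, 6))
  expect_equal(bs$subject_order,
               order(rowSums(coh$tau_probability$values)))
  # nesting: each lower threshold includes every region of the higher one
  maps <- bs$threshold_maps
  for (j in 2:ncol(maps)) expect_true(all(maps[, j] >= maps[, j - 1]))
  expect_error(braak_stage_summary(coh$tau_probability, reg,
                                   thresholds = c(0.1, 0.2)),
               "decreasing")
  # a single hot region is present in all four maps
  one <- matrix(0, 4, 66, dimnames = list(paste0("s", 1:4), reg$name))
  one[, 5] <- 0.5
  m1 <- regional_matrix(one, provenance = list(transformation = "mixture_probability"))
  bs1 <- braak_stage_summary(m1, reg)
  expect_true(all(bs1$threshold_maps[5, ]))
  expect_true(all(!bs1$threshold_maps[-5, ]))
})

test_that("greedy cohort matching equals a brute-force oracle and respects uniqueness", {
  set.seed(3)
  pool <- data.frame(age = rnorm(180, 72, 7), edu = rnorm(180, 14, 3),
                     tau = rnorm(180, 1.3, 0.2))
  refs <- data.frame(age = rnorm(60, 70, 6), edu = rnorm(60, 15, 3),
                     tau = rnorm(60, 1.25, 0.15))
  idx <- match_cohorts(refs, pool, c("age", "edu", "tau"))
  expect_length(idx, 60)
  expect_false(anyDuplicated(idx) > 0)
  # independent oracle: z-score jointly, then greedy nearest neighbour
  all_v <- rbind(as.matrix(refs), as.matrix(pool))
  mu <- colMeans(all_v); sdv <- apply(all_v, 2, sd)
  Rz <- scale(as.matrix(refs), mu, sdv)
  Pz <- scale(as.matrix(pool), mu, sdv)
  used <- rep(FALSE, nrow(Pz)); oracle <- integer(nrow(Rz))
  for (i in seq_len(nrow(Rz))) {
    d <- sqrt(rowSums((Pz - matrix(Rz[i, ], nrow(Pz), 3,
                                   byrow = TRUE))^2))
    d[used] <- Inf
    oracle[i] <- which.min(d); used[oracle[i]] <- TRUE
  }
  expect_equal(idx, oracle)
  # exact copies in the pool are matched at distance zero
  pool2 <- rbind(refs, pool)
  idx2 <- match_cohorts(refs, pool2, c("age", "edu", "tau"))
  expect_equal(idx2, seq_len(60))
  expect_error(match_cohorts(pool, refs, c("age", "edu", "tau")), "pool")
})
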