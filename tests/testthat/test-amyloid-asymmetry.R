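test_that("the planted amyloid boost is detected as regional underestimation", {
  reg <- fx_regions()
  con <- fx_connectome()
  coh <- simulate_cohort(reg, con, cohort_spec(n = 80), seed = 3)
  fit <- esm_fit(coh$tau_probability, con,
                 c("left entorhinal", "right entorhinal"),
                 grid = esm_grid_coarse(), dt = 0.02)
  rep <- amyloid_residual_report(fit, coh$amyloid_probability)
  expect_false(rep$degenerate)
  expect_equal(sort(unique(rep$table$class)),
               c("overestimated", "underestimated"))
  # classification is the sign of the residual, exhaustively
  expect_equal(rep$table$class == "underestimated", rep$table$residual > 0)
  vuln <- reg$base_name[match(rep$table$region, reg$name)] %in%
    tauspread:::.amyloid_vulnerable
  expect_true(mean(rep$table$class[vuln] == "underestimated") > 0.9)
  # boosted regions carry more amyloid: positive t, significant
  expect_gt(rep$t_test$statistic, 0)
  expect_lt(rep$t_test$p_value, 0.05)
  expect_gt(rep$correlation$r, 0)
  expect_lt(rep$correlation$p_value, 0.05)
  # the amyloid term survives adjustment for regional tau
  amy_row <- rep$partial_model[rep$partial_model$term == "amy", ]
  expect_gt(amy_row$estimate, 0)
  expect_lt(amy_row$p, 0.05)
  # amyloid-positive subjects, whose tau the connectivity-only model
  # cannot fully explain, fit worse than amyloid-negative subjects
  s <- summarize_fit(fit, strata = ifelse(coh$subjects$amyloid_status == 1,
                                          "pos", "neg"))
  expect_lt(s$strata$global_r2[s$strata$stratum == "pos"],
            s$strata$global_r2[s$strata$stratum == "neg"])
})

test_that("an exact model fit yields a degenerate residual report", {
  coh <- fx_cohort()
  con <- fx_connectome()
  fit <- esm_fit(coh$tau_probability, con,
                 c("left entorhinal", "right entorhinal"),
                 grid = fx_grid_small(), dt = 0.02)
  fit$observed <- fit$predicted  # force residuals to zero
  rep <- amyloid_residual_report(fit, coh$amyloid_probability)
  expect_true(rep$degenerate)
})

test_that("laterality is zero for hemispherically symmetric subjects", {
  reg <- fx_regions()
  pairs <- homotopic_pairs(reg)
  v <- matrix(runif(2 * 66), 2, 66, dimnames = list(c("s1", "s2"), reg$name))
  v[, pairs$right_id] <- v[, pairs$left_id]
  m <- regional_matrix(v, provenance = list(transformation = "mixture_probability"))
  expect_equal(unname(laterality_index(m, reg)), c(0, 0))
})

test_that("left-seeded cohorts produce left-dominant classes and positive laterality", {
  reg <- fx_regions()
  conL <- simulate_connectome(reg, seed = 1,
                              limbic_homotopic_strength = 0.02)
  spec <- cohort_spec(n = 40, epicenter_side = "left", amyloid_boost = 0)
  coh <- simulate_cohort(reg, conL, spec, seed = 6)
  ps <- epicenter_search(coh$tau_probability, conL, "per_subject",
                         grid = esm_grid_coarse(), dt = 0.02)
  tab <- table(factor(ps$class, c("left-limbic", "right-limbic", "other")))
  # left-limbic dominates and essentially no contralateral calls
  expect_equal(names(which.max(tab)), "left-limbic")
  expect_lte(unname(tab["right-limbic"]), 2)
  li <- laterality_index(coh$tau_probability, reg)
  expect_gt(mean(li > 0), 0.75)
  expect_lt(t.test(li, alternative = "greater")$p.value, 0.001)
  rep <- asymmetry_report(ps, coh$tau_probability, reg, coh$subjects)
  expect_s3_class(rep, "asymmetry_report")
  expect_equal(unname(rep$proportions["left-limbic"]),
               unname(tab["left-limbic"] / 40))
})

test_that("epicenter class associates with laterality in mixed-side cohorts", {
  reg <- fx_regions()
  conL <- simulate_connectome(reg, seed = 1,
                              limbic_homotopic_strength = 0.02)
  spec <- cohort_spec(n = 60, epicenter_side = "random", amyloid_boost = 0)
  coh <- simulate_cohort(reg, conL, spec, seed = 8)
  ps <- epicenter_search(coh$tau_probability, conL, "per_subject",
                         grid = esm_grid_coarse(), dt = 0.02)
  rep <- asymmetry_report(ps, coh$tau_probability, reg, coh$subjects)
  expect_lt(rep$laterality_glm$class_f_p, 0.01)
  # regional GLM table carries BH-adjusted q-values
  expect_false(is.null(rep$regional_glm))
  expect_equal(rep$regional_glm$q,
               p.adjust(rep$regional_glm$p, method = "BH"))
  # essentially no cross-side confusion among limbic classifications
  side <- coh$ground_truth$epicenter_side
  expect_lte(sum(side == "L" & ps$class == "right-limbic") +
               sum(side == "R" & ps$class == "left-limbic"), 2)
})
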