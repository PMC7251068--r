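test_that("confound regression removes a planted age effect", {
  reg <- fx_regions()
  set.seed(3)
  n <- 500
  covs <- data.frame(age = rnorm(n, 72, 7), sex = rbinom(n, 1, 0.5),
                     choroid_plexus = rnorm(n, 1.2, 0.15))
  base <- matrix(rnorm(n * 66, 1.2, 0.1), n, 66,
                 dimnames = list(paste0("s", 1:n), reg$name))
  planted <- base + 0.02 * (covs$age - 70)   # strong linear age effect
  suvr <- regional_matrix(planted)
  out <- regress_confounds(suvr, covs, "residualize")
  cors <- apply(out$values, 2, cor, y = covs$age)
  expect_lt(max(abs(cors)), 0.02)
  # grand means preserved so values stay on the SUVR scale
  expect_equal(colMeans(out$values), colMeans(planted), tolerance = 1e-10)
  # identity strategy
  expect_equal(regress_confounds(suvr, covs, "none")$values, suvr$values)
})

test_that("w-scores are zero for reference subjects lying on the reference fit", {
  reg <- fx_regions()
  n <- 100
  set.seed(12)
  covs <- data.frame(age = seq(60, 80, length.out = n),
                     sex = rbinom(n, 1, 0.5),
                     choroid_plexus = rnorm(n, 1.2, 0.1))
  v <- matrix(1 + 0.01 * covs$age + 0.05 * covs$sex +
                0.2 * covs$choroid_plexus + rnorm(n * 66, sd = 0.05),
              n, 66, dimnames = list(paste0("s", 1:n), reg$name))
  refmask <- rep(TRUE, n); refmask[1] <- FALSE
  # place the held-out subject exactly on the reference model's fit
  X <- cbind(1, as.matrix(covs))
  beta_hat <- solve(crossprod(X[refmask, ]),
                    crossprod(X[refmask, ], v[refmask, ]))
  v[1, ] <- X[1, , drop = FALSE] %*% beta_hat
  suvr <- regional_matrix(v)
  out <- regress_confounds(suvr, covs, "wscore", reference_group = refmask)
  expect_equal(max(abs(out$values[1, ])), 0, tolerance = 1e-8)
  # w-scores in the reference group are standardized residuals
  expect_equal(unname(apply(out$values[refmask, ], 2, sd)), rep(1, 66),
               tolerance = 0.02)
  expect_error(regress_confounds(suvr, covs, "wscore",
                                 reference_group = rep(FALSE, n)),
               "reference")
})

test_that("mixture transform yields bounded, monotone probabilities close to the full-sample posterior", {
  reg <- fx_regions()
  set.seed(6)
  n <- 250
  prev <- seq(0.15, 0.45, length.out = 6)
  vals <- sapply(prev, function(p) {
    memb <- rbinom(n, 1, p)
    rnorm(n, ifelse(memb == 1, 1.6, 1.0), ifelse(memb == 1, 0.15, 0.1))
  })
  dimnames(vals) <- list(paste0("s", 1:n), reg$name[1:6])
  suvr <- regional_matrix(vals)
  tr <- mixture_probability_transform(suvr, repeats = 3, seed = 2)
  expect_true(all(tr$matrix$values >= 0 & tr$matrix$values <= 1))
  expect_length(tr$failed, 0)
  # CV-averaged values track the full-sample posterior
  full <- sapply(seq_along(tr$fits), function(j) {
    posterior_upper(tr$fits[[j]], vals[, j])
  })
  expect_lt(mean(abs(full - tr$matrix$values)), 0.02)
  # posterior pinning at the extremes, under the recovered fit
  f1 <- tr$fits[[1]]
  expect_gt(posterior_upper(f1, f1$means[2] + 3 * f1$sds[2]), 0.99)
  expect_lt(posterior_upper(f1, f1$means[1]), 0.05)
})

test_that("alternative transforms hit their documented endpoints", {
  reg <- fx_regions()
  set.seed(8)
  vals <- matrix(runif(50 * 4, 1, 2), 50, 4,
                 dimnames = list(paste0("s", 1:50), reg$name[1:4]))
  suvr <- regional_matrix(vals)
  mm <- alternative_transform(suvr, "minmax")
  expect_equal(unname(apply(mm$values, 2, min)), rep(0, 4))
  expect_equal(unname(apply(mm$values, 2, max)), rep(1, 4))
  ref <- rnorm(200, 1.2, 0.1)
  ec <- alternative_transform(suvr, "reference_ecdf", reference_values = ref,
                              n_boot = 2000, seed = 3)
  expect_true(all(ec$values >= 0 & ec$values <= 1))
  # values below every bootstrap maximum map to 0, above every one to 1
  lo <- regional_matrix(matrix(0.2, 5, 4,
                               dimnames = list(paste0("a", 1:5),
                                               reg$name[1:4])))
  hi <- regional_matrix(matrix(9, 5, 4,
                               dimnames = list(paste0("a", 1:5),
                                               reg$name[1:4])))
  expect_equal(unname(alternative_transform(lo, "reference_ecdf",
                                            reference_values = ref,
                                            n_boot = 500,
                                            seed = 3)$values[1, 1]), 0)
  expect_equal(unname(alternative_transform(hi, "reference_ecdf",
                                            reference_values = ref,
                                            n_boot = 500,
                                            seed = 3)$values[1, 1]), 1)
  zero_spread <- regional_matrix(matrix(1, 5, 4,
                                        dimnames = list(paste0("a", 1:5),
                                                        reg$name[1:4])))
  expect_error(alternative_transform(zero_spread, "minmax"), "spread")
})

test_that("region-set selection restricts columns and drops planted unimodal regions", {
  reg78 <- build_region_table("full78")
  set.seed(5)
  n <- 150
  vals <- matrix(rnorm(n * 78, 1.2, 0.1), n, 78,
                 dimnames = list(paste0("s", 1:n), reg78$name))
  suvr <- regional_matrix(vals)
  m66 <- select_region_set(suvr, reg78, "cortical66")
  expect_equal(ncol(m66$values), 66)
  expect_equal(m66$provenance$region_set, "cortical66")
  # bimodal_only with one planted unimodal region among bimodal ones
  bimix <- sapply(1:5, function(j) {
    memb <- rbinom(n, 1, 0.4)
    rnorm(n, ifelse(memb == 1, 1.7, 1.0), 0.1)
  })
  vals5 <- cbind(bimix, rnorm(n, 1.2, 0.08))
  dimnames(vals5) <- list(paste0("s", 1:n), reg78$name[1:6])
  tr <- mixture_probability_transform(regional_matrix(vals5),
                                      repeats = 2, seed = 4)
  sel <- select_region_set(tr$matrix, reg78, "bimodal_only", fits = tr$fits)
  expect_false(reg78$name[6] %in% sel$regions)
  expect_setequal(sel$regions, reg78$name[1:5])
  # all-bimodal input is untouched
  all_bi <- tr$fits[vapply(tr$fits, function(f) f$bimodal, logical(1))]
  m_bi <- regional_matrix(tr$matrix$values[, names(all_bi), drop = FALSE],
                          provenance = tr$matrix$provenance)
  expect_equal(ncol(select_region_set(m_bi, reg78, "bimodal_only",
                                      fits = all_bi)$values),
               length(all_bi))
})
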