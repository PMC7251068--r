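# Forward-model correctness is checked against closed forms and an
# independent adaptive ODE integrator (deSolve), then the grid-search
# fitting layer against self-consistency and noisy recovery.

test_that("zero coupling reduces to exponential clearance of the seed", {
  w <- matrix(0, 4, 4, dimnames = rep(list(paste0("r", 1:4)), 2))
  p <- esm_forward(w, 1, list(beta = 0.7, delta = 0.5, t_eff = 2, x0 = 0.1),
                   dt = 1e-5)
  expect_lt(abs(p[1] - 0.1 * exp(-0.5 * 2)), 1e-6)
  expect_equal(unname(p[2:4]), rep(0, 3))
})

test_that("frozen and saturating limits behave as expected", {
  w <- matrix(1, 6, 6, dimnames = rep(list(paste0("r", 1:6)), 2))
  diag(w) <- 0
  frozen <- esm_forward(w, 2, list(beta = 0, delta = 0, t_eff = 7, x0 = 0.3))
  expect_equal(unname(frozen), c(0, 0.3, 0, 0, 0, 0))
  sat <- esm_forward(w, 1, list(beta = 1, delta = 0, t_eff = 100, x0 = 0.1))
  expect_true(all(sat > 0.99))
  # balanced production and clearance: little to no spreading
  bal <- esm_forward(w, 1, list(beta = 0.3, delta = 0.3, t_eff = 30,
                                x0 = 0.05))
  expect_lt(max(bal), 0.1)
  expect_lt(max(bal[-1]), 0.05)
})

test_that("Euler integration matches an independent adaptive integrator to 1e-3", {
  set.seed(11)
  for (rep in 1:4) {
    n <- sample(4:10, 1)
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- runif(n * (n - 1) / 2) *
      (runif(n * (n - 1) / 2) < 0.6)
    w <- w + t(w)
    dimnames(w) <- rep(list(paste0("r", seq_len(n))), 2)
    pars <- list(beta = runif(1, 0.3, 1.5), delta = runif(1, 0.05, 0.5),
                 t_eff = runif(1, 3, 12), x0 = 0.1)
    ours <- esm_forward(w, 1, pars, dt = 5e-4)
    ch <- tauspread:::row_normalize(w)
    rhs <- function(t, x, p) {
      list(pars$beta * (1 - x) * as.numeric(ch %*% x) - pars$delta * x)
    }
    ref <- deSolve::ode(c(pars$x0, rep(0, n - 1)), c(0, pars$t_eff), rhs,
                        NULL, method = "ode45")
    expect_lt(max(abs(ours - ref[2, -1])), 1e-3)
  }
})

test_that("trajectories stay within [0,1] and respond monotonically to the rates", {
  reg <- fx_regions()
  con <- fx_connectome()
  set.seed(13)
  for (rep in 1:3) {
    beta <- runif(1, 0.2, 1.5); delta <- runif(1, 0.05, 0.6)
    tr <- esm_forward(con, sample(66, 2),
                      list(beta = beta, delta = delta, t_eff = 15, x0 = 0.1),
                      trajectory = TRUE)
    expect_true(all(tr$trajectory >= 0 & tr$trajectory <= 1))
    expect_gte(sum(esm_forward(con, 1:2, list(beta = beta * 1.5,
                                              delta = delta, t_eff = 15,
                                              x0 = 0.1))),
               sum(esm_forward(con, 1:2, list(beta = beta, delta = delta,
                                              t_eff = 15, x0 = 0.1))))
    expect_lte(sum(esm_forward(con, 1:2, list(beta = beta,
                                              delta = delta * 1.5,
                                              t_eff = 15, x0 = 0.1))),
               sum(esm_forward(con, 1:2, list(beta = beta, delta = delta,
                                              t_eff = 15, x0 = 0.1))))
  }
})

test_that("unstable steps and bad epicenters are rejected", {
  w <- matrix(1, 5, 5, dimnames = rep(list(paste0("r", 1:5)), 2))
  diag(w) <- 0
  expect_error(esm_forward(w, 1, list(beta = 3, delta = 0, t_eff = 5,
                                      x0 = 0.9), dt = 1), "unstable")
  expect_error(esm_forward(w, integer(0),
                           list(beta = 1, delta = 0, t_eff = 5, x0 = 0.1)),
               "non-empty")
  expect_error(esm_forward(w, "left entorhinal",
                           list(beta = 1, delta = 0, t_eff = 5, x0 = 0.1)),
               "not found")
})

test_that("a noise-free subject at a grid point is recovered exactly", {
  con <- fx_connectome()
  grid <- fx_grid_small()
  truth <- list(beta = grid$beta[3], delta = grid$delta[2],
                t_eff = grid$t_eff[2], x0 = 0.1)
  obs <- esm_forward(con, c(4, 37), truth, dt = 0.02)
  fit <- fit_subject(con, c(4, 37), obs, grid = grid, dt = 0.02)
  expect_equal(fit$params$beta, truth$beta)
  expect_equal(fit$params$delta, truth$delta)
  expect_equal(fit$params$t_eff, truth$t_eff)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(fit$sse, 1e-20)
})

test_that("an all-zero subject selects a no-spread regime with flagged r-squared", {
  con <- fx_connectome()
  fit <- fit_subject(con, c(4, 37), rep(0, 66), grid = fx_grid_small(),
                     dt = 0.02)
  expect_lt(sum(fit$predicted), 0.01)
  expect_true(is.na(fit$r_squared))
})

test_that("noisy subjects are recovered with high fit and a faithful rate balance", {
  con <- fx_connectome()
  grid <- fx_grid_small()
  set.seed(21)
  ok_r2 <- ok_ratio <- logical(8)
  for (i in 1:8) {
    truth <- list(beta = runif(1, 0.3, 1.2), delta = runif(1, 0.1, 0.5),
                  t_eff = runif(1, 8, 18), x0 = 0.1)
    clean <- esm_forward(con, c(4, 37), truth, dt = 0.02)
    obs <- pmin(pmax(clean + rnorm(66, sd = 0.05), 0), 1)
    fit <- fit_subject(con, c(4, 37), obs, grid = grid, dt = 0.02)
    ok_r2[i] <- fit$r_squared > 0.8
    ratio <- (fit$params$beta / fit$params$delta) / (truth$beta / truth$delta)
    ok_ratio[i] <- ratio > 0.5 && ratio < 2
  }
  expect_gte(mean(ok_r2), 7 / 8)
  expect_gte(mean(ok_ratio), 7 / 8)
})

test_that("cohort fitting reduces correctly to perfect and singleton cases", {
  reg <- fx_regions()
  con <- fx_connectome()
  grid <- fx_grid_small()
  # observations generated exactly at grid points for 6 subjects
  set.seed(31)
  obs <- t(sapply(1:6, function(i) {
    esm_forward(con, c(4, 37),
                list(beta = sample(grid$beta, 1),
                     delta = sample(grid$delta, 1),
                     t_eff = sample(grid$t_eff, 1), x0 = 0.1), dt = 0.02)
  }))
  dimnames(obs) <- list(paste0("s", 1:6), reg$name)
  mat <- regional_matrix(obs, provenance = list(transformation = "mixture_probability"))
  fit <- esm_fit(mat, con, c(4, 37), grid = grid, dt = 0.02)
  expect_equal(fit$global_r2, 1, tolerance = 1e-8)
  expect_equal(unname(fit$parameters$r_squared), rep(1, 6),
               tolerance = 1e-8)
  expect_equal(fit$mean_individual_r2, 1, tolerance = 1e-8)
  expect_equal(fit$predicted, fit$observed, tolerance = 1e-10)
  # singleton cohort: global fit equals the subject's fit
  one <- regional_matrix(obs[1, , drop = FALSE],
                         provenance = list(transformation = "mixture_probability"))
  f1 <- esm_fit(one, con, c(4, 37), grid = grid, dt = 0.02)
  expect_equal(f1$global_r2, f1$parameters$r_squared[1])
})

test_that("esm_fit methods expose coefficients, residuals, predictions and replicates", {
  coh <- fx_cohort()
  con <- fx_connectome()
  fit <- esm_fit(coh$tau_probability, con,
                 c("left entorhinal", "right entorhinal"),
                 grid = fx_grid_small(), dt = 0.02)
  cf <- coef(fit)
  expect_equal(dim(cf), c(40, 3))
  expect_equal(colnames(cf), c("beta", "delta", "t_eff"))
  expect_equal(residuals(fit), fit$observed - fitted(fit))
  pr <- predict(fit, con)
  expect_equal(pr, fitted(fit), tolerance = 1e-10)
  # forecasting beyond the fitted duration never lowers burden when
  # production dominates for a high-ratio subject
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_true(all(sims[[1]] >= 0 & sims[[1]] <= 1))
  expect_identical(simulate(fit, nsim = 2, seed = 1), sims)
  s <- summary(fit)
  expect_s3_class(s, "summary.esm_fit")
  expect_output(print(s), "global r\\^2")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
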