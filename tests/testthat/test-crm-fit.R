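test_that("loss matches hand evaluation and self-consistency", {
  p <- crm_params(x0_tilde = 0.1, C0_tilde = 0.05, A0 = 2, A0c = 2,
                  gamma = 4.8)
  times <- default_time_grid()
  pair <- nitrate_pair(times, simulate_crm(p, times)$A,
                       times, simulate_crm(p, times, growth_on = FALSE)$A)
  expect_lt(crm_loss(p, pair), 1e-16)

  # flat data matched by zero biomass
  p0 <- crm_params(x0_tilde = 0, C0_tilde = 0.05, A0 = 2, A0c = 2)
  flat <- nitrate_pair(0:3, rep(2, 4), 0:3, rep(2, 4))
  expect_equal(crm_loss(p0, flat), 0)

  # two-point toy: linear decline 2 - 0.1 t, data [2, 1.8] in both arms
  ptoy <- crm_params(x0_tilde = 0.1, C0_tilde = 1e-8, A0 = 2, A0c = 2,
                     gamma = 4.8, K_A = 1e-7, K_C_tilde = 1e-7)
  toy <- nitrate_pair(c(0, 1), c(2, 1.8), c(0, 1), c(2, 1.8))
  expect_equal(crm_loss(ptoy, toy), 0.005, tolerance = 1e-5)
})

test_that("loss depends only on the set of (time, value) points", {
  p <- crm_params(x0_tilde = 0.1, C0_tilde = 0.05, A0 = 2, A0c = 2)
  times <- default_time_grid()
  am <- simulate_crm(p, times)$A + 0.05
  ap <- simulate_crm(p, times, growth_on = FALSE)$A - 0.03
  base <- crm_loss(p, nitrate_pair(times, am, times, ap))
  # dropping a point from one arm: each sum runs over its own points and the
  # normalizer is the total point count
  drop1 <- crm_loss(p, nitrate_pair(times[-4], am[-4], times, ap))
  resid4 <- (simulate_crm(p, times)$A[4] - am[4])^2
  expect_equal(drop1, (base * 20 - resid4) / 19, tolerance = 1e-8)
  # scale consistency: doubling concentrations quadruples the loss, so the
  # RMSE normalized by a doubled input is unchanged
  p2 <- crm_params(x0_tilde = 0.2, C0_tilde = 0.1, A0 = 4, A0c = 4,
                   gamma = p$gamma, K_A = 2 * p$K_A,
                   K_C_tilde = 2 * p$K_C_tilde)
  l2 <- crm_loss(p2, nitrate_pair(times, 2 * am, times, 2 * ap))
  expect_equal(sqrt(l2) / 4, sqrt(base) / 2, tolerance = 1e-6)
})

test_that("noiseless fits recover the generating parameters", {
  truth <- crm_params(x0_tilde = 0.1, C0_tilde = 0.05, A0 = 2, A0c = 2,
                      gamma = 4.8, K_A = 0.01, K_C_tilde = 0.01)
  pair <- synth_nitrate_pair(truth, noise_sd = 0, seed = 1)$pair
  fit <- fit_crm(pair, gamma = 4.8, n_starts = 4, seed = 11)
  cf <- coef(fit)
  expect_true(fit$converged)
  expect_lt(abs(cf[["x0_tilde"]] - 0.1) / 0.1, 0.02)
  expect_lt(abs(cf[["gammaC0_tilde"]] - 4.8 * 0.05) / (4.8 * 0.05), 0.02)
})

test_that("a flat pair fits to negligible biomass activity", {
  flat <- nitrate_pair(default_time_grid(), rep(2, 10),
                       default_time_grid(), rep(2, 10))
  fit <- fit_crm(flat, n_starts = 3, seed = 2)
  expect_lte(coef(fit)[["x0_tilde"]], 1.1e-4)
  expect_lt(fit$rmse_norm, 1e-4)
})

test_that("fits are deterministic given the seed", {
  truth <- crm_params(x0_tilde = 0.01, C0_tilde = 0.5, A0 = 2, A0c = 2,
                      gamma = 4.8)
  pair <- synth_nitrate_pair(truth, noise_sd = 0.02, seed = 9)$pair
  f1 <- fit_crm(pair, n_starts = 4, seed = 77)
  f2 <- fit_crm(pair, n_starts = 4, seed = 77)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loss, f2$loss)
})

test_that("per-point errors stay below 10% of input nitrate at 2% noise", {
  set.seed(5)
  anchors <- regime_scenarios()
  for (truth in anchors) {
    truth$gamma <- 4.8
    pair <- synth_nitrate_pair(truth, noise_sd = 0.02)$pair
    fit <- fit_crm(pair, gamma = 4.8, n_starts = 4, seed = 3)
    expect_lt(max(fit$per_point_err), 0.10)
  }
})

test_that("fit methods expose predictions, residuals and simulation", {
  truth <- crm_params(x0_tilde = 0.1, C0_tilde = 0.05, A0 = 2, A0c = 2,
                      gamma = 4.8)
  pair <- synth_nitrate_pair(truth, noise_sd = 0, seed = 4)$pair
  fit <- fit_crm(pair, gamma = 4.8, n_starts = 2, seed = 5)

  pred <- predict(fit, times = c(0, 1, 2))
  expect_named(pred, c("chl-", "chl+"))
  expect_equal(nrow(pred[["chl-"]]), 3)

  res <- residuals(fit)
  expect_equal(nrow(res), 20)
  expect_lt(max(abs(res$residual)), 1e-3)

  sims <- simulate(fit, nsim = 2, seed = 6, noise_sd = 0.02)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "nitrate_pair")

  sm <- summary(fit)
  expect_equal(sm$regime$label, "II")
})

test_that("replicate panels aggregate to condition medians", {
  truth <- crm_params(x0_tilde = 0.1, C0_tilde = 0.05, A0 = 2, A0c = 2,
                      gamma = 4.8)
  pairs <- lapply(1:3, function(r) {
    synth_nitrate_pair(truth, noise_sd = 0.02, seed = 100 + r,
                       soil_id = "s1", perturbed_pH = 6,
                       replicate = r)$pair
  })
  panel <- fit_crm_panel(pairs, n_starts = 3, seed = 8)
  expect_equal(nrow(panel$fits), 3)
  expect_equal(nrow(panel$conditions), 1)
  expect_equal(panel$conditions$x0_tilde,
               stats::median(panel$fits$x0_tilde))
  expect_equal(panel$conditions$n_replicates, 3)
})

test_that("sensitivity scan is near zero when fixed at truth", {
  sc <- regime_scenarios()[2]
  out <- sensitivity_scan(sc, gamma_grid = 4, K_grid = 0.01,
                          n_starts = 3, seed = 10)
  expect_true(all(out$rmse_norm < 1e-3))
})

test_that("amendment-ratio fitting recovers the planted stoichiometry", {
  base <- crm_params(x0_tilde = 0.1, C0_tilde = 0.05, A0 = 2, A0c = 2,
                     gamma = 4.8)
  doses <- c(0, 0.25, 0.5)
  make_series <- function(ratio, seed) {
    lapply(seq_along(doses), function(i) {
      tr <- base
      tr$C0_tilde <- base$C0_tilde + doses[i] * ratio
      synth_nitrate_pair(tr, noise_sd = 0, seed = seed + i)$pair
    })
  }
  fit2 <- fit_amendment_ratio(make_series(2, 1), base, doses)
  expect_lt(abs(fit2$ratio - 2) / 2, 0.10)
  # zero-dose series reduces to the base fit
  expect_lt(fit2$per_dose$loss[1], 1e-12)
  # fast (glucose-like) vs slow (acetate-like) utilization ordering
  fit1 <- fit_amendment_ratio(make_series(1, 7), base, doses)
  expect_gt(fit2$ratio, fit1$ratio)
  expect_error(fit_amendment_ratio(make_series(2, 1)[1], base, doses[1]),
               "at least 2 doses")
})

test_that("rate-based inference maps DEA/DP onto the model parameters", {
  expect_equal(infer_from_rates(1, 1),
               list(x0_tilde = 1, gammaC0_tilde = 0, clipped = FALSE))
  expect_equal(infer_from_rates(2, 5)$gammaC0_tilde, 3)
  expect_warning(out <- infer_from_rates(2, 1.5), "clipped")
  expect_equal(out$gammaC0_tilde, 0)
  expect_true(out$clipped)
  expect_error(infer_from_rates(-1, 2), "non-negative")
})
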