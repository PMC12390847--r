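test_that("rescaling applies the printed parameter combinations", {
  raw <- crm_params_raw(x0 = 0.1, r_A = 1, r_C = 1, K_A = 0.01, K_C = 0.01,
                        gamma = 4, A0 = 2, C0 = 0.05)
  p <- rescale_params(raw)
  expect_equal(p$x0_tilde, 0.1)
  expect_equal(p$C0_tilde, 0.05)

  raw2 <- crm_params_raw(x0 = 0.05, r_A = 2, r_C = 1, K_A = 0.01,
                         K_C = 0.005, gamma = 4, A0 = 2, C0 = 0.025)
  p2 <- rescale_params(raw2)
  expect_equal(p2$x0_tilde, 0.1)
  expect_equal(p2$C0_tilde, 0.05)
  expect_equal(p2$K_C_tilde, 0.01)

  raw_bad <- crm_params_raw(x0 = 0.1, r_A = 1, r_C = 0, K_A = 0.01,
                            K_C = 0.01, gamma = 4, A0 = 2, C0 = 0.05)
  expect_error(rescale_params(raw_bad), "rescal")
})

test_that("rescaled system reproduces raw-system nitrate dynamics", {
  times <- seq(0, 4, by = 0.25)
  set.seed(42)
  for (i in 1:5) {
    raw <- crm_params_raw(x0 = runif(1, 0.01, 0.2), r_A = runif(1, 0.5, 3),
                          r_C = runif(1, 0.5, 3), K_A = 0.01, K_C = 0.01,
                          gamma = runif(1, 2, 6), A0 = 2,
                          C0 = runif(1, 0.01, 0.5))
    a_raw <- integrate_raw_oracle(raw, times)[, "A"]
    a_resc <- simulate_crm(rescale_params(raw), times)$A
    expect_lt(max(abs(a_raw - a_resc)), 1e-6)
  }
})

test_that("simulation honours limiting cases and the chloramphenicol arm", {
  times <- default_time_grid()
  # no biomass, no consumption
  p0 <- crm_params(x0_tilde = 0, C0_tilde = 0.05, A0 = 2, A0c = 2)
  expect_equal(simulate_crm(p0, times)$A, rep(2, length(times)))

  # growth arrested: constant-rate decline at x0_tilde while A >> K_A
  p <- crm_params(x0_tilde = 0.1, C0_tilde = 0.05, A0 = 2, A0c = 2,
                  K_A = 0.01)
  tr <- simulate_crm(p, times, growth_on = FALSE)
  rates <- -diff(tr$A) / diff(tr$time)
  keep <- tr$A[-1] > 10 * p$K_A
  expect_true(all(abs(rates[keep] - 0.1) / 0.1 < 0.01))

  # resurgent-growth scenario: accelerating decline, exhausted by day 4
  p3 <- crm_params(x0_tilde = 0.001, C0_tilde = 2, A0 = 2, A0c = 2,
                   gamma = 4, K_A = 0.01, K_C_tilde = 0.01)
  tr3 <- simulate_crm(p3, seq(0, 4, by = 0.5))
  expect_lt(tr3$A[length(tr3$A)], 0.05)
  rate3 <- -diff(tr3$A) / diff(tr3$time)
  expect_gt(rate3[4], rate3[1])  # decline accelerates
})

test_that("trajectories are monotone and non-negative", {
  set.seed(7)
  for (i in 1:8) {
    p <- crm_params(x0_tilde = 10^runif(1, -3, -0.5),
                    C0_tilde = 10^runif(1, -2.5, 0.4),
                    A0 = 2, A0c = 2, gamma = runif(1, 2, 6))
    for (arm in c(TRUE, FALSE)) {
      tr <- simulate_crm(p, seq(0, 4, by = 0.1), growth_on = arm)
      expect_true(all(diff(tr$A) <= 1e-9))
      expect_true(all(diff(tr$C_tilde) <= 1e-9))
      expect_true(all(diff(tr$x_tilde) >= -1e-9))
      expect_true(all(tr$A >= 0 & tr$C_tilde >= 0 & tr$x_tilde >= 0))
    }
  }
})

test_that("growth-arrest time matches the closed-form expression", {
  p <- crm_params(x0_tilde = 0.1, C0_tilde = 0.05, A0 = 2, A0c = 2,
                  gamma = 4)
  expect_equal(growth_stop_time(p), log(3) / 4, tolerance = 1e-12)

  # nitrate runs out first when the nutrient pool is effectively infinite
  p2 <- crm_params(x0_tilde = 0.001, C0_tilde = 50, A0 = 2, A0c = 2,
                   gamma = 4)
  expect_equal(growth_stop_time(p2), log(2 * 4 / 0.001 + 1) / 4)

  # gamma -> 0 limit: constant-rate depletion
  p3 <- crm_params(x0_tilde = 0.1, C0_tilde = 0.05, A0 = 2, A0c = 2,
                   gamma = 0)
  expect_equal(growth_stop_time(p3), 0.05 / 0.1)

  p4 <- crm_params(x0_tilde = 0, C0_tilde = 0.05, A0 = 2, A0c = 2)
  expect_identical(growth_stop_time(p4), Inf)
})

test_that("ODE nutrient-exhaustion time approaches t* for small affinities", {
  p <- crm_params(x0_tilde = 0.1, C0_tilde = 0.05, A0 = 2, A0c = 2,
                  gamma = 4, K_A = 1e-4, K_C_tilde = 1e-4)
  tr <- simulate_crm(p, seq(0, 0.5, by = 5e-4))
  crossing <- tr$time[min(which(tr$C_tilde < p$K_C_tilde))]
  expect_lt(abs(crossing - growth_stop_time(p)) / growth_stop_time(p), 0.02)
})

test_that("closed form has the stated post-arrest slope and degenerate limits", {
  p <- crm_params(x0_tilde = 0.1, C0_tilde = 0.05, A0 = 2, A0c = 2,
                  gamma = 4)
  tstar <- growth_stop_time(p)
  tt <- tstar + c(0.5, 1)
  cf <- closed_form_crm(p, tt)
  slope <- -(diff(cf$A) / diff(cf$time))
  expect_equal(slope, 4 * 0.05 + 0.1, tolerance = 1e-10)

  p0 <- crm_params(x0_tilde = 0, C0_tilde = 0.05, A0 = 2, A0c = 2)
  expect_equal(closed_form_crm(p0, 0:4)$A, rep(2, 5))
})

test_that("closed form approaches the ODE solution as affinities shrink", {
  tt <- seq(0, 4, by = 0.02)
  # oracle-computed sup-norm gaps at K = 0.01 (dense 4-day grid): the gap is
  # largest at the resurgent-growth exhaustion corner and shrinks ~10x per
  # decade of K
  gap_at <- function(K) {
    vapply(regime_scenarios(), function(s) {
      s$K_A <- K; s$K_C_tilde <- K
      max(abs(closed_form_crm(s, tt)$A - simulate_crm(s, tt)$A))
    }, numeric(1))
  }
  g1 <- gap_at(1e-2)
  expect_equal(g1, c(0.0119, 0.0234, 0.1876), tolerance = 0.05)
  g2 <- gap_at(1e-3)
  g3 <- gap_at(1e-4)
  expect_true(all(g2 < g1))
  expect_true(all(g3 < g2))
  expect_lt(max(g3), 0.003)
})

test_that("long-format export carries all state variables and the arm", {
  p <- crm_params(x0_tilde = 0.1, C0_tilde = 0.05, A0 = 2, A0c = 2)
  tr <- simulate_crm(p, c(0, 1, 2), growth_on = FALSE)
  long <- trajectory_long(tr)
  expect_equal(nrow(long), 9)
  expect_setequal(unique(long$variable), c("A", "C_tilde", "x_tilde"))
  expect_true(all(long$arm == "chl+"))
  expect_equal(long$value[long$variable == "A"], tr$A)
})
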