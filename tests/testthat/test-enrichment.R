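test_that("noise standard deviation follows the two-term formula", {
  expect_equal(noise_sd(0, noise_model(0.1, 4.5)), 4.5)
  expect_equal(noise_sd(50, noise_model(0.1, 0)), 5)
  expect_equal(noise_sd(20, noise_model(0.2, 3)), 5)
  expect_equal(noise_sd(c(0, 20), noise_model(0.2, 3)), c(3, 5))
})

test_that("noise model is recovered from synthetic replicate profiles", {
  sr <- synth_replicates(n_asv = 2000, n_replicates = 3,
                         c_frac = 0.21, c0 = 4.5, seed = 2)
  nm <- fit_noise_model(sr$counts)
  expect_lt(abs(nm$c_frac - 0.21) / 0.21, 0.2)
  expect_lt(abs(nm$c0 - 4.5) / 4.5, 0.2)

  # identical replicates: no noise at all
  flat <- matrix(rep(c(0, 5, 100, 2000), each = 3), nrow = 3)
  nm0 <- fit_noise_model(flat, high_thresh = 50)
  expect_equal(nm0$c_frac, 0)
  expect_equal(nm0$c0, 0)

  # purely fractional truth: fitted constant term stays below one count
  srf <- synth_replicates(n_asv = 2000, c_frac = 0.21, c0 = 0,
                          mean_log = log(500), sd_log = 1, seed = 3)
  nmf <- fit_noise_model(srf$counts)
  expect_lt(nmf$c0, 1)

  expect_error(fit_noise_model(matrix(1:5, nrow = 1)), "2 replicates")
  low <- matrix(rpois(60, 3), nrow = 3)
  expect_error(fit_noise_model(low), "high_thresh")
  expect_warning(out <- fit_noise_model(low, fallback = noise_model(0.2, 4)),
                 "fallback")
  expect_equal(out$c_frac, 0.2)
})

test_that("critical z matches the printed Bonferroni values and inversion", {
  expect_equal(round(critical_z(0.05, 2000), 1), 4.2)
  expect_equal(round(critical_z(0.05, 2500), 1), 4.3)
  expect_equal(round(critical_z(0.05, 1), 2), 1.96)
  # brute-force inversion of the normal CDF
  for (n in c(10, 300, 5000)) {
    zc <- critical_z(0.05, n)
    brute <- uniroot(function(z) 1 - pnorm(z) - 0.05 / (2 * n),
                     c(0, 10), tol = 1e-10)$root
    expect_equal(zc, brute, tolerance = 1e-6)
  }
  # strictly increasing in the number of tests
  zs <- vapply(c(10, 100, 1000, 10000), function(n) critical_z(0.05, n),
               numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("z-scores follow the depth-matched convention", {
  nm <- noise_model(0.2, 4.5)
  # identical arms score zero
  cm <- matrix(c(50, 60, 70), 3, 4)
  z0 <- enrichment_zscores(cm, cm, rep(1000, 3), rep(1000, 3), nm)
  expect_equal(unname(z0), rep(0, 4))

  # worked example: 200 vs 20 counts at equal spikes; sigma at the null mean
  # (110.5 counts) on the chl+ scale
  z <- enrichment_zscores(matrix(rep(200, 3)), matrix(rep(20, 3)),
                          rep(1000, 3), rep(1000, 3), nm)
  expect_equal(unname(z), 180 / sqrt((0.2 * 110.5)^2 + 4.5^2),
               tolerance = 1e-10)

  # absent from both arms: exactly zero even with unequal spike counts
  zz <- enrichment_zscores(matrix(rep(0, 3)), matrix(rep(0, 3)),
                           c(900, 1100, 1000), c(1200, 800, 1000), nm)
  expect_identical(unname(zz), 0)

  # swapping arms negates the z-score (equal depths)
  cm2 <- matrix(c(100, 120, 110), 3, 1)
  cp2 <- matrix(c(50, 55, 60), 3, 1)
  za <- enrichment_zscores(cm2, cp2, rep(1000, 3), rep(1000, 3), nm)
  zb <- enrichment_zscores(cp2, cm2, rep(1000, 3), rep(1000, 3), nm)
  expect_equal(unname(za), -unname(zb), tolerance = 1e-10)

  expect_error(enrichment_zscores(cm, cm[1:2, ], rep(1, 3), rep(1, 2), nm),
               "unmatched")
})

test_that("regime calls take unions and remove no-nitrate responders", {
  z1 <- c(a = 10, b = 1, c = 0)
  z2 <- c(a = 0, b = 8, c = 0)
  z3 <- c(a = 0, b = 0, c = 12)
  call <- call_enriched(
    list(c1 = z1, c2 = z2, c3 = z3),
    n_asv_by_condition = c(c1 = 100, c2 = 100, c3 = 100),
    regime_by_condition = c(c1 = "II", c2 = "II", c3 = "III"),
    nn_z = c(a = 9, b = 0, c = 0), nn_n_asv = 100)
  # ASV enriched in only one Regime-II condition is still in the union;
  # the NN responder is removed
  expect_setequal(call$by_regime[["II"]], "b")
  expect_setequal(call$by_regime[["III"]], "c")
  expect_equal(call$nn_responders, "a")

  empty <- call_enriched(list(c1 = c(a = 0.5)),
                         n_asv_by_condition = c(c1 = 100),
                         regime_by_condition = c(c1 = "I"))
  expect_length(empty$by_regime[["I"]], 0)
})

test_that("planted growers are recovered exactly from a synthetic panel", {
  sct <- synth_count_table(small_synth_config(grower_fold = 100), seed = 3)
  enr <- enrichment_analysis(sct$table, sct$truth$regime_by_condition)
  expect_setequal(enr$call$by_regime[["III"]], sct$truth$growers_III)
  expect_true(all(sct$truth$growers_II %in% enr$call$by_regime[["II"]]))
  expect_length(intersect(enr$call$by_regime[["III"]],
                          sct$truth$nn_responders), 0)
})
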