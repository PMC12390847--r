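# Build a presence_matrix directly (the class is a plain list), planting an
# optional single-taxon pH signal.
make_pm <- function(n_soils = 8, reps = 4, n_taxa = 12, signal = TRUE,
                    seed = 1) {
  set.seed(seed)
  ph <- seq(4.5, 8.5, length.out = n_soils)
  soil <- rep(sprintf("s%02d", seq_len(n_soils)), each = reps)
  native <- rep(ph, each = reps)
  X <- matrix(rbinom(length(soil) * n_taxa, 1, 0.4), length(soil), n_taxa,
              dimnames = list(NULL, paste0("t", seq_len(n_taxa))))
  if (signal) X[, 1] <- as.integer(native > 7)
  structure(list(X = X, soil_id = soil, native_pH = native,
                 level = "family", rel_thresh = 0),
            class = "presence_matrix")
}

test_that("presence matrix thresholds and aggregation behave as defined", {
  sct <- synth_count_table(small_synth_config(), seed = 5)
  tab <- sct$table
  m <- tab$meta
  samples <- m$sample_id[m$timepoint == "end" & m$treatment == "chl-" &
                           m$nitrate == "plus"][1:10]
  enriched <- sct$truth$growers_III
  pm0 <- build_presence_matrix(tab, enriched, samples, level = "asv",
                               rel_thresh = 0)
  # threshold 0 equals abundance > 0
  community <- setdiff(colnames(tab$counts), tab$spike_ids)
  cnt <- tab$counts[samples, intersect(enriched, community), drop = FALSE]
  expect_equal(unname(pm0$X), unname((cnt > 0) * 1))

  # a taxon between the two thresholds is present at 0.001, absent at 0.005
  rel <- cnt / rowSums(tab$counts[samples, community])
  mid <- which(rel > 0.001 & rel < 0.005, arr.ind = TRUE)
  if (nrow(mid) > 0) {
    pm1 <- build_presence_matrix(tab, enriched, samples, "asv", 0.001)
    pm5 <- build_presence_matrix(tab, enriched, samples, "asv", 0.005)
    expect_equal(pm1$X[mid[1, 1], mid[1, 2]], 1)
    expect_equal(pm5$X[mid[1, 1], mid[1, 2]], 0)
  }

  # family aggregation ORs member presences
  pmf <- build_presence_matrix(tab, enriched, samples, level = "family",
                               rel_thresh = 0)
  fam <- tab$taxonomy$family[match(intersect(enriched, community),
                                   tab$taxonomy$asv)]
  f1 <- unique(fam)[1]
  expect_equal(unname(pmf$X[, f1]),
               unname((rowSums(pm0$X[, fam == f1, drop = FALSE]) > 0) * 1))

  expect_error(build_presence_matrix(tab, character(0), samples), "empty")
})

test_that("LASSO recovers a planted single-taxon pH signal", {
  pm <- make_pm(signal = TRUE, seed = 2)
  fit <- fit_lasso_cv(pm, seed = 3)
  expect_gt(fit$coefficients[["t1"]], 0)
  r2 <- r2_by_soil(fit$predictions, pm$native_pH, pm$soil_id)
  expect_gt(r2, 0.5)
})

test_that("pure-noise presences shrink almost all coefficients to zero", {
  pm <- make_pm(signal = FALSE, seed = 4)
  fit <- fit_lasso_cv(pm, seed = 5)
  nz <- sum(fit$coefficients[-1] != 0)
  expect_lte(nz, 3)
  expect_error(
    fit_lasso_cv(structure(list(X = pm$X, soil_id = pm$soil_id,
                                native_pH = rep(7, length(pm$native_pH)),
                                level = "family", rel_thresh = 0),
                           class = "presence_matrix")),
    "constant")
})

test_that("leave-one-soil-out predicts held-out soils from a clean signal", {
  pm <- make_pm(n_soils = 6, signal = TRUE, seed = 6)
  lo <- loso_predict(pm, seed = 7)
  expect_false(anyNA(lo$predicted))
  # the planted step signal survives held-out prediction
  r2 <- r2_by_soil(lo$predicted, lo$native_pH, lo$soil_id)
  expect_gt(r2, 0.3)
  # in-sample predictions are at least as good in aggregate
  fit <- fit_lasso_cv(pm, seed = 7)
  r2_in <- r2_by_soil(fit$predictions, pm$native_pH, pm$soil_id)
  expect_gte(r2_in, r2 - 0.05)

  two <- make_pm(n_soils = 2, signal = TRUE)
  expect_error(loso_predict(two), "3 soils")
})

test_that("soil-level R squared follows its definition", {
  obs <- c(5, 5, 7, 7, 9, 9)
  soil <- rep(c("a", "b", "c"), each = 2)
  expect_equal(r2_by_soil(obs, obs, soil), 1)
  expect_equal(r2_by_soil(rep(7, 6), obs, soil), 0)
  expect_lt(r2_by_soil(rev(obs), obs, soil), 0)
  expect_error(r2_by_soil(obs, rep(5, 6), soil), "variance")
})

test_that("soil-level permutation p-value is smoothed and calibrated", {
  pm <- make_pm(signal = TRUE, seed = 8)
  expect_warning(pp <- permutation_pvalue(pm, n_perm = 59, seed = 9),
                 "100 permutations")
  expect_gt(pp$p_value, 0)   # +1 smoothing forbids p = 0
  expect_lte(pp$p_value, 0.1)  # the planted signal is clearly atypical

  # null signal: observed R2 is unremarkable among permutations
  pm0 <- make_pm(signal = FALSE, seed = 10)
  suppressWarnings(pp0 <- permutation_pvalue(pm0, n_perm = 59, seed = 11))
  expect_gt(pp0$p_value, 0.05)
})

test_that("a pure-noise column does not lift held-out accuracy", {
  deltas <- vapply(1:3, function(i) {
    pm <- make_pm(n_soils = 6, signal = TRUE, seed = 20 + i)
    base <- r2_by_soil(loso_predict(pm, seed = 1)$predicted,
                       pm$native_pH, pm$soil_id)
    set.seed(30 + i)
    pm$X <- cbind(pm$X, noise = rbinom(nrow(pm$X), 1, 0.5))
    plus <- r2_by_soil(loso_predict(pm, seed = 1)$predicted,
                       pm$native_pH, pm$soil_id)
    plus - base
  }, numeric(1))
  expect_lt(mean(deltas), 0.05)
})
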