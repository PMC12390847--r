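#' Configuration for the synthetic microcosm generator
#'
#' Defaults mirror the study design the analysis assumes: soils spread over
#' a native pH gradient, 13 perturbed pH levels between 3 and 9,
#' triplicates, ten sampling times over 91 hours, 2 mM nitrate input, 2%
#' multiplicative nitrate measurement noise, spike-ins near 8.9% of reads,
#' and count noise with c_frac = 0.21, c0 = 4.5.
#'
#' @param n_soils number of soils.
#' @param native_pH_range range of native pH values (soils are evenly
#'   spaced over it).
#' @param ph_grid perturbed pH levels.
#' @param n_replicates biological replicates per condition.
#' @param times sampling grid, days.
#' @param noise_sd fractional nitrate measurement noise.
#' @param gamma growth rate used for truth parameters, 1/day.
#' @param n_asv,n_phyla community richness for count tables.
#' @param depth expected community reads per sample.
#' @param depth_sd lognormal sd of the per-run (condition-level) depth
#'   factor; conditions are processed in separate runs, so depth varies a
#'   lot across them (this drives the wide spike-fraction dispersion and
#'   the high correlation between the two spike ASVs).
#' @param rep_depth_sd lognormal sd of the within-run (replicate-level)
#'   depth factor; replicate triplets share a run, so this is small and is
#'   absorbed by the empirical replicate noise model.
#' @param spike_frac target spike-in fraction of total reads.
#' @param spike_cv independent fractional noise of spike-in counts beyond
#'   Poisson counting (default 0.05): spike DNA is added in known equal
#'   quantities, so its per-sample noise is pipetting and counting, not the
#'   biological replicate variability of community ASVs.
#' @param c_frac,c0 count noise truth.
#' @param grower_fold abundance fold applied to planted growers (default
#'   100: dominant-group growth folds over a four-day incubation reach
#'   one to two orders of magnitude).
#' @param n_growers planted growers per regime (II and III each).
#' @param n_nn planted no-nitrate responders.
#' @param death_factor survival multiplier applied to acid-sensitive phyla
#'   per pH unit below 4.
#' @return a list of class \code{synth_config}.
#' @export
synth_config <- function(n_soils = 10,
                         native_pH_range = c(4.7, 8.3),
                         ph_grid = seq(3, 9, length.out = 13),
                         n_replicates = 3,
                         times = default_time_grid(),
                         noise_sd = 0.02,
                         gamma = 4.8,
                         n_asv = 400, n_phyla = 40,
                         depth = 3e4, depth_sd = 0.7, rep_depth_sd = 0.15,
                         spike_frac = 0.089, spike_cv = 0.05,
                         c_frac = 0.21, c0 = 4.5,
                         grower_fold = 100,
                         n_growers = 10, n_nn = 2,
                         death_factor = 0.3) {
  structure(as.list(environment()), class = "synth_config")
}

# Regime boundaries in perturbed-pH space; both shift upward with native pH
# so more acidic soils enter the acidic-death regime after smaller acidic
# perturbations.
.regime_boundaries <- function(native_pH) {
  list(acid = 3.8 + 0.10 * (native_pH - 6.5),
       base = 7.8 + 0.15 * (native_pH - 6.5))
}

.regime_for <- function(native_pH, perturbed_pH) {
  b <- .regime_boundaries(native_pH)
  ifelse(perturbed_pH <= b$acid, "I",
         ifelse(perturbed_pH >= b$base, "III", "II"))
}

# Truth parameters for one condition: regime anchor values jittered +/-50%,
# redrawn (up to a clamp) into the planted regime's quadrant with a 20%
# margin from the classification thresholds so the planted label is
# recoverable exactly in the noiseless limit.
.draw_truth <- function(regime, frac_in_II, gamma, thresholds) {
  x_thr <- thresholds$x_thr; c_thr <- thresholds$c_thr
  anchor <- switch(regime,
                   I = c(x = 0.01, c = 0.005),
                   II = c(x = 0.1 * (0.7 + 0.6 * frac_in_II), c = 0.05),
                   III = c(x = 0.001, c = 2))
  ok <- function(x0, gc0) {
    switch(regime,
           I = x0 <= 0.8 * x_thr && gc0 <= 0.8 * c_thr,
           II = x0 >= 1.2 * x_thr && gc0 <= 0.8 * c_thr,
           III = x0 <= 0.8 * x_thr && gc0 >= 1.2 * c_thr)
  }
  for (try in 1:50) {
    x0 <- anchor[["x"]] * stats::runif(1, 0.5, 1.5)
    c0 <- anchor[["c"]] * stats::runif(1, 0.5, 1.5)
    if (ok(x0, gamma * c0)) {
      return(list(x0_tilde = unname(x0), C0_tilde = unname(c0)))
    }
  }
  list(x0_tilde = anchor[["x"]], C0_tilde = anchor[["c"]])
}

#' Generate one synthetic nitrate time-series pair
#'
#' Simulates both treatment arms from the model, applies multiplicative
#' Gaussian measurement noise, and floors readings at zero.
#'
#' @param truth a \code{crm_params} object.
#' @param times sampling grid, days.
#' @param noise_sd fractional measurement noise (0 for noiseless data).
#' @param seed optional integer seed.
#' @param soil_id,perturbed_pH,replicate labels carried into the pair.
#' @return a list with the \code{pair} (a \code{nitrate_pair}) and the
#'   \code{truth} parameters.
#' @export
synth_nitrate_pair <- function(truth, times = default_time_grid(),
                               noise_sd = 0.02, seed = NULL,
                               soil_id = NA, perturbed_pH = NA,
                               replicate = 1L) {
  stopifnot(inherits(truth, "crm_params"))
  a_minus <- simulate_crm(truth, times, growth_on = TRUE)$A
  a_plus <- simulate_crm(truth, times, growth_on = FALSE)$A
  with_seed(seed, {
    if (noise_sd > 0) {
      a_minus <- pmax(a_minus * (1 + stats::rnorm(length(times), 0, noise_sd)), 0)
      a_plus <- pmax(a_plus * (1 + stats::rnorm(length(times), 0, noise_sd)), 0)
    }
    list(pair = nitrate_pair(times, a_minus, times, a_plus,
                             soil_id = soil_id, perturbed_pH = perturbed_pH,
                             replicate = replicate),
         truth = truth)
  })
}

#' Generate a soil x pH panel of nitrate pairs with planted regimes
#'
#' Each (soil, perturbed pH) condition is assigned a regime from the
#' native-pH-dependent boundaries, truth parameters are drawn around the
#' regime anchor values (within Regime II the biomass activity rises with
#' perturbed pH), and replicate pairs are simulated with measurement noise.
#'
#' @param config a \code{synth_config}.
#' @param seed integer seed (required for reproducibility).
#' @param thresholds \code{regime_thresholds} the planted parameters respect.
#' @return a list with \code{pairs} (list of \code{nitrate_pair}) and
#'   \code{truth} (data frame: soil_id, native_pH, perturbed_pH, regime,
#'   x0_tilde, C0_tilde, gammaC0_tilde).
#' @export
synth_soil_gradient <- function(config = synth_config(), seed = 1,
                                thresholds = regime_thresholds()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    natives <- seq(config$native_pH_range[1], config$native_pH_range[2],
                   length.out = config$n_soils)
    pairs <- list()
    rows <- list()
    k <- 0L
    for (s in seq_len(config$n_soils)) {
      soil <- sprintf("soil%02d", s)
      b <- .regime_boundaries(natives[s])
      for (ph in config$ph_grid) {
        regime <- .regime_for(natives[s], ph)
        frac <- min(max((ph - b$acid) / (b$base - b$acid), 0), 1)
        tr <- .draw_truth(regime, frac, config$gamma, thresholds)
        params <- crm_params(x0_tilde = tr$x0_tilde, C0_tilde = tr$C0_tilde,
                             A0 = 2, A0c = 2, gamma = config$gamma)
        for (r in seq_len(config$n_replicates)) {
          k <- k + 1L
          pairs[[k]] <- synth_nitrate_pair(
            params, times = config$times, noise_sd = config$noise_sd,
            soil_id = soil, perturbed_pH = ph, replicate = r)$pair
        }
        rows[[length(rows) + 1L]] <- data.frame(
          soil_id = soil, native_pH = natives[s], perturbed_pH = ph,
          regime = regime, x0_tilde = tr$x0_tilde, C0_tilde = tr$C0_tilde,
          gammaC0_tilde = config$gamma * tr$C0_tilde)
      }
    }
    list(pairs = pairs, truth = do.call(rbind, rows))
  })
}

#' Generate a synthetic ASV count table with spike-ins and planted signals
#'
#' Emulates the sequencing design: T0 samples, endpoint chl-/chl+ samples
#' for every (soil, perturbed pH) condition, and a no-nitrate chl-/chl+
#' contrast at the unperturbed pH of each soil. Base ASV abundances are
#' log-normal; planted growers are boosted in the chl- endpoint of their
#' regime's conditions (Bacillota in the resurgent-growth regime,
#' Pseudomonadota/Bacteroidota in the nutrient-limiting regime); planted
#' no-nitrate responders are boosted in every chl- arm including the
#' no-nitrate contrast; acid-sensitive phyla are depleted below pH 4 in
#' endpoint samples (survival-fold signal). Counts are drawn from the
#' truncated-Gaussian replicate noise model around expected counts; two
#' spike-in ASVs at the target read fraction share each sample's depth
#' factor. Regime-III growers occupy native-pH niches, so their presence
#' carries a recoverable native-pH signal.
#'
#' @param config a \code{synth_config}.
#' @param seed integer seed.
#' @return a list with \code{table} (a \code{count_table}) and \code{truth}
#'   (planted grower/NN sets, regime map, noise parameters, niche centers).
#' @export
synth_count_table <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    natives <- seq(config$native_pH_range[1], config$native_pH_range[2],
                   length.out = config$n_soils)
    soils <- sprintf("soil%02d", seq_len(config$n_soils))

    phyla <- c("Pseudomonadota", "Bacteroidota", "Bacillota",
               "Actinomycetota", "Acidobacteriota", "Verrucomicrobiota",
               "Planctomycetota", "Chloroflexota", "Gemmatimonadota",
               "Myxococcota")
    if (config$n_phyla > length(phyla)) {
      phyla <- c(phyla, sprintf("Phylum%02d",
                                seq_len(config$n_phyla - length(phyla))))
    }
    phyla <- phyla[seq_len(config$n_phyla)]
    # dominant phyla get most ASVs; a long tail of rare phyla keeps the
    # phylum roster full
    w <- c(rep(8, min(3, length(phyla))),
           rep(2, max(min(7, length(phyla) - 3), 0)))
    w <- c(w, rep(0.7, max(length(phyla) - length(w), 0)))
    asv_phylum <- sample(phyla, config$n_asv, replace = TRUE,
                         prob = w / sum(w))
    # guarantee signal phyla have enough members to plant growers in
    for (ph in c("Pseudomonadota", "Bacteroidota", "Bacillota")) {
      need <- config$n_growers + 2 - sum(asv_phylum == ph)
      if (need > 0) {
        asv_phylum[sample(which(!asv_phylum %in%
                                  c("Pseudomonadota", "Bacteroidota",
                                    "Bacillota")), need)] <- ph
      }
    }
    # every phylum represented at least once
    for (ph in setdiff(phyla, unique(asv_phylum))) {
      asv_phylum[sample(which(asv_phylum %in% names(sort(table(asv_phylum),
                                                         decreasing = TRUE))[1]),
                        1)] <- ph
    }
    asv_ids <- sprintf("ASV%04d", seq_len(config$n_asv))
    taxonomy <- data.frame(
      asv = asv_ids, phylum = asv_phylum,
      family = paste0(asv_phylum, "_fam",
                      1 + (seq_len(config$n_asv) %% 3)),
      genus = paste0(asv_phylum, "_gen", seq_len(config$n_asv)))

    bacillota <- which(asv_phylum == "Bacillota")
    proteo <- which(asv_phylum %in% c("Pseudomonadota", "Bacteroidota"))
    growers_III <- sample(bacillota, min(config$n_growers, length(bacillota)))
    growers_II <- sample(proteo, min(config$n_growers, length(proteo)))
    # no-nitrate responders live in the abundant copiotrophic phyla (their
    # growth is a response to the incubation itself, typical of dominant
    # opportunists), not in rare phyla
    nn_pool <- setdiff(proteo, growers_II)
    nn_idx <- sample(nn_pool, min(config$n_nn, length(nn_pool)))

    # base relative abundances; growers get moderate base abundance so both
    # arms keep them detectable
    base <- stats::rlnorm(config$n_asv, 0, 1.5)
    base[c(growers_III, growers_II)] <-
      stats::rlnorm(length(c(growers_III, growers_II)), 1, 0.3)
    base <- base / sum(base)

    # native-pH niches for regime-III growers: each grower occupies soils
    # within +/- 1.2 pH units of its preferred native pH
    niche <- stats::runif(length(growers_III),
                          config$native_pH_range[1],
                          config$native_pH_range[2])
    occupancy <- matrix(1, config$n_soils, config$n_asv)
    for (gi in seq_along(growers_III)) {
      occupancy[abs(natives - niche[gi]) > 1.2, growers_III[gi]] <- 0
    }

    acid_sensitive <- asv_phylum != "Bacillota"

    meta_rows <- list(); count_rows <- list()
    spike_each <- config$depth * config$spike_frac /
      (1 - config$spike_frac) / 2
    nm <- noise_model(config$c_frac, config$c0)

    draw_sample <- function(expected) {
      n <- stats::rnorm(length(expected), expected, noise_sd(expected, nm))
      pmax(round(n), 0)
    }

    add_sample <- function(id, soil_i, ph, treatment, nitrate, timepoint,
                           rep, modifier, run_factor = 1) {
      depth_factor <- run_factor * stats::rlnorm(1, 0, config$rep_depth_sd)
      expected <- config$depth * base * occupancy[soil_i, ] * modifier *
        depth_factor
      es <- rep(spike_each * depth_factor, 2)
      spikes <- pmax(round(stats::rnorm(2, es,
                                        sqrt((config$spike_cv * es)^2 + es))),
                     0)
      counts <- draw_sample(expected)
      meta_rows[[length(meta_rows) + 1L]] <<- data.frame(
        sample_id = id, soil_id = soils[soil_i],
        native_pH = natives[soil_i], perturbed_pH = ph,
        treatment = treatment, nitrate = nitrate, timepoint = timepoint,
        replicate = rep)
      count_rows[[length(count_rows) + 1L]] <<- c(counts, spikes)
    }

    for (s in seq_len(config$n_soils)) {
      t0_run <- stats::rlnorm(1, 0, config$depth_sd)
      for (r in seq_len(config$n_replicates)) {
        add_sample(sprintf("%s_T0_r%d", soils[s], r), s, NA, "none",
                   "minus", "T0", r, rep(1, config$n_asv), t0_run)
      }
      for (ph in config$ph_grid) {
        run <- stats::rlnorm(1, 0, config$depth_sd)
        regime <- .regime_for(natives[s], ph)
        death <- rep(1, config$n_asv)
        if (ph < 4) {
          death[acid_sensitive] <- config$death_factor^(4 - ph)
        }
        grow <- rep(1, config$n_asv)
        if (regime == "III") grow[growers_III] <- config$grower_fold
        if (regime == "II") grow[growers_II] <- config$grower_fold
        grow[nn_idx] <- config$grower_fold  # NN responders grow regardless
        for (r in seq_len(config$n_replicates)) {
          tag <- sprintf("%s_pH%.1f_r%d", soils[s], ph, r)
          add_sample(paste0(tag, "_chlminus"), s, ph, "chl-", "plus",
                     "end", r, death * grow, run)
          add_sample(paste0(tag, "_chlplus"), s, ph, "chl+", "plus",
                     "end", r, death, run)
        }
      }
      # no-nitrate contrast at (approximately) unperturbed pH
      nn_run <- stats::rlnorm(1, 0, config$depth_sd)
      nn_grow <- rep(1, config$n_asv); nn_grow[nn_idx] <- config$grower_fold
      for (r in seq_len(config$n_replicates)) {
        tag <- sprintf("%s_NN_r%d", soils[s], r)
        add_sample(paste0(tag, "_chlminus"), s, natives[s], "chl-",
                   "minus", "end", r, nn_grow, nn_run)
        add_sample(paste0(tag, "_chlplus"), s, natives[s], "chl+",
                   "minus", "end", r, rep(1, config$n_asv), nn_run)
      }
    }

    counts <- do.call(rbind, count_rows)
    meta <- do.call(rbind, meta_rows)
    spike_ids <- c("SPIKE_Escherichia", "SPIKE_Parabacteroides")
    colnames(counts) <- c(asv_ids, spike_ids)
    rownames(counts) <- meta$sample_id

    table <- count_table(counts = counts, taxonomy = taxonomy, meta = meta,
                         spike_ids = spike_ids)
    regime_map <- character(0)
    for (s in seq_len(config$n_soils)) {
      for (ph in config$ph_grid) {
        regime_map[paste(soils[s], ph, sep = "|")] <-
          .regime_for(natives[s], ph)
      }
    }
    list(table = table,
         truth = list(growers_III = asv_ids[growers_III],
                      growers_II = asv_ids[growers_II],
                      nn_responders = asv_ids[nn_idx],
                      regime_by_condition = regime_map,
                      niche = stats::setNames(niche, asv_ids[growers_III]),
                      c_frac = config$c_frac, c0 = config$c0))
  })
}

#' Generate synthetic replicate count profiles from the noise model
#'
#' Draws replicate x ASV counts around log-normal expected abundances with
#' the truncated-Gaussian noise model — the fixture for noise-model
#' recovery and enrichment calibration checks.
#'
#' @param n_asv number of ASVs.
#' @param n_replicates replicates.
#' @param c_frac,c0 noise truth.
#' @param mean_log,sd_log log-normal parameters of expected counts.
#' @param seed integer seed.
#' @return a list with \code{counts} (replicates x ASVs) and
#'   \code{expected}.
#' @export
synth_replicates <- function(n_asv = 2000, n_replicates = 3,
                             c_frac = 0.21, c0 = 4.5,
                             mean_log = log(60), sd_log = 1.5, seed = 1) {
  with_seed(seed, {
    expected <- stats::rlnorm(n_asv, mean_log, sd_log)
    nm <- noise_model(c_frac, c0)
    counts <- t(vapply(seq_len(n_replicates), function(r) {
      pmax(round(stats::rnorm(n_asv, expected, noise_sd(expected, nm))), 0)
    }, numeric(n_asv)))
    colnames(counts) <- sprintf("ASV%04d", seq_len(n_asv))
    list(counts = counts, expected = expected)
  })
}
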