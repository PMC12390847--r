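#' Empirical replicate noise model
#'
#' Repeated measurements of an ASV with mean abundance \code{n} counts are
#' modelled as Gaussian with standard deviation
#' \deqn{\sigma(n) = \sqrt{(c_{frac} n)^2 + c_0^2},}
#' combining a fractional term (library-size and ecological variability)
#' with a constant counting floor. The model is fitted separately per soil
#' and perturbed pH, as those samples are processed in separate runs.
#'
#' @param c_frac fractional noise magnitude (dimensionless, >= 0).
#' @param c0 constant noise magnitude (counts, >= 0).
#' @param soil_id,perturbed_pH scope labels.
#' @return an object of class \code{noise_model}.
#' @export
noise_model <- function(c_frac, c0, soil_id = NA, perturbed_pH = NA) {
  stopifnot(c_frac >= 0, c0 >= 0)
  structure(list(c_frac = c_frac, c0 = c0, soil_id = soil_id,
                 perturbed_pH = perturbed_pH),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("noise_model: c_frac = %.3g, c0 = %.3g counts\n",
              x$c_frac, x$c0))
  invisible(x)
}

#' Replicate noise standard deviation
#'
#' @param n mean counts (vectorized, >= 0).
#' @param model a \code{noise_model}.
#' @return standard deviation in counts.
#' @export
noise_sd <- function(n, model) {
  stopifnot(inherits(model, "noise_model"), all(n >= 0))
  sqrt((model$c_frac * n)^2 + model$c0^2)
}

#' Fit the replicate noise model from replicate count profiles
#'
#' \code{c_frac} is estimated from moderate-abundance ASVs (pair mean above
#' \code{high_thresh} counts), where the constant term is negligible: the
#' median absolute pairwise relative difference is scaled to a Gaussian
#' standard deviation (x 1.4826) and divided by sqrt(2) because a
#' replicate-replicate difference carries the noise of both measurements.
#' \code{c0} is then the smallest value for which the requested fraction of
#' all replicate-pair comparisons deviate from the 1:1 line by less than
#' \eqn{\sigma(c_0, c_{frac})} (deviation measured perpendicular to the 1:1
#' line, i.e. \eqn{|n_1 - n_2|/\sqrt 2}), found by monotone bisection.
#'
#' @param replicate_counts matrix, replicates x ASVs, raw counts.
#' @param high_thresh minimum pair-mean count for the c_frac estimate
#'   (default 50).
#' @param coverage target coverage of the +/- 1 sigma band (default 0.67).
#' @param fallback optional \code{noise_model} returned (with a warning)
#'   when no ASV exceeds \code{high_thresh}.
#' @param soil_id,perturbed_pH scope labels stored in the result.
#' @return a fitted \code{noise_model}.
#' @export
fit_noise_model <- function(replicate_counts, high_thresh = 50,
                            coverage = 0.67, fallback = NULL,
                            soil_id = NA, perturbed_pH = NA) {
  replicate_counts <- as.matrix(replicate_counts)
  if (nrow(replicate_counts) < 2) {
    stop("fit_noise_model: need at least 2 replicates")
  }
  idx <- utils::combn(nrow(replicate_counts), 2)
  rel <- c(); diffs <- c(); means <- c()
  for (k in seq_len(ncol(idx))) {
    a <- replicate_counts[idx[1, k], ]
    b <- replicate_counts[idx[2, k], ]
    m <- (a + b) / 2
    hi <- m > high_thresh
    rel <- c(rel, ((a - b) / m)[hi])
    nz <- m > 0
    diffs <- c(diffs, abs(a - b)[nz] / sqrt(2))
    means <- c(means, m[nz])
  }
  if (length(rel) == 0) {
    if (!is.null(fallback)) {
      warning("fit_noise_model: no ASVs above high_thresh; using fallback")
      return(fallback)
    }
    stop("fit_noise_model: no ASVs above high_thresh for c_frac estimation")
  }
  c_frac <- stats::median(abs(rel)) * 1.4826 / sqrt(2)

  frac_within <- function(c0) {
    mean(diffs <= sqrt((c_frac * means)^2 + c0^2))
  }
  if (frac_within(0) >= coverage) {
    c0 <- 0
  } else {
    lo <- 0; hi <- max(diffs) + 1
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (frac_within(mid) >= coverage) hi <- mid else lo <- mid
    }
    c0 <- hi
  }
  noise_model(c_frac = c_frac, c0 = c0, soil_id = soil_id,
              perturbed_pH = perturbed_pH)
}

#' Bonferroni-corrected critical z-score
#'
#' \eqn{z_{crit} = \Phi^{-1}(1 - \alpha / 2 n_{ASV})}: the two-tailed
#' Bonferroni threshold at level \code{alpha} over the non-zero ASVs of a
#' sample pair.
#'
#' @param alpha significance level (default 0.05).
#' @param n_asv number of non-zero ASVs.
#' @return the critical z value.
#' @export
critical_z <- function(alpha = 0.05, n_asv) {
  stopifnot(alpha > 0, alpha < 1, n_asv >= 1)
  stats::qnorm(1 - alpha / (2 * n_asv))
}

#' Per-ASV enrichment z-scores from replicate pairs
#'
#' For each replicate pair (rep1-rep1, rep2-rep2, ...), spike-normalized
#' abundances are differenced and mapped back to the chl+ arm's count scale
#' (multiplied by the chl+ sample's spike count) so that the count-scale
#' noise model applies:
#' \deqn{z = \frac{(Abs^- - Abs^+)\, s^+}{\sigma(\bar n + pseudo)},}
#' where \eqn{\bar n} is the null-hypothesis mean on the chl+ count scale
#' (the average of the depth-matched chl- count and the chl+ count):
#' under the null the two arms share one mean, and evaluating \eqn{\sigma}
#' at its symmetric estimate avoids the asymmetric z inflation that occurs
#' when the reference count alone fluctuates low. The pseudocount is
#' applied on the common count scale, so it cancels exactly in the
#' difference — an ASV absent from both arms scores z = 0 regardless of the
#' depth ratio. The median z across replicate pairs is assigned to each
#' ASV.
#'
#' @param counts_minus,counts_plus matrices, replicates x ASVs, raw counts
#'   for the chl- and chl+ arm (rows aligned by replicate).
#' @param spike_minus,spike_plus per-replicate spike-in counts.
#' @param model a \code{noise_model} for this (soil, perturbed pH).
#' @param pseudo pseudocount in raw counts (default 0.5).
#' @return a named numeric vector of median z-scores per ASV.
#' @export
enrichment_zscores <- function(counts_minus, counts_plus,
                               spike_minus, spike_plus, model,
                               pseudo = 0.5) {
  counts_minus <- as.matrix(counts_minus)
  counts_plus <- as.matrix(counts_plus)
  if (nrow(counts_minus) != nrow(counts_plus)) {
    stop("enrichment_zscores: unmatched replicate counts between arms")
  }
  stopifnot(length(spike_minus) == nrow(counts_minus),
            length(spike_plus) == nrow(counts_plus),
            all(spike_minus > 0), all(spike_plus > 0))
  zs <- vapply(seq_len(nrow(counts_minus)), function(r) {
    # abundances with the pseudocount applied on the chl+ count scale:
    # ((c- * s+/s- + pseudo) - (c+ + pseudo)) / s+, remapped to counts
    mapped_minus <- counts_minus[r, ] * spike_plus[r] / spike_minus[r]
    diff_counts <- mapped_minus - counts_plus[r, ]
    n_null <- (mapped_minus + counts_plus[r, ]) / 2 + pseudo
    diff_counts / noise_sd(n_null, model)
  }, numeric(ncol(counts_minus)))
  z <- apply(matrix(zs, ncol = nrow(counts_minus)), 1, stats::median)
  names(z) <- colnames(counts_minus)
  z
}

#' Call enriched ASVs per functional regime
#'
#' Per condition, enriched ASVs are those with median z above the
#' Bonferroni critical value for that condition's non-zero ASV count. Per
#' regime, the call is the union over that regime's conditions, minus the
#' no-nitrate responders (ASVs enriched in the no-nitrate chl-/chl+
#' contrast at its own critical value) — false positives that respond to
#' the incubation itself rather than to nitrate.
#'
#' @param z_by_condition named list of per-ASV median z vectors.
#' @param n_asv_by_condition named numeric, non-zero ASV count per condition.
#' @param regime_by_condition named character, regime label per condition.
#' @param nn_z optional per-ASV median z of the no-nitrate contrast.
#' @param nn_n_asv non-zero ASV count of the no-nitrate contrast.
#' @param alpha significance level (default 0.05).
#' @return an object of class \code{enrichment_call}: per-condition sets,
#'   the NN-responder set, the per-regime union sets, and the critical
#'   values used.
#' @export
call_enriched <- function(z_by_condition, n_asv_by_condition,
                          regime_by_condition, nn_z = NULL,
                          nn_n_asv = NULL, alpha = 0.05) {
  conds <- names(z_by_condition)
  stopifnot(!is.null(conds),
            all(conds %in% names(n_asv_by_condition)),
            all(conds %in% names(regime_by_condition)))
  z_crit <- vapply(conds, function(cc) {
    critical_z(alpha, max(n_asv_by_condition[[cc]], 1))
  }, numeric(1))
  per_condition <- lapply(conds, function(cc) {
    z <- z_by_condition[[cc]]
    names(z)[!is.na(z) & z > z_crit[[cc]]]
  })
  names(per_condition) <- conds

  nn_responders <- character(0)
  if (!is.null(nn_z)) {
    if (is.null(nn_n_asv)) nn_n_asv <- sum(!is.na(nn_z))
    nn_crit <- critical_z(alpha, max(nn_n_asv, 1))
    nn_responders <- names(nn_z)[!is.na(nn_z) & nn_z > nn_crit]
  }

  regimes <- unique(unname(regime_by_condition[conds]))
  by_regime <- lapply(regimes, function(r) {
    u <- unique(unlist(per_condition[conds[regime_by_condition[conds] == r]]))
    setdiff(u, nn_responders)
  })
  names(by_regime) <- regimes

  structure(list(per_condition = per_condition,
                 nn_responders = nn_responders,
                 by_regime = by_regime, z_crit = z_crit, alpha = alpha),
            class = "enrichment_call")
}

#' @export
print.enrichment_call <- function(x, ...) {
  cat("enrichment_call:\n")
  for (r in names(x$by_regime)) {
    cat(sprintf("  Regime %s: %d enriched ASVs\n", r,
                length(x$by_regime[[r]])))
  }
  cat(sprintf("  NN responders removed: %d\n", length(x$nn_responders)))
  invisible(x)
}

#' Differential enrichment analysis of a count table
#'
#' Drives the full enrichment workflow on a \code{count_table}: fits the
#' replicate noise model per (soil, perturbed pH) from the chl+ endpoint
#' replicates, computes per-ASV median z-scores for each nitrate-amended
#' condition, the no-nitrate contrast at unperturbed pH per soil, and calls
#' enriched ASVs per regime.
#'
#' @param table a \code{count_table}.
#' @param regime_by_condition named character vector of regime labels,
#'   names formatted \code{"soil|pH"}.
#' @param alpha significance level (default 0.05).
#' @param pseudo count pseudocount (default 0.5).
#' @param high_thresh,coverage passed to \code{\link{fit_noise_model}}.
#' @param fallback_model optional \code{noise_model} used when a condition
#'   has too few moderate-abundance ASVs.
#' @return a list with \code{call} (an \code{enrichment_call}),
#'   \code{z_by_condition} and the per-condition \code{noise_models}.
#' @export
enrichment_analysis <- function(table, regime_by_condition, alpha = 0.05,
                                pseudo = 0.5, high_thresh = 50,
                                coverage = 0.67, fallback_model = NULL) {
  stopifnot(inherits(table, "count_table"))
  m <- table$meta
  community <- setdiff(colnames(table$counts), table$spike_ids)
  cnt <- table$counts[, community, drop = FALSE]
  spk <- rowSums(table$counts[, table$spike_ids, drop = FALSE])

  arm_rows <- function(sel, treatment) {
    i <- which(sel & m$treatment == treatment)
    i[order(m$replicate[i])]
  }

  # noise is fitted on the same quantity the z-scores compare: spike-
  # normalized counts mapped back to a common count scale, so spike-in
  # measurement noise is part of the empirical null
  depth_matched <- function(rows) {
    sweep(cnt[rows, , drop = FALSE], 1, mean(spk[rows]) / spk[rows], `*`)
  }

  end_nitrate <- m$timepoint == "end" & m$nitrate == "plus"
  conds <- intersect(unique(.cond_key(m[end_nitrate, , drop = FALSE])),
                     names(regime_by_condition))
  z_by_condition <- list(); n_asv <- c(); models <- list()
  for (cond in conds) {
    sel <- end_nitrate & .cond_key(m) == cond
    im <- arm_rows(sel, "chl-"); ip <- arm_rows(sel, "chl+")
    reps <- intersect(m$replicate[im], m$replicate[ip])
    if (length(reps) < 2) next
    im <- im[m$replicate[im] %in% reps]; ip <- ip[m$replicate[ip] %in% reps]
    nm <- tryCatch(
      fit_noise_model(depth_matched(ip), high_thresh = high_thresh,
                      coverage = coverage, fallback = fallback_model,
                      soil_id = m$soil_id[ip[1]],
                      perturbed_pH = m$perturbed_pH[ip[1]]),
      error = function(e) fallback_model)
    if (is.null(nm)) next
    z_by_condition[[cond]] <- enrichment_zscores(
      cnt[im, , drop = FALSE], cnt[ip, , drop = FALSE],
      spk[im], spk[ip], nm, pseudo = pseudo)
    n_asv[cond] <- sum(colSums(cnt[c(im, ip), , drop = FALSE]) > 0)
    models[[cond]] <- nm
  }

  # no-nitrate contrast at unperturbed pH: chl- vs chl+ without nitrate
  nn_sel <- m$timepoint == "end" & m$nitrate == "minus"
  nn_z <- NULL; nn_n <- NULL
  if (any(nn_sel)) {
    im <- arm_rows(nn_sel, "chl-"); ip <- arm_rows(nn_sel, "chl+")
    reps <- intersect(m$replicate[im], m$replicate[ip])
    if (length(reps) >= 2) {
      im <- im[m$replicate[im] %in% reps]
      ip <- ip[m$replicate[ip] %in% reps]
      nm <- tryCatch(
        fit_noise_model(depth_matched(ip), high_thresh = high_thresh,
                        coverage = coverage, fallback = fallback_model),
        error = function(e) fallback_model)
      if (!is.null(nm)) {
        nn_z <- enrichment_zscores(cnt[im, , drop = FALSE],
                                   cnt[ip, , drop = FALSE],
                                   spk[im], spk[ip], nm, pseudo = pseudo)
        nn_n <- sum(colSums(cnt[c(im, ip), , drop = FALSE]) > 0)
      }
    }
  }

  call <- call_enriched(z_by_condition,
                        n_asv_by_condition = n_asv,
                        regime_by_condition = regime_by_condition,
                        nn_z = nn_z, nn_n_asv = nn_n, alpha = alpha)
  list(call = call, z_by_condition = z_by_condition,
       noise_models = models, nn_z = nn_z)
}
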