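#' Regime classification thresholds
#'
#' Thresholds on the two fitted parameters separating the functional
#' regimes: a biomass-activity threshold \code{x_thr} placed at the valley
#' between the two modes of the (bimodal) \eqn{\tilde x(0)} distribution,
#' and a nutrient threshold \code{c_thr} placed at the tail of the
#' near-zero mode of \eqn{\gamma\tilde C(0)}.
#'
#' @param x_thr biomass-activity threshold, mM/day (default 0.05).
#' @param c_thr nutrient threshold on \eqn{\gamma\tilde C(0)}, mM/day
#'   (default 1.5).
#' @return an object of class \code{regime_thresholds}.
#' @export
regime_thresholds <- function(x_thr = 0.05, c_thr = 1.5) {
  stopifnot(x_thr > 0, c_thr > 0)
  structure(list(x_thr = x_thr, c_thr = c_thr), class = "regime_thresholds")
}

#' Classify fitted parameters into functional regimes
#'
#' Regime I (acidic death): both \eqn{\tilde x(0)} and
#' \eqn{\gamma\tilde C(0)} low. Regime II (nutrient limiting): high
#' \eqn{\tilde x(0)}, low \eqn{\gamma\tilde C(0)}. Regime III (resurgent
#' growth): low \eqn{\tilde x(0)}, high \eqn{\gamma\tilde C(0)}. The
#' remaining quadrant (both high) carries no named regime; it is labelled II
#' with \code{ambiguous_quadrant = TRUE} so the ambiguity is surfaced rather
#' than hidden.
#'
#' @param x0_tilde fitted biomass activity (mM/day); vectorized.
#' @param gammaC0_tilde fitted \eqn{\gamma\tilde C(0)} (mM/day); vectorized.
#' @param thresholds a \code{regime_thresholds} object.
#' @return for scalar input, a list with \code{label} and
#'   \code{ambiguous_quadrant}; for vector input, a data frame with those
#'   columns.
#' @export
classify_regime <- function(x0_tilde, gammaC0_tilde,
                            thresholds = regime_thresholds()) {
  stopifnot(inherits(thresholds, "regime_thresholds"),
            length(x0_tilde) == length(gammaC0_tilde))
  if (any(!is.finite(x0_tilde)) || any(!is.finite(gammaC0_tilde)) ||
      any(x0_tilde < 0) || any(gammaC0_tilde < 0)) {
    stop("classify_regime: inputs must be finite and non-negative")
  }
  x_hi <- x0_tilde >= thresholds$x_thr
  c_hi <- gammaC0_tilde >= thresholds$c_thr
  label <- ifelse(!x_hi & !c_hi, "I",
                  ifelse(!x_hi & c_hi, "III", "II"))
  ambiguous <- x_hi & c_hi
  if (length(x0_tilde) == 1) {
    list(label = label, ambiguous_quadrant = ambiguous)
  } else {
    data.frame(label = label, ambiguous_quadrant = ambiguous)
  }
}

#' Derive a regime threshold from a parameter distribution
#'
#' Two modes are supported. \code{"bimodal_valley"} locates the minimum of a
#' kernel-density estimate of \code{log10(value + 0.01)} between the two
#' largest density modes and returns it on the original scale — the rule used
#' for the biomass-activity threshold. \code{"tail"} returns the stated
#' quantile of the values belonging to the dominant near-zero mode, i.e. the
#' upper edge of the null mode — the rule used for the nutrient threshold.
#'
#' @param values parameter samples (>= 30).
#' @param mode \code{"bimodal_valley"} or \code{"tail"}.
#' @param tail_prob quantile used in \code{"tail"} mode (default 0.9).
#' @param offset visualization offset inside the log transform (default 0.01).
#' @return the threshold on the original parameter scale.
#' @export
threshold_from_distribution <- function(values,
                                        mode = c("bimodal_valley", "tail"),
                                        tail_prob = 0.9, offset = 0.01) {
  mode <- match.arg(mode)
  values <- values[is.finite(values)]
  if (length(values) < 30) {
    stop("threshold_from_distribution: need at least 30 samples")
  }
  z <- log10(values + offset)
  if (stats::sd(z) < 1e-10) {
    stop("threshold_from_distribution: no valley in a constant distribution")
  }
  d <- stats::density(z, n = 512)
  y <- d$y
  # interior local maxima of the KDE
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  if (mode == "bimodal_valley") {
    # candidate modes must not be incidental KDE ripples
    is_max <- is_max[y[is_max] >= 0.05 * max(y)]
    if (length(is_max) < 2) {
      stop("threshold_from_distribution: distribution is not bimodal (no valley)")
    }
    top2 <- is_max[order(y[is_max], decreasing = TRUE)[1:2]]
    lo <- min(top2); hi <- max(top2)
    valley <- lo + which.min(y[lo:hi]) - 1
    # a genuine valley dips well below the smaller of the two modes
    if (y[valley] > 0.8 * min(y[top2])) {
      stop("threshold_from_distribution: modes are not separated (no valley)")
    }
    return(10^d$x[valley] - offset)
  }
  # tail mode: values in the dominant (near-zero) mode, bounded above by the
  # first valley after it when one exists
  main <- if (length(is_max) >= 1) is_max[which.max(y[is_max])] else which.max(y)
  upper <- Inf
  if (length(is_max) >= 2) {
    later <- is_max[is_max > main]
    if (length(later) > 0) {
      nxt <- later[1]
      valley <- main + which.min(y[main:nxt]) - 1
      upper <- 10^d$x[valley] - offset
    }
  }
  null_mode <- values[values <= upper]
  as.numeric(stats::quantile(null_mode, tail_prob))
}
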