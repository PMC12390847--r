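#' Presence/absence matrix of resurgent-growth taxa
#'
#' Builds the binary design matrix for native-pH prediction: rows are
#' samples assigned to the resurgent-growth regime, columns are the
#' identified grower taxa at the requested level, entries indicate whether
#' the taxon's relative read abundance exceeds a threshold. Aggregating
#' ASVs to a higher level ORs their presence.
#'
#' @param table a \code{count_table}.
#' @param enriched character vector of enriched (grower) ASV IDs.
#' @param samples sample IDs forming the rows (the Regime-III samples).
#' @param level \code{"asv"}, \code{"genus"}, \code{"family"} or
#'   \code{"phylum"}.
#' @param rel_thresh relative-abundance presence threshold (0, 0.001 or
#'   0.005).
#' @return an object of class \code{presence_matrix}: binary matrix
#'   \code{X}, \code{soil_id} and \code{native_pH} per row.
#' @export
build_presence_matrix <- function(table, enriched, samples,
                                  level = c("asv", "genus", "family",
                                            "phylum"),
                                  rel_thresh = 0) {
  stopifnot(inherits(table, "count_table"))
  level <- match.arg(level)
  if (length(enriched) == 0) {
    stop("build_presence_matrix: empty enriched taxon set")
  }
  rows <- match(samples, rownames(table$counts))
  if (any(is.na(rows))) {
    stop("build_presence_matrix: unknown samples: ",
         paste(samples[is.na(rows)], collapse = ", "))
  }
  community <- setdiff(colnames(table$counts), table$spike_ids)
  cnt <- table$counts[rows, community, drop = FALSE]
  rel <- cnt / pmax(rowSums(cnt), 1)
  enriched <- intersect(enriched, community)
  pres_asv <- rel[, enriched, drop = FALSE] > rel_thresh

  if (level == "asv") {
    X <- pres_asv
  } else {
    labels <- table$taxonomy[[level]][match(enriched, table$taxonomy$asv)]
    labels[is.na(labels)] <- "unassigned"
    groups <- unique(labels)
    X <- vapply(groups, function(g) {
      rowSums(pres_asv[, labels == g, drop = FALSE]) > 0
    }, logical(nrow(pres_asv)))
    X <- matrix(X, nrow = nrow(pres_asv),
                dimnames = list(rownames(pres_asv), groups))
  }
  meta <- table$meta[rows, , drop = FALSE]
  structure(list(X = X * 1, soil_id = meta$soil_id,
                 native_pH = meta$native_pH, level = level,
                 rel_thresh = rel_thresh),
            class = "presence_matrix")
}

# glmnet needs >= 2 columns; pad with an all-zero dummy when necessary.
.pad_X <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, ".dummy" = 0)
}

#' Cross-validated LASSO of native pH on taxon presence
#'
#' Additive linear model of native pH on binary presences with L1 penalty;
#' the penalty is chosen by k-fold cross-validation (CV-minimum rule) with
#' a seed-pinned fold assignment.
#'
#' @param pm a \code{presence_matrix}.
#' @param folds number of CV folds (default 10, reduced to the sample count
#'   if needed).
#' @param seed integer seed for fold assignment.
#' @return an object of class \code{ph_lasso} with the \code{glmnet} cv
#'   fit, selected \code{lambda}, \code{coefficients} and in-sample
#'   \code{predictions}.
#' @export
fit_lasso_cv <- function(pm, folds = 10, seed = NULL) {
  stopifnot(inherits(pm, "presence_matrix"))
  y <- pm$native_pH
  if (length(unique(y)) < 2) {
    stop("fit_lasso_cv: native pH is constant; degenerate fit")
  }
  X <- pm$X
  informative <- apply(X, 2, function(col) stats::var(col) > 0)
  if (!any(informative)) {
    # no informative presences: the model degenerates to the grand mean
    co <- stats::setNames(c(mean(y), rep(0, ncol(X))),
                          c("(Intercept)", colnames(X)))
    return(structure(list(cv = NULL, lambda = Inf, coefficients = co,
                          predictions = rep(mean(y), nrow(X)), pm = pm),
                     class = "ph_lasso"))
  }
  Xi <- .pad_X(X[, informative, drop = FALSE])
  nfolds <- max(3, min(folds, nrow(Xi)))
  foldid <- with_seed(seed, sample(rep(seq_len(nfolds),
                                       length.out = nrow(Xi))))
  # LOSO refits on few samples per fold trigger a structural note about
  # ungrouped CV; it carries no information here
  cv <- tryCatch(
    withCallingHandlers(
      glmnet::cv.glmnet(Xi, y, alpha = 1, foldid = foldid),
      warning = function(w) {
        if (grepl("grouped=FALSE", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }),
    error = function(e) NULL)
  if (!is.null(cv)) {
    model <- cv
    s <- cv$lambda.min
  } else {
    # tiny degenerate designs can leave a CV fold without any varying
    # predictor; fall back to the un-cross-validated path at its least
    # penalized lambda
    model <- glmnet::glmnet(Xi, y, alpha = 1)
    s <- min(model$lambda)
  }
  co_raw <- as.matrix(stats::coef(model, s = s))[, 1]
  co <- stats::setNames(rep(0, ncol(X) + 1), c("(Intercept)", colnames(X)))
  co[intersect(names(co_raw), names(co))] <-
    co_raw[intersect(names(co_raw), names(co))]
  pred <- as.numeric(stats::predict(model, newx = Xi, s = s))
  structure(list(cv = model, lambda = s, coefficients = co,
                 informative = informative,
                 predictions = pred, pm = pm),
            class = "ph_lasso")
}

#' @export
print.ph_lasso <- function(x, ...) {
  nz <- x$coefficients[-1]
  nz <- nz[nz != 0]
  cat(sprintf("ph_lasso: lambda = %.4g, %d taxa selected\n",
              x$lambda, length(nz)))
  invisible(x)
}

#' @export
predict.ph_lasso <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predictions)
  if (is.null(object$cv)) {
    return(rep(object$coefficients[["(Intercept)"]], nrow(newdata)))
  }
  newX <- .pad_X(newdata[, object$informative, drop = FALSE])
  as.numeric(stats::predict(object$cv, newx = newX, s = object$lambda))
}

#' Leave-one-soil-out predictions
#'
#' For each soil, refits the LASSO on all other soils' samples and predicts
#' the held-out soil's samples, so the model never sees the target native
#' pH level.
#'
#' @param pm a \code{presence_matrix} spanning at least 3 soils.
#' @param folds,seed passed to \code{\link{fit_lasso_cv}}.
#' @return a data frame with \code{sample}, \code{soil_id},
#'   \code{native_pH} and out-of-sample \code{predicted}.
#' @export
loso_predict <- function(pm, folds = 10, seed = NULL) {
  stopifnot(inherits(pm, "presence_matrix"))
  soils <- unique(pm$soil_id)
  if (length(soils) < 3) {
    stop("loso_predict: need at least 3 soils for leave-one-soil-out")
  }
  pred <- rep(NA_real_, nrow(pm$X))
  for (s in soils) {
    hold <- pm$soil_id == s
    train <- structure(list(X = pm$X[!hold, , drop = FALSE],
                            soil_id = pm$soil_id[!hold],
                            native_pH = pm$native_pH[!hold],
                            level = pm$level, rel_thresh = pm$rel_thresh),
                       class = "presence_matrix")
    fit <- fit_lasso_cv(train, folds = folds, seed = seed)
    pred[hold] <- predict(fit, newdata = pm$X[hold, , drop = FALSE])
  }
  data.frame(sample = rownames(pm$X) %||% seq_len(nrow(pm$X)),
             soil_id = pm$soil_id, native_pH = pm$native_pH,
             predicted = pred)
}

#' Prediction R-squared on per-soil means
#'
#' Predicted and observed native pH are averaged per soil before computing
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}; values below zero indicate
#' predictions worse than the grand mean.
#'
#' @param pred per-sample predictions.
#' @param obs per-sample observed native pH.
#' @param soil_id per-sample soil labels.
#' @return the soil-level R-squared.
#' @export
r2_by_soil <- function(pred, obs, soil_id) {
  stopifnot(length(pred) == length(obs), length(obs) == length(soil_id))
  pm <- tapply(pred, soil_id, mean)
  om <- tapply(obs, soil_id, mean)
  if (length(om) < 2 || stats::var(om) == 0) {
    stop("r2_by_soil: observed per-soil means have no variance")
  }
  1 - sum((om - pm)^2) / sum((om - mean(om))^2)
}

#' Soil-level permutation p-value for the pH regression
#'
#' Permutes the soil-to-native-pH assignment (all samples of a soil receive
#' the same permuted pH, preserving the replicate structure), refits the
#' LASSO in-sample each time, and compares the permuted soil-level
#' R-squared values with the observed one:
#' \eqn{p = (1 + \#\{R^2_{perm} \ge R^2_{obs}\}) / (1 + n_{perm})}.
#'
#' @param pm a \code{presence_matrix}.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param folds CV folds per refit.
#' @return a list with \code{p_value}, \code{observed_r2} and the permuted
#'   \code{perm_r2} values.
#' @export
permutation_pvalue <- function(pm, n_perm = 1000, seed = NULL, folds = 10) {
  stopifnot(inherits(pm, "presence_matrix"))
  if (n_perm < 100) {
    warning("permutation_pvalue: fewer than 100 permutations")
  }
  fit <- fit_lasso_cv(pm, folds = folds, seed = seed)
  obs_r2 <- r2_by_soil(fit$predictions, pm$native_pH, pm$soil_id)

  soils <- unique(pm$soil_id)
  soil_ph <- vapply(soils, function(s) pm$native_pH[pm$soil_id == s][1],
                    numeric(1))
  perm_r2 <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      shuffled <- stats::setNames(sample(soil_ph), soils)
      ppm <- pm
      ppm$native_pH <- unname(shuffled[pm$soil_id])
      pf <- tryCatch(fit_lasso_cv(ppm, folds = folds, seed = NULL),
                     error = function(e) NULL)
      if (is.null(pf)) return(NA_real_)
      r2_by_soil(pf$predictions, ppm$native_pH, ppm$soil_id)
    }, numeric(1))
  })
  perm_r2 <- perm_r2[!is.na(perm_r2)]
  list(p_value = (1 + sum(perm_r2 >= obs_r2)) / (1 + length(perm_r2)),
       observed_r2 = obs_r2, perm_r2 = perm_r2)
}
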