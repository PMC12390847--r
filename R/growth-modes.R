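#' Assemble the phylum x condition growth matrix
#'
#' @param folds a growth \code{fold_table} at phylum level (already
#'   non-negative through clipping).
#' @return a non-negative matrix, phyla in rows, conditions in columns, with
#'   the condition table attached as the \code{"conditions"} attribute.
#' @export
build_growth_matrix <- function(folds) {
  stopifnot(inherits(folds, "fold_table"))
  G <- folds$folds
  if (length(G) == 0) stop("build_growth_matrix: empty fold table")
  if (any(G < 0)) {
    stop("build_growth_matrix: negative entries; growth folds must be clipped")
  }
  attr(G, "conditions") <- folds$conditions
  G
}

#' Fraction of matrix variation retained by a factorization
#'
#' \eqn{1 - \|G - WH\|_F^2 / \|G\|_F^2}, clipped to [0, 1].
#'
#' @param G non-negative matrix.
#' @param W,H factor matrices with conforming shapes.
#' @return a fraction in [0, 1].
#' @export
variance_retained <- function(G, W, H) {
  denom <- sum(G^2)
  if (denom == 0) stop("variance_retained: zero matrix")
  min(max(1 - sum((G - W %*% H)^2) / denom, 0), 1)
}

# One NMF run: Lee-Seung multiplicative updates for the Frobenius objective.
.nmf_run <- function(G, rank, W0, H0, max_iter, tol) {
  eps <- 1e-12
  W <- W0; H <- H0
  err_old <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (t(W) %*% G) / (t(W) %*% W %*% H + eps)
    W <- W * (G %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    if (it %% 10 == 0) {
      err <- sum((G - W %*% H)^2)
      if (abs(err_old - err) < tol * max(err, eps)) break
      err_old <- err
    }
  }
  list(W = W, H = H, err = sum((G - W %*% H)^2))
}

#' Rank-k non-negative matrix factorization of the growth matrix
#'
#' Decomposes \eqn{G \approx W H} with non-negative factors using
#' multiplicative updates (Frobenius objective) from multiple random
#' restarts, returning the best restart. With the default rank 2, the rows
#' of \code{H} are two growth modes across conditions and the rows of
#' \code{W} give each phylum's loading on the two modes.
#'
#' @param G non-negative matrix (phyla x conditions).
#' @param rank factorization rank (default 2).
#' @param seed integer seed; the multistart is deterministic given it.
#' @param n_restarts random restarts (default 10).
#' @param max_iter,tol update iterations and relative convergence tolerance.
#' @return an object of class \code{growth_nmf} with \code{W}, \code{H},
#'   \code{variance_retained} and \code{reconstruction_error}.
#' @export
nmf_decompose <- function(G, rank = 2, seed = NULL, n_restarts = 10,
                          max_iter = 2000, tol = 1e-9) {
  G <- as.matrix(G)
  if (any(G < 0)) stop("nmf_decompose: G must be non-negative")
  if (sum(G) == 0) stop("nmf_decompose: all-zero matrix")
  scale0 <- sqrt(mean(G) / rank)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      W0 <- matrix(stats::runif(nrow(G) * rank, 0.1, 1) * scale0,
                   nrow(G), rank)
      H0 <- matrix(stats::runif(rank * ncol(G), 0.1, 1) * scale0,
                   rank, ncol(G))
      run <- .nmf_run(G, rank, W0, H0, max_iter, tol)
      if (is.null(best) || run$err < best$err) best <- run
    }
  })
  # fix the W/H scale ambiguity: unit-norm rows of H, magnitude in W, so
  # phylum weights are comparable across modes; order modes by total weight
  W <- best$W; H <- best$H
  for (k in seq_len(rank)) {
    nk <- sqrt(sum(H[k, ]^2))
    if (nk > 0) {
      H[k, ] <- H[k, ] / nk
      W[, k] <- W[, k] * nk
    }
  }
  ord <- order(colSums(W), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  dimnames(W) <- list(rownames(G), paste0("mode", seq_len(rank)))
  dimnames(H) <- list(paste0("mode", seq_len(rank)), colnames(G))
  structure(list(W = W, H = H,
                 variance_retained = variance_retained(G, W, H),
                 reconstruction_error = best$err,
                 rank = rank, n_restarts = n_restarts),
            class = "growth_nmf")
}

#' @export
print.growth_nmf <- function(x, ...) {
  cat(sprintf("growth_nmf: rank %d, %.2f%% of matrix variation retained\n",
              x$rank, 100 * x$variance_retained))
  invisible(x)
}
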