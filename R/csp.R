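# Common Spatial Patterns: class covariance estimation, whitening, joint
# diagonalization, projection and log-variance features.
#
# Convention: eigenvalues are sorted descending by class A, so the first m
# columns of P maximize class-A variance and the last m maximize class-B
# variance.  Because the whitened class covariances share eigenvectors, the
# paired eigenvalues satisfy lambda_A + lambda_B = 1 for every column.

# per-trial channel-mean-removed sample covariance, trace-normalized.
# var of projected rows and the CSP fit both derive from this matrix, so most
# of the pipeline can run on covariances instead of raw time series.
trial_covariance <- function(E) {
  E <- E - rowMeans(E)
  S <- tcrossprod(E) / (ncol(E) - 1L)
  S / sum(diag(S))
}

#' Average trace-normalized class covariance
#'
#' The per-trial sample covariance (after channel-mean removal) is normalized
#' by its trace and averaged over all trials of one class.  Trace
#' normalization makes trials with different overall power contribute equally.
#'
#' @param trials a [trial_set()] or an `n x channels x samples` array.
#' @param label class whose trials to average (ignored when `trials` carries
#'   no labels and all trials are used).
#' @return a symmetric channels x channels matrix with unit trace.
#' @export
class_covariance <- function(trials, label = NULL) {
  if (inherits(trials, "trial_set")) {
    idx <- if (is.null(label)) seq_len(n_trials(trials)) else which(trials$labels == label)
    if (!length(idx)) stopf("no trials with label '%s'", label)
    arr <- trials$trials
  } else {
    arr <- trials
    idx <- seq_len(dim(arr)[1L])
  }
  C <- dim(arr)[2L]
  if (dim(arr)[3L] < C)
    warnf("trial length %d < channel count %d: covariance is rank-deficient",
          dim(arr)[3L], C)
  S <- matrix(0, C, C)
  for (i in idx) S <- S + trial_covariance(arr[i, , ])
  S / length(idx)
}

shrink <- function(S, gamma) {
  C <- nrow(S)
  (1 - gamma) * S + gamma * (sum(diag(S)) / C) * diag(C)
}

#' Fit a CSP decomposition from two class covariance matrices
#'
#' Whitens the composite covariance `S_A + S_B` and jointly diagonalizes the
#' class covariances: the returned projection satisfies
#' `t(P) %*% (S_A + S_B) %*% P = I`, with `t(P) %*% S_A %*% P` diagonal and its
#' diagonal (`eigvals_A`) sorted descending.  Paired class eigenvalues sum to
#' one per column.  Spatial patterns (how each CSP component projects onto the
#' channels) are returned as the columns of `patterns = solve(t(P))`.
#'
#' @param S_A,S_B symmetric positive semi-definite channels x channels class
#'   covariance matrices (unit trace).
#' @param shrinkage_gamma shrinkage weight applied to both inputs when the
#'   composite matrix has condition number above `1e10` (default `1e-6`).
#' @return an object of class `csp_model` with elements `P` (projection,
#'   filters in columns), `patterns`, `eigvals_A`, `eigvals_B`.
#' @export
fit_csp <- function(S_A, S_B, shrinkage_gamma = 1e-6) {
  stopifnot(is.matrix(S_A), is.matrix(S_B), all(dim(S_A) == dim(S_B)))
  S_A <- (S_A + t(S_A)) / 2
  S_B <- (S_B + t(S_B)) / 2
  Sc <- S_A + S_B
  ev <- eigen(Sc, symmetric = TRUE)
  if (min(ev$values) <= 0 || max(ev$values) / max(min(ev$values), .Machine$double.xmin) > 1e10) {
    warnf("composite covariance ill-conditioned; applying shrinkage gamma = %g",
          shrinkage_gamma)
    S_A <- shrink(S_A, shrinkage_gamma)
    S_B <- shrink(S_B, shrinkage_gamma)
    ev <- eigen(S_A + S_B, symmetric = TRUE)
  }
  # whitening: t(W) %*% Sc %*% W = I
  W <- ev$vectors %*% diag(1 / sqrt(ev$values), length(ev$values))
  TA <- t(W) %*% S_A %*% W
  ea <- eigen((TA + t(TA)) / 2, symmetric = TRUE)   # descending by default
  P <- W %*% ea$vectors
  lamA <- ea$values
  lamB <- diag(t(P) %*% S_B %*% P)
  structure(list(P = P, patterns = S_A %*% P + S_B %*% P,
                 eigvals_A = lamA, eigvals_B = lamB),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("CSP model: %d channels; class-A eigenvalues %s ... %s\n",
              nrow(x$P), format(x$eigvals_A[1L], digits = 3),
              format(x$eigvals_A[length(x$eigvals_A)], digits = 3)))
  invisible(x)
}

#' Spatially filter a trial with a CSP projection
#'
#' @param trial channels x samples matrix `E`.
#' @param model a [fit_csp()] result (or any matrix taken as `P`).
#' @return `Z = t(P) %*% E`, channels x samples.
#' @export
csp_project <- function(trial, model) {
  P <- if (inherits(model, "csp_model")) model$P else model
  if (nrow(trial) != nrow(P))
    stopf("channel count %d does not match projection (%d)", nrow(trial), nrow(P))
  t(P) %*% trial
}

#' Log-variance CSP features
#'
#' The first `m` and last `m` rows of the projected trial are retained and the
#' feature for row i is `log(var_i / sum(var_j))` over the 2m retained rows,
#' so `sum(exp(F)) == 1` per trial.
#'
#' @param Z projected trial (channels x samples), or a [csp_model()] plus raw
#'   trial via [csp_project()] upstream.
#' @param m spatial filters retained per side (default 2).
#' @param variance_floor lower bound applied to row variances before the log
#'   (default `1e-12`).
#' @return numeric vector of 2m features, named by projected row index.
#' @export
csp_features <- function(Z, m = 2, variance_floor = 1e-12) {
  C <- nrow(Z)
  if (2 * m > C) stopf("2m = %d exceeds channel count %d", 2 * m, C)
  rows <- c(seq_len(m), C - m + seq_len(m))
  v <- apply(Z[rows, , drop = FALSE], 1L, stats::var)
  if (any(v < variance_floor)) {
    warnf("zero-variance projected row; flooring at %g", variance_floor)
    v <- pmax(v, variance_floor)
  }
  f <- log(v / sum(v))
  names(f) <- paste0("f", rows)
  f
}

# features straight from a per-trial covariance: var(row i of t(P) E) equals
# diag(t(P) S P); the trace normalization of S cancels in the ratio.
csp_features_cov <- function(S, model, m = 2, variance_floor = 1e-12) {
  P <- model$P
  C <- ncol(P)
  rows <- c(seq_len(m), C - m + seq_len(m))
  v <- colSums(P[, rows, drop = FALSE] * (S %*% P[, rows, drop = FALSE]))
  v <- pmax(v, variance_floor)
  f <- log(v / sum(v))
  names(f) <- paste0("f", rows)
  f
}
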