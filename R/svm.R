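# Soft-margin linear SVM (libsvm via e1071) behind a small surface that fixes
# the sign convention: positive decision values correspond to class A (the
# first label level, "H" by convention).  Bias correction subtracts the mean
# decision value observed during a no-task baseline.

#' Train a soft-margin linear SVM
#'
#' Minimizes `0.5 * t(w) %*% w + C * sum(xi)` over separating hyperplanes;
#' prediction is `sign(t(w) %*% x + b)` mapped to the class labels with
#' positive values for class A.  Features enter as produced (log-variance
#' features are already scale-stabilized); no internal standardization.
#'
#' @param features n x k numeric matrix.
#' @param labels two-class labels, length n.
#' @param C slack weight (default 1).
#' @return an object of class `svm_model` with elements `w` (length k), `b`,
#'   `C` and `levels` (class A first).
#' @export
train_svm <- function(features, labels, C = 1) {
  features <- as.matrix(features)
  labels <- as_class_factor(labels)
  if (any(!is.finite(features))) stopf("non-finite feature values")
  if (nlevels(droplevels(labels)) < 2L) stopf("both classes must be present")
  fit <- e1071::svm(features, labels, kernel = "linear", cost = C,
                    scale = FALSE, type = "C-classification")
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # enforce: positive decision <=> class A (first level)
  dv <- drop(features %*% w) + b
  pred_first <- levels(labels)[ifelse(dv >= 0, 1L, 2L)]
  if (mean(pred_first == as.character(labels)) < mean(pred_first != as.character(labels))) {
    w <- -w
    b <- -b
  }
  structure(list(w = w, b = b, C = C, levels = levels(labels)),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("Linear SVM: %d features, C = %g, classes %s(+) / %s(-)\n",
              length(x$w), x$C, x$levels[1L], x$levels[2L]))
  invisible(x)
}

#' Bias-corrected SVM decision value
#'
#' @param model an [train_svm()] result.
#' @param x a k-vector or n x k matrix of features.
#' @param bias_offset baseline mean decision value to subtract (default 0).
#' @return numeric decision value(s): `t(w) %*% x + b - bias_offset`.
#' @export
decision_value <- function(model, x, bias_offset = 0) {
  stopifnot(inherits(model, "svm_model"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(x) != length(model$w))
    stopf("feature dimension %d does not match model (%d)", ncol(x), length(model$w))
  drop(x %*% model$w) + model$b - bias_offset
}

svm_predict_class <- function(model, x, bias_offset = 0) {
  dv <- decision_value(model, x, bias_offset)
  factor(model$levels[ifelse(dv >= 0, 1L, 2L)], levels = model$levels)
}

#' Estimate the classifier bias from baseline windows
#'
#' The mean raw decision value over feature vectors extracted while the
#' participant fixates (no imagery); subtracting it recenters the online
#' decision stream around zero.
#'
#' @param model an [train_svm()] result.
#' @param baseline_features matrix of k-feature rows from baseline windows.
#' @return scalar bias offset.
#' @export
estimate_bias <- function(model, baseline_features) {
  baseline_features <- as.matrix(baseline_features)
  if (!nrow(baseline_features)) stopf("empty baseline")
  mean(decision_value(model, baseline_features))
}

#' Clip outliers and normalize EEG amplitudes to [-1, 1]
#'
#' The `clip_frac` largest and smallest amplitude values (quantiles pooled
#' over all channels and samples of the recording) are treated as outliers and
#' replaced by the bounds; the bounded signal is then mapped linearly so the
#' bounds become -1 and +1.  This evens out absolute amplitude differences
#' between subjects and acquisition systems before building a fused model.
#'
#' @param x a [continuous_eeg()], [trial_set()], or numeric array.
#' @param clip_frac fraction clipped at each tail (default 0.015, i.e. the
#'   1.5% extremes).
#' @param bounds optional `c(lo, hi)` to reuse stored normalization bounds
#'   instead of estimating them (what an online system does for new data).
#' @return object of the same type with normalized amplitudes and an attribute
#'   `norm_params = list(lo, hi, clip_frac)`.
#' @export
normalize_subject <- function(x, clip_frac = 0.015, bounds = NULL) {
  vals <- if (inherits(x, "continuous_eeg")) x$samples
          else if (inherits(x, "trial_set")) x$trials
          else x
  if (is.null(bounds)) {
    if (!(clip_frac > 0 && clip_frac < 0.5)) stopf("clip_frac must be in (0, 0.5)")
    bounds <- stats::quantile(vals, c(clip_frac, 1 - clip_frac), names = FALSE)
  }
  lo <- bounds[1L]; hi <- bounds[2L]
  if (hi - lo < .Machine$double.eps)
    stopf("constant signal: cannot normalize")
  out <- (pmin(pmax(vals, lo), hi) - lo) / (hi - lo) * 2 - 1
  np <- list(lo = lo, hi = hi, clip_frac = clip_frac)
  if (inherits(x, "continuous_eeg")) { x$samples <- out } else
  if (inherits(x, "trial_set")) { x$trials <- out } else x <- out
  attr(x, "norm_params") <- np
  x
}
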