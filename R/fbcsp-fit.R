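# The central model: filter bank -> per-band CSP -> log-variance features ->
# mutual-information selection -> linear SVM.
#
# Filtering and the per-trial covariance are label-free per-trial operations,
# so the fit runs on a precomputed n_trials x n_bands stack of trace-normalized
# band covariances; cross-validation reuses the same stack and refits only the
# supervised stages inside each training fold.

# n x n_bands x C x C stack of per-trial band covariances
band_covariances <- function(ts, spec) {
  stopifnot(inherits(ts, "trial_set"))
  n <- n_trials(ts)
  C <- dim(ts$trials)[2L]
  filters <- build_filters(spec, ts$fs)
  covs <- array(0, c(n, spec$n_bands, C, C))
  for (i in seq_len(n)) {
    E <- ts$trials[i, , ]
    for (b in seq_len(spec$n_bands)) {
      Eb <- t(vapply(seq_len(C), function(ch) sos_filter(filters[[b]], E[ch, ]),
                     numeric(ncol(E))))
      if (spec$mode == "zero_phase")
        Eb <- t(vapply(seq_len(C), function(ch)
          rev(sos_filter(filters[[b]], rev(Eb[ch, ]))), numeric(ncol(E))))
      covs[i, b, , ] <- trial_covariance(Eb)
    }
  }
  covs
}

# supervised stages from the covariance stack; `idx` selects training trials
fbcsp_fit_cov <- function(covs, labels, idx = seq_along(labels), m, k, C,
                          pair_completion = FALSE, shrinkage_gamma = 1e-6,
                          variance_floor = 1e-12, bandwidth_rule = 1.06) {
  n_bands <- dim(covs)[2L]
  lv <- levels(labels)
  csp <- vector("list", n_bands)
  for (b in seq_len(n_bands)) {
    iA <- idx[labels[idx] == lv[1L]]
    iB <- idx[labels[idx] == lv[2L]]
    if (!length(iA) || !length(iB)) stopf("both classes required for CSP")
    S_A <- colMeans(covs[iA, b, , , drop = FALSE], dims = 2L)
    S_B <- colMeans(covs[iB, b, , , drop = FALSE], dims = 2L)
    csp[[b]] <- fit_csp(S_A, S_B, shrinkage_gamma)
  }
  feat <- fbcsp_features_cov(covs, csp, idx, m, variance_floor)
  column_ids <- data.frame(band = rep(seq_len(n_bands), each = 2L * m),
                           filter = rep(seq_len(2L * m), n_bands))
  selection <- select_features(feat, labels[idx], k = k, column_ids = column_ids,
                               pair_completion = pair_completion,
                               bandwidth_rule = bandwidth_rule)
  svm <- train_svm(feat[, selection$selected, drop = FALSE], labels[idx], C = C)
  list(csp = csp, selection = selection, svm = svm, column_ids = column_ids,
       train_features = feat)
}

# feature table (rows = trials in idx, columns = band-major (band, filter))
fbcsp_features_cov <- function(covs, csp, idx, m, variance_floor = 1e-12) {
  n_bands <- dim(covs)[2L]
  feat <- matrix(0, length(idx), n_bands * 2L * m)
  for (r in seq_along(idx)) {
    for (b in seq_len(n_bands)) {
      feat[r, (b - 1L) * 2L * m + seq_len(2L * m)] <-
        csp_features_cov(covs[idx[r], b, , ], csp[[b]], m, variance_floor)
    }
  }
  colnames(feat) <- paste0("b", rep(seq_len(n_bands), each = 2L * m),
                           ".f", rep(seq_len(2L * m), n_bands))
  feat
}

#' Fit a filter-bank CSP classification model
#'
#' Trains the full two-class pipeline on an epoched trial set: each trial is
#' decomposed by the band-pass [filter_bank()], a CSP projection is fit per
#' band from the class-average trace-normalized covariances, log-variance
#' features of the first and last `m` CSP components are extracted, the `k`
#' feature columns with the highest mutual information with the class labels
#' are selected, and a soft-margin linear SVM is trained on them.
#'
#' @param x a [trial_set()] (labels taken from it), or an
#'   `n x channels x samples` array with `labels` supplied.
#' @param labels per-trial labels when `x` is a bare array.
#' @param bands a [filter_bank()] specification.
#' @param m CSP filters retained per side per band (default 2).
#' @param k feature columns selected by mutual information (default 4).
#' @param C SVM slack weight (default 1).
#' @param pair_completion also select mirror CSP filters
#'   (see [select_features()], default `FALSE`).
#' @param shrinkage_gamma,variance_floor,bandwidth_rule numerical guards; see
#'   [fit_csp()], [csp_features()] and [mutual_information()].
#' @return an object of class `fbcsp`: per-band `csp` models, the
#'   `selection`, the `svm`, the training `features` table and the
#'   configuration.  Methods: [predict.fbcsp()], `print`, `summary`, `coef`.
#' @examples
#' cfg <- synth_config(n_channels = 8, n_trials_per_class = 10, trial_s = 2, seed = 1)
#' ts <- generate_subject(cfg)
#' fit <- fbcsp(ts)
#' table(predict(fit, ts), ts$labels)
#' @export
fbcsp <- function(x, labels = NULL, bands = filter_bank(), m = 2, k = 4, C = 1,
                  pair_completion = FALSE, shrinkage_gamma = 1e-6,
                  variance_floor = 1e-12, bandwidth_rule = 1.06) {
  if (!inherits(x, "trial_set")) {
    if (is.null(labels)) stopf("labels required when x is not a trial_set")
    x <- trial_set(x, labels, fs = attr(x, "fs") %||% stop("fs unknown"))
  }
  covs <- band_covariances(x, bands)
  fit <- fbcsp_fit_cov(covs, x$labels, seq_len(n_trials(x)), m = m, k = k, C = C,
                       pair_completion = pair_completion,
                       shrinkage_gamma = shrinkage_gamma,
                       variance_floor = variance_floor,
                       bandwidth_rule = bandwidth_rule)
  structure(list(bands = bands, fs = x$fs, channel_names = x$channel_names,
                 m = m, k = k, C = C, csp = fit$csp, selection = fit$selection,
                 svm = fit$svm, column_ids = fit$column_ids,
                 features = fit$train_features, levels = levels(x$labels),
                 n_train = n_trials(x), call = match.call()),
            class = "fbcsp")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class labels or decision values from a fitted FBCSP model
#'
#' @param object a fitted [fbcsp()] model.
#' @param newdata a [trial_set()], an `n x channels x samples` array, or a
#'   precomputed feature matrix (`n x k`, matching the selected columns).
#' @param type `"class"` (default), `"decision"` for bias-corrected decision
#'   values, or `"feature"` for the selected feature matrix.
#' @param bias_offset baseline offset subtracted from decision values
#'   (default: the model's stored offset, 0 if none).
#' @param ... unused.
#' @return factor of predicted labels, numeric decision values, or the feature
#'   matrix.
#' @export
predict.fbcsp <- function(object, newdata, type = c("class", "decision", "feature"),
                          bias_offset = NULL, ...) {
  type <- match.arg(type)
  bias_offset <- bias_offset %||% object$bias_offset %||% 0
  feat <- fbcsp_selected_features(object, newdata)
  switch(type,
         feature = feat,
         decision = decision_value(object$svm, feat, bias_offset),
         class = svm_predict_class(object$svm, feat, bias_offset))
}

fbcsp_selected_features <- function(object, newdata) {
  if (is.matrix(newdata) && ncol(newdata) == object$k) return(newdata)
  ts <- if (inherits(newdata, "trial_set")) newdata
        else trial_set(newdata, rep(object$levels, length.out = dim(newdata)[1L]),
                       object$fs, object$channel_names)
  if (dim(ts$trials)[2L] != length(object$channel_names))
    stopf("channel count %d does not match model (%d)",
          dim(ts$trials)[2L], length(object$channel_names))
  covs <- band_covariances(ts, object$bands)
  feat <- fbcsp_features_cov(covs, object$csp, seq_len(n_trials(ts)), object$m)
  feat[, object$selection$selected, drop = FALSE]
}

#' @export
print.fbcsp <- function(x, ...) {
  cat(sprintf("FBCSP model: %d bands x 2m=%d CSP features, k = %d selected, SVM C = %g\n",
              x$bands$n_bands, 2 * x$m, x$k, x$C))
  cat(sprintf("  trained on %d trials (%s vs %s), %d channels at %g Hz\n",
              x$n_train, x$levels[1L], x$levels[2L],
              length(x$channel_names), x$fs))
  invisible(x)
}

#' @export
summary.fbcsp <- function(object, ...) {
  e <- band_edges(object$bands)
  sel <- object$selection
  ids <- sel$column_ids[sel$selected, , drop = FALSE]
  out <- data.frame(column = sel$selected,
                    band = ids$band,
                    band_hz = sprintf("%g-%g", e[ids$band, 1L], e[ids$band, 2L]),
                    filter = ids$filter,
                    mi_bits = sel$mi_scores[sel$selected],
                    svm_weight = object$svm$w)
  structure(list(model = object, selected = out), class = "summary.fbcsp")
}

#' @export
print.summary.fbcsp <- function(x, ...) {
  print(x$model)
  cat("Selected features (descending mutual information):\n")
  print(x$selected, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.fbcsp <- function(object, ...) {
  w <- object$svm$w
  names(w) <- colnames(object$features)[object$selection$selected]
  c(w, bias = object$svm$b)
}
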