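# Subject-independent fused model: select subjects whose individual repeated
# cross-validation accuracy reaches a threshold, normalize each subject's
# amplitudes to [-1, 1], concatenate trials, and train one FBCSP model on the
# pooled set.

#' Build a subject-independent fused FBCSP model
#'
#' Each subject is first evaluated with repeated stratified cross-validation;
#' subjects whose mean accuracy reaches `threshold` (equality passes) enter
#' the pool.  Each passing subject's recording is normalized to `[-1, 1]`
#' via [normalize_subject()] (outlier clipping at `clip_frac` per tail), the
#' trials are concatenated, and the full pipeline ([fbcsp()]) is trained on
#' the pooled trial set.
#'
#' @param subjects list of [trial_set()] objects, one per subject.
#' @param threshold minimum individual CV accuracy for inclusion
#'   (default 0.75).
#' @param clip_frac amplitude clipping fraction per tail (default 0.015).
#' @param n_folds,n_reps individual CV protocol (default 10 x 10).
#' @param seed seed for the per-subject CV fold shuffling.
#' @param select optional logical vector overriding the CV-based subject
#'   selection (e.g. when individual accuracies are already known).
#' @param ... passed to [fbcsp()] (bands, m, k, C, ...).
#' @return an object of class `fbcsp_fused` (inherits `fbcsp`) with extra
#'   elements `norm_params` (per included subject), `subject_accuracy`,
#'   `included`, `n_train` and `bias_offset` (0 until estimated online).
#' @export
fuse_subjects <- function(subjects, threshold = 0.75, clip_frac = 0.015,
                          n_folds = 10, n_reps = 10, seed = 1, select = NULL, ...) {
  stopifnot(length(subjects) >= 2L)
  acc <- rep(NA_real_, length(subjects))
  if (is.null(select)) {
    for (s in seq_along(subjects)) {
      cv <- cross_validate(subjects[[s]], n_folds = n_folds, n_reps = n_reps,
                           seed = sub_seed(seed, "fuse-cv", s), ...)
      acc[s] <- cv$mean_accuracy
    }
    select <- acc >= threshold
  }
  if (sum(select) < 2L)
    stopf("fewer than 2 subjects pass the %.0f%% accuracy threshold", 100 * threshold)
  norm_params <- vector("list", length(subjects))
  normed <- list()
  for (s in which(select)) {
    ns <- normalize_subject(subjects[[s]], clip_frac = clip_frac)
    norm_params[[s]] <- attr(ns, "norm_params")
    normed[[length(normed) + 1L]] <- ns
  }
  pooled <- bind_trial_sets(normed)
  fit <- fbcsp(pooled, ...)
  fit$norm_params <- norm_params
  fit$subject_accuracy <- acc
  fit$included <- which(select)
  fit$clip_frac <- clip_frac
  fit$threshold <- threshold
  fit$bias_offset <- 0
  class(fit) <- c("fbcsp_fused", class(fit))
  fit
}

#' @export
print.fbcsp_fused <- function(x, ...) {
  cat(sprintf("Fused subject-independent FBCSP model: %d subjects pooled, %d trials\n",
              length(x$included), x$n_train))
  NextMethod()
}

#' Predict with a fused model on a new subject's trials
#'
#' The new subject's amplitudes are normalized with their own pooled quantiles
#' (the model's stored `clip_frac`), exactly as the online system treats a new
#' user, before the fused pipeline is applied.
#'
#' @inheritParams predict.fbcsp
#' @param normalize apply per-subject normalization first (default `TRUE`).
#' @export
predict.fbcsp_fused <- function(object, newdata, type = c("class", "decision", "feature"),
                                bias_offset = NULL, normalize = TRUE, ...) {
  if (normalize && inherits(newdata, "trial_set"))
    newdata <- normalize_subject(newdata, clip_frac = object$clip_frac %||% 0.015)
  NextMethod(object, newdata = newdata, type = match.arg(type),
             bias_offset = bias_offset)
}
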