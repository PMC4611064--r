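# Offline evaluation: repeated stratified k-fold cross-validation with the
# full pipeline refit inside each training fold, sensitivity/specificity,
# label-permutation significance testing, and leave-one-subject-out transfer.

make_stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))        # uses the caller-set RNG state
    if (length(idx) < n_folds)
      stopf("class '%s' has %d trials, fewer than %d folds", cl, length(idx), n_folds)
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Repeated stratified cross-validation of the FBCSP pipeline
#'
#' In each repetition the trials are randomly shuffled into `n_folds`
#' class-stratified folds; for every fold the complete supervised pipeline
#' (per-band CSP, mutual-information selection, SVM) is refit on the training
#' trials only and scored on the held-out trials.  Band-pass filtering and
#' per-trial covariances are label-free per-trial operations and are computed
#' once up front.
#'
#' @param data a [trial_set()].
#' @param n_folds folds per repetition (default 10).
#' @param n_reps repetitions with fresh fold compositions (default 10).
#' @param seed RNG seed for fold shuffling.
#' @param bands,m,k,C,pair_completion pipeline configuration, see [fbcsp()].
#' @param labels optional label override (used by the permutation test).
#' @param covs optional precomputed [band_covariances()] stack.
#' @return an object of class `cv_report`: `per_rep_accuracy`,
#'   `mean_accuracy`, `sd_accuracy`, `sensitivity`, `specificity` (class A
#'   positive, pooled confusion counts), `fold_spec` and `seed`.
#' @export
cross_validate <- function(data, n_folds = 10, n_reps = 10, seed = 1,
                           bands = filter_bank(), m = 2, k = 4, C = 1,
                           pair_completion = FALSE, labels = NULL, covs = NULL) {
  stopifnot(inherits(data, "trial_set"))
  labels <- if (is.null(labels)) data$labels else as_class_factor(labels, levels(data$labels))
  if (is.null(covs)) covs <- band_covariances(data, bands)
  n <- length(labels)
  lv <- levels(labels)
  per_rep <- numeric(n_reps)
  conf <- matrix(0, 2L, 2L, dimnames = list(truth = lv, pred = lv))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (r in seq_len(n_reps)) {
    fold <- make_stratified_folds(labels, n_folds)
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      fit <- fbcsp_fit_cov(covs, labels, tr, m = m, k = k, C = C,
                           pair_completion = pair_completion)
      feat <- fbcsp_features_cov(covs, fit$csp, te, m)
      pred <- svm_predict_class(fit$svm, feat[, fit$selection$selected, drop = FALSE])
      correct <- correct + sum(pred == labels[te])
      for (i in seq_along(te))
        conf[as.integer(labels[te[i]]), as.integer(pred[i])] <-
          conf[as.integer(labels[te[i]]), as.integer(pred[i])] + 1
    }
    per_rep[r] <- correct / n
  }
  structure(list(per_rep_accuracy = per_rep,
                 mean_accuracy = mean(per_rep),
                 sd_accuracy = stats::sd(per_rep),
                 sensitivity = conf[1L, 1L] / sum(conf[1L, ]),
                 specificity = conf[2L, 2L] / sum(conf[2L, ]),
                 confusion = conf,
                 fold_spec = c(n_folds = n_folds, n_reps = n_reps),
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%dx%d-fold CV: accuracy %.1f%% (sd %.1f), sensitivity %.1f%%, specificity %.1f%%\n",
              x$fold_spec["n_reps"], x$fold_spec["n_folds"],
              100 * x$mean_accuracy, 100 * (x$sd_accuracy %||% 0),
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Sensitivity and specificity from predictions
#'
#' Class A (`"H"`, happy imagery) is the positive class:
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP).
#'
#' @param predictions,labels equal-length class vectors.
#' @param positive the positive class (default: first label level).
#' @return named vector `c(sensitivity, specificity)`; `NaN` with a warning
#'   when a class is absent from `labels`.
#' @export
confusion_stats <- function(predictions, labels, positive = NULL) {
  if (length(predictions) != length(labels)) stopf("length mismatch")
  labels <- as_class_factor(labels)
  positive <- positive %||% levels(labels)[1L]
  pos <- labels == positive
  if (!any(pos) || all(pos))
    warnf("sensitivity/specificity undefined: only one class present in labels")
  sens <- sum(predictions == positive & pos) / sum(pos)
  spec <- sum(predictions != positive & !pos) / sum(!pos)
  c(sensitivity = sens, specificity = spec)
}

#' Label-permutation randomization test
#'
#' Repeats the full cross-validation with uniformly permuted trial labels to
#' build the null distribution of accuracies, and ranks the observed accuracy
#' within it (strictly-less ranking, ties counted as half).
#'
#' @param data a [trial_set()].
#' @param n_perm permutations (the reference protocol uses 1001).
#' @param n_folds,n_reps CV protocol applied to each permutation.
#' @param seed RNG seed (permutations and fold shuffles derive from it).
#' @param observed optional precomputed observed accuracy; computed with the
#'   same CV protocol if missing.
#' @param ... pipeline configuration passed to [cross_validate()].
#' @return an object of class `rand_test_report`: `null_accuracies`,
#'   `observed`, `percentile_rank`.
#' @export
randomization_test <- function(data, n_perm = 1001, n_folds = 10, n_reps = 10,
                               seed = 1, observed = NULL, ...) {
  stopifnot(n_perm >= 1)
  covs <- band_covariances(data, list(...)$bands %||% filter_bank())
  if (is.null(observed))
    observed <- cross_validate(data, n_folds, n_reps,
                               seed = sub_seed(seed, "rt-obs"), covs = covs,
                               ...)$mean_accuracy
  null_acc <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    set.seed(sub_seed(seed, "rt-perm", p))
    perm <- sample(as.character(data$labels))
    null_acc[p] <- cross_validate(data, n_folds, n_reps,
                                  seed = sub_seed(seed, "rt-cv", p),
                                  labels = perm, covs = covs, ...)$mean_accuracy
  }
  rank <- (sum(null_acc < observed) + 0.5 * sum(null_acc == observed)) / n_perm
  structure(list(null_accuracies = null_acc, observed = observed,
                 percentile_rank = rank, n_perm = n_perm, seed = seed),
            class = "rand_test_report")
}

#' @export
print.rand_test_report <- function(x, ...) {
  cat(sprintf("Randomization test (%d permutations): observed %.1f%%, null mean %.1f%%, percentile rank %.3f\n",
              x$n_perm, 100 * x$observed, 100 * mean(x$null_accuracies),
              x$percentile_rank))
  invisible(x)
}

#' Leave-one-subject-out transfer evaluation
#'
#' For each subject, a fused pipeline is trained on all other subjects
#' (per-subject normalization, concatenation, full FBCSP fit) and tested on
#' the held-out subject's trials.  The held-out subject is normalized with its
#' own pooled quantiles, as the online system would treat a new user.
#'
#' @param subjects list of [trial_set()] objects (>= 2).
#' @param clip_frac amplitude clipping fraction (default 0.015).
#' @param ... pipeline configuration passed to [fbcsp()].
#' @return numeric vector of held-out accuracies, one per subject.
#' @export
leave_one_subject_out <- function(subjects, clip_frac = 0.015, ...) {
  if (length(subjects) < 2L) stopf("need at least 2 subjects")
  acc <- numeric(length(subjects))
  for (s in seq_along(subjects)) {
    model <- fuse_subjects(subjects[-s], clip_frac = clip_frac,
                           select = rep(TRUE, length(subjects) - 1L), ...)
    pred <- predict(model, subjects[[s]])
    acc[s] <- mean(pred == subjects[[s]]$labels)
  }
  acc
}
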