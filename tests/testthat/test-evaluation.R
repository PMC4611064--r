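test_that("cross-validation separates a strongly discriminable subject", {
  ts <- small_subject()
  cv <- cross_validate(ts, n_folds = 5, n_reps = 2, seed = 1, covs = small_covs())
  expect_gt(cv$mean_accuracy, 0.85)
  expect_length(cv$per_rep_accuracy, 2)
  expect_true(all(cv$per_rep_accuracy >= 0 & cv$per_rep_accuracy <= 1))
  # sensitivity/specificity agree with the pooled confusion counts
  expect_equal(cv$sensitivity, cv$confusion[1, 1] / sum(cv$confusion[1, ]))
  expect_equal(cv$specificity, cv$confusion[2, 2] / sum(cv$confusion[2, ]))
})

test_that("random labels drive accuracy to chance", {
  ts <- null_subject()
  set.seed(1)
  cv <- cross_validate(ts, n_folds = 5, n_reps = 4, seed = 2,
                       labels = sample(as.character(ts$labels)))
  expect_lt(abs(cv$mean_accuracy - 0.5), 0.15)
})

test_that("fold construction respects stratification and size limits", {
  ts <- small_subject()
  expect_error(cross_validate(ts, n_folds = 16, n_reps = 1), "fewer than")
  set.seed(1)
  fold <- fbcsp:::make_stratified_folds(ts$labels, 5)
  for (f in 1:5)
    expect_equal(as.integer(table(ts$labels[fold == f])), c(3L, 3L))
})

test_that("identical seeds reproduce identical CV reports", {
  ts <- small_subject()
  covs <- small_covs()
  a <- cross_validate(ts, n_folds = 5, n_reps = 2, seed = 9, covs = covs)
  b <- cross_validate(ts, n_folds = 5, n_reps = 2, seed = 9, covs = covs)
  expect_identical(a$per_rep_accuracy, b$per_rep_accuracy)
  expect_identical(a$confusion, b$confusion)
})

test_that("confusion statistics follow the TP/FN/TN/FP arithmetic", {
  labels <- rep(c("H", "M"), each = 10)
  expect_equal(unname(confusion_stats(labels, labels)), c(1, 1))
  expect_equal(unname(confusion_stats(rep("H", 20), labels)), c(1, 0))
  # TP=30 FN=10 TN=35 FP=5 -> sensitivity 0.75, specificity 0.875
  truth <- rep(c("H", "M"), c(40, 40))
  pred <- c(rep("H", 30), rep("M", 10), rep("M", 35), rep("H", 5))
  expect_equal(unname(confusion_stats(pred, truth)), c(30 / 40, 35 / 40))
  expect_warning(confusion_stats(rep("H", 3), factor(rep("H", 3), c("H", "M"))),
                 "one class")
})

test_that("permutation null is centred on chance and ranks correctly", {
  ts <- null_subject()
  rt <- randomization_test(ts, n_perm = 30, n_folds = 5, n_reps = 1, seed = 3,
                           observed = 0.9)
  expect_length(rt$null_accuracies, 30)
  expect_lt(abs(mean(rt$null_accuracies) - 0.5), 0.06)
  expect_equal(rt$percentile_rank, 1)                # 0.9 beats every null
  rt2 <- randomization_test(ts, n_perm = 30, n_folds = 5, n_reps = 1, seed = 3,
                            observed = 0)
  expect_equal(rt2$percentile_rank, 0)
  # ties count as half
  rnk <- (sum(rt$null_accuracies < median(rt$null_accuracies)) +
            0.5 * sum(rt$null_accuracies == median(rt$null_accuracies))) / 30
  rt3 <- randomization_test(ts, n_perm = 30, n_folds = 5, n_reps = 1, seed = 3,
                            observed = median(rt$null_accuracies))
  expect_equal(rt3$percentile_rank, rnk)
})

test_that("preprocessing is per-trial: no information crosses trials", {
  # the covariance stack of a subset equals the matching slice of the full
  # stack, so fold-wise refits can never see held-out trials
  ts <- small_subject()
  full <- small_covs()
  sub <- trial_set(ts$trials[3:7, , , drop = FALSE], ts$labels[3:7], ts$fs)
  part <- fbcsp:::band_covariances(sub, filter_bank())
  expect_identical(part, full[3:7, , , , drop = FALSE])
})

test_that("leave-one-subject-out transfers across same-family subjects", {
  cfg <- small_cfg(n_per_class = 10)
  subs <- lapply(1:3, function(s) generate_subject(cfg, s))
  acc <- leave_one_subject_out(subs)
  expect_length(acc, 3)
  expect_true(all(acc >= 0.85))
  # a label-permuted held-out subject scores at chance
  perm <- subs[[3]]
  set.seed(5)
  perm$labels <- sample(perm$labels)
  acc_perm <- leave_one_subject_out(list(subs[[1]], subs[[2]], perm))
  expect_lt(abs(acc_perm[3] - 0.5), 0.2)
  expect_error(leave_one_subject_out(subs[1]), "at least 2")
})
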