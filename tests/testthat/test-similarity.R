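test_that("similarity indices behave at the identity and under shuffling", {
  set.seed(71)
  a <- rnorm(28)
  expect_equal(csp_similarity(a, a, "correlation"), 1)
  expect_equal(csp_similarity(a, a, "euclidean"), 0)
  b <- sample(a)
  expect_lt(abs(csp_similarity(a, b, "correlation")), 0.5)
  expect_error(csp_similarity(a, rnorm(10)), "lengths")
  expect_warning(s <- csp_similarity(a, rep(1, 28), "correlation"), "undefined")
  expect_true(is.na(s))
})

test_that("similarity is invariant to positive rescaling and sign flips", {
  set.seed(73)
  a <- rnorm(28); b <- rnorm(28)
  for (m in c("correlation", "mutual_information", "euclidean")) {
    s <- csp_similarity(a, b, m)
    expect_equal(csp_similarity(7 * a, b, m), s, tolerance = 1e-12)
    expect_equal(csp_similarity(-a, 0.1 * b, m), s, tolerance = 1e-12)
  }
})

test_that("correlation similarity decays monotonically along a noise ladder", {
  set.seed(79)
  a <- rnorm(28)
  levels <- seq(0, 3, length.out = 10)
  # average over noise draws so the trend is about the ladder, not one sample
  sim <- sapply(levels, function(s)
    mean(replicate(30, csp_similarity(a, a + rnorm(28, sd = s), "correlation"))))
  expect_equal(sim[1], 1)
  expect_lt(cor(seq_along(sim), sim, method = "spearman"), -0.9)
  # correlation- and euclidean-based orderings of the ladder agree
  sim_e <- sapply(levels, function(s)
    mean(replicate(30, csp_similarity(a, a + rnorm(28, sd = s), "euclidean"))))
  expect_gt(cor(rank(-sim), rank(sim_e), method = "spearman"), 0.9)
})

test_that("OLS regression matches the closed-form oracle", {
  expect_equal(similarity_accuracy_regression(c(0, 1, 2), c(0, 1, 2)),
               c(slope = 1, intercept = 0, r_squared = 1))
  set.seed(83)
  x <- rnorm(12); y <- 2.5 * x - 1 + rnorm(12, sd = 0.1)
  fit <- similarity_accuracy_regression(x, y)
  # brute-force least squares and r^2 = 1 - SSE/SST
  bx <- cov(x, y) / var(x); b0 <- mean(y) - bx * mean(x)
  sse <- sum((y - b0 - bx * x)^2); sst <- sum((y - mean(y))^2)
  expect_equal(unname(fit), c(bx, b0, 1 - sse / sst), tolerance = 1e-8)
  expect_warning(r <- similarity_accuracy_regression(rep(1, 5), rnorm(5)),
                 "constant")
  expect_true(all(is.na(r)))
  # uncorrelated pairs rarely explain much variance
  r2s <- replicate(50, similarity_accuracy_regression(rnorm(12),
                                                      rnorm(12))["r_squared"])
  expect_lt(median(r2s), 0.3)
})

test_that("run CSP extraction is deterministic and condition-resolved", {
  ts <- small_subject()
  p1 <- extract_run_csp(ts)
  p2 <- extract_run_csp(ts)
  expect_identical(p1, p2)
  expect_equal(colnames(p1), c("H", "M"))
  expect_equal(nrow(p1), 12)
  one_class <- trial_set(ts$trials[ts$labels == "H", , , drop = FALSE],
                         droplevels(ts$labels[ts$labels == "H"]), ts$fs)
  expect_error(extract_run_csp(one_class), "classes|two")
})

test_that("runs from the model's own family are more similar than permuted runs", {
  cfg <- small_cfg(n_per_class = 10)
  subs <- lapply(1:2, function(s) generate_subject(cfg, s))
  model <- fuse_subjects(subs, select = c(TRUE, TRUE))
  wins <- 0L
  n_seeds <- 5L
  for (s in seq_len(n_seeds)) {
    run <- generate_subject(cfg, subject = 10L + s)
    perm <- run
    set.seed(s)
    perm$labels <- sample(perm$labels)
    ref <- model_csp_patterns(model)
    sim_true <- csp_similarity(extract_run_csp(run)[, "H"], ref[, "H"])
    sim_perm <- csp_similarity(extract_run_csp(perm)[, "H"], ref[, "H"])
    wins <- wins + (sim_true >= sim_perm)
  }
  expect_gte(wins, 4L)
})

test_that("the similarity report assembles per-run indices and regressions", {
  cfg <- small_cfg(n_per_class = 8)
  subs <- lapply(1:2, function(s) generate_subject(cfg, s))
  model <- fuse_subjects(subs, select = c(TRUE, TRUE))
  runs <- lapply(3:6, function(s) generate_subject(cfg, s))
  rep_ <- similarity_report(runs, model, accuracies = c(0.55, 0.6, 0.7, 0.65),
                            methods = c("correlation", "euclidean"))
  expect_equal(nrow(rep_$per_run), 4 * 2 * 2)
  expect_true(all(rep_$per_run$similarity[rep_$per_run$method == "euclidean"] >= 0))
  expect_true(all(abs(rep_$per_run$similarity[rep_$per_run$method == "correlation"]) <= 1))
  expect_equal(nrow(rep_$regression), 4)
  expect_true(all(rep_$regression$r_squared >= 0 & rep_$regression$r_squared <= 1))
})
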