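test_that("class entropy matches the closed form", {
  expect_equal(class_entropy(rep(c("H", "M"), each = 40)), 1.0)
  expect_equal(class_entropy(rep("H", 80)), 0.0)
  # 60/20 split: -(0.75 log2 0.75 + 0.25 log2 0.25)
  expect_equal(class_entropy(rep(c("H", "M"), c(60, 20))),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-12)
  expect_equal(class_entropy(rep(c("H", "M"), c(60, 20))), 0.811278,
               tolerance = 1e-6)
  expect_error(class_entropy(character(0)), "empty")
})

test_that("mutual information brackets informative and useless features", {
  labels <- rep(c("H", "M"), each = 40)
  sep <- ifelse(labels == "H", 1, -1) + rnorm(80, sd = 1e-3)
  expect_gt(mutual_information(sep, labels), 0.95)
  expect_equal(mutual_information(rep(2.5, 80), labels), 0)
  # label-independent feature: near zero on average over label shuffles
  set.seed(13)
  noise <- rnorm(400)
  lab400 <- rep(c("H", "M"), each = 200)
  mis <- replicate(100, mutual_information(noise, sample(lab400)))
  expect_lt(mean(mis), 0.05)
  # bounds hold column-wise
  expect_true(all(mis >= 0 & mis <= 1))
})

test_that("the kernel MI estimator matches a direct nested-loop evaluation", {
  set.seed(17)
  labels <- factor(rep(c("H", "M"), c(12, 9)), levels = c("H", "M"))
  x <- rnorm(21) + (labels == "H") * 1.5
  # independent brute-force implementation of the same estimator
  direct <- local({
    Hw <- -sum(table(labels) / 21 * log2(table(labels) / 21))
    dens <- matrix(0, 21, 2)
    for (ci in 1:2) {
      xs <- x[as.integer(labels) == ci]
      h <- 1.06 * sd(xs) * length(xs)^(-0.2)
      for (i in 1:21) {
        acc <- 0
        for (s in seq_along(xs)) acc <- acc + dnorm(x[i], xs[s], h)
        dens[i, ci] <- acc / length(xs)
      }
    }
    pw <- as.numeric(table(labels)) / 21
    HwF <- 0
    for (i in 1:21) {
      pf <- dens[i, 1] * pw[1] + dens[i, 2] * pw[2]
      post <- dens[i, ] * pw / pf
      HwF <- HwF - sum(post[post > 0] * log2(post[post > 0])) / 21
    }
    Hw - HwF
  })
  expect_equal(mutual_information(x, labels), direct, tolerance = 1e-8)
})

test_that("MI is invariant to monotone rescaling of the feature", {
  set.seed(19)
  labels <- rep(c("H", "M"), each = 40)
  x <- rnorm(80) + (labels == "H") * 1
  m1 <- mutual_information(x, labels)
  m2 <- mutual_information(5 * x - 3, labels)
  expect_equal(m1, m2, tolerance = 0.05)
})

test_that("top-k selection sorts by score with a deterministic tie-break", {
  labels <- rep(c("H", "M"), each = 30)
  set.seed(23)
  strong <- ifelse(labels == "H", 1, -1) + rnorm(60, sd = 0.2)
  weak <- ifelse(labels == "H", 1, -1) + rnorm(60, sd = 2)
  feats <- cbind(strong, rnorm(60), weak, rnorm(60))
  sel <- select_features(feats, labels, k = 2)
  expect_equal(sort(sel$selected), c(1L, 3L))
  expect_equal(sel$selected[1], 1L)                  # highest score first
  expect_error(select_features(feats, labels, k = 5), "exceeds")
  # all-equal scores fall back to column order
  const <- matrix(rep(rnorm(60), 4), 60, 4)
  sel2 <- select_features(const, labels, k = 2)
  expect_equal(sel2$selected, c(1L, 2L))
})

test_that("pair completion pulls in the mirror CSP filter", {
  labels <- rep(c("H", "M"), each = 30)
  set.seed(29)
  # 1 band, m = 2: columns are filters 1, 2, 3, 4; only column 1 informative
  feats <- cbind(ifelse(labels == "H", 1, -1) + rnorm(60, 0.1),
                 rnorm(60), rnorm(60), rnorm(60))
  ids <- data.frame(band = 1L, filter = 1:4)
  sel <- select_features(feats, labels, k = 2, column_ids = ids,
                         pair_completion = TRUE)
  expect_equal(sort(sel$selected), c(1L, 4L))        # filter 1 and its mirror 4
})

test_that("the discriminative band's features top the MI ranking", {
  fit <- small_fit()
  sel_bands <- fit$column_ids$band[order(-fit$selection$mi_scores)]
  expect_true(all(sel_bands[1:2] %in% c(2L, 4L)))    # alpha-frontal / beta-central
})
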