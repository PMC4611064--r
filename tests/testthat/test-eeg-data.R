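test_that("delimited EEG round-trips through the sidecar format", {
  set.seed(4)
  eeg <- continuous_eeg(matrix(rnorm(2 * 5000, sd = 40), 2, 5000), fs = 500,
                        channel_names = c("Fp1", "Cz"),
                        events = data.frame(onset = 1, duration = 2, label = "H"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eeg(eeg, path)
  back <- read_eeg(path)
  expect_equal(dim(back$samples), c(2L, 5000L))
  expect_equal(back$samples, eeg$samples, tolerance = 1e-12)
  expect_equal(back$fs, 500)
  expect_equal(back$channel_names, c("Fp1", "Cz"))
  expect_equal(back$events$label, "H")
})

test_that("delimited reader enforces its format contract", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t2\t3", "4\t5\t6"), path)
  expect_error(read_eeg(path), "sidecar")
  jsonlite::write_json(list(fs = 10), paste0(path, ".json"), auto_unbox = TRUE)
  expect_silent(read_eeg(path))
  writeLines(c("1\t2\t3", "4\t5"), path)          # ragged rows
  expect_error(read_eeg(path), "inconsistent")
})

test_that("EDF reader recovers channels, rate, amplitudes and annotations", {
  set.seed(9)
  nch <- 28
  samples <- matrix(rnorm(nch * 3 * 100, sd = 30), nch, 300)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf_fixture(path, samples, fs = 100,
                    annotations = data.frame(onset = c(0.5, 1.5),
                                             duration = c(1, 1),
                                             label = c("H", "M")))
  eeg <- read_eeg(path)
  expect_s3_class(eeg, "continuous_eeg")
  expect_length(eeg$channel_names, nch)
  expect_equal(eeg$fs, 100)
  expect_equal(ncol(eeg$samples), 300)
  # int16 quantization of a 400 uV physical span: step ~6.1e-3 uV
  expect_lt(max(abs(eeg$samples - samples)), 0.01)
  expect_equal(eeg$events$label, c("H", "M"))
  expect_equal(eeg$events$onset, c(0.5, 1.5))
  # truncated file is rejected
  raw <- readBin(path, "raw", file.info(path)$size)
  writeBin(raw[1:(length(raw) - 400)], path)
  expect_error(read_eeg(path), "truncated")
})

test_that("epoching cuts equal half-open windows with cue labels", {
  fs <- 100
  sch <- data.frame(label = c("H", "REST", "M", "REST"),
                    onset = c(0, 5, 7, 12), duration = c(5, 2, 5, 2),
                    run = 1L)
  eeg <- continuous_eeg(matrix(seq_len(2 * 1400), 2, 1400), fs = fs)
  ts <- epoch_trials(eeg, sch, keep_labels = c("H", "M"))
  expect_equal(dim(ts$trials), c(2L, 2L, 500L))
  expect_equal(as.character(ts$labels), c("H", "M"))
  # exact half-open windows: first H sample is sample 1, first M is 701
  expect_equal(ts$trials[1, 1, 1], 1)
  expect_equal(ts$trials[2, 1, 1], eeg$samples[1, 701])
  # exhaustive and non-overlapping over kept blocks
  expect_equal(prod(dim(ts$trials)[c(1, 3)]), sum(sch$duration[c(1, 3)] * fs))
  expect_error(epoch_trials(eeg, sch, keep_labels = character(0)), "at least one")
  sch$duration[3] <- 4
  expect_error(epoch_trials(eeg, sch, keep_labels = c("H", "M")), "unequal")
})

test_that("an offline run epochs into 16 five-second regulation trials", {
  sch <- offline_schedule(n_runs = 1, reps_per_run = 8)
  fs <- 500
  span <- max(sch$onset + sch$duration)
  eeg <- continuous_eeg(matrix(rnorm(2 * span * fs), 2), fs = fs)
  ts <- epoch_trials(eeg, sch)
  expect_equal(dim(ts$trials)[1], 16L)
  expect_equal(dim(ts$trials)[3], 2500L)
  expect_equal(as.integer(table(ts$labels)), c(8L, 8L))
})

test_that("trial_set validates its invariants", {
  arr <- array(0, c(4, 3, 10))
  expect_error(trial_set(arr, c("H", "M", "H"), 100), "length")
  expect_error(trial_set(arr, c("H", "M", "X", "H"), 100), "classes|alphabet")
  expect_error(trial_set(array(0, c(0, 3, 10)), character(0), 100), "at least one")
})

test_that("model archives round-trip bit-exactly and detect corruption", {
  model <- small_fit()
  path <- withr::local_tempfile(fileext = ".fbm")
  write_model(model, path)
  back <- read_model(path)
  expect_identical(back$svm$w, model$svm$w)
  expect_identical(back$svm$b, model$svm$b)
  for (b in seq_along(model$csp))
    expect_identical(back$csp[[b]]$P, model$csp[[b]]$P)
  expect_identical(back$selection$selected, as.integer(model$selection$selected))
  expect_equal(back$levels, model$levels)
  # predictions from the restored model are identical
  ts <- small_subject()
  expect_identical(predict(back, ts, type = "decision"),
                   predict(model, ts, type = "decision"))

  raw <- readBin(path, "raw", file.info(path)$size)
  writeBin(raw[1:(length(raw) - 64)], path)        # truncation
  expect_error(read_model(path), "truncated|corrupt")
  flip <- raw
  flip[length(flip) - 3L] <- xor(flip[length(flip) - 3L], as.raw(0xff))
  writeBin(flip, path)                              # bit corruption
  expect_error(read_model(path), "checksum")
})

test_that("fused model archives restore normalization and bias state", {
  cfg <- small_cfg(n_per_class = 8)
  subs <- lapply(1:2, function(s) generate_subject(cfg, s))
  fused <- fuse_subjects(subs, select = c(TRUE, TRUE))
  fused$bias_offset <- 0.25
  path <- withr::local_tempfile(fileext = ".fbm")
  write_model(fused, path)
  back <- read_model(path)
  expect_s3_class(back, "fbcsp_fused")
  expect_identical(back$bias_offset, 0.25)
  expect_equal(back$included, fused$included)
  expect_identical(back$norm_params[[1]]$lo, fused$norm_params[[1]]$lo)
  expect_identical(predict(back, subs[[1]], type = "decision"),
                   predict(fused, subs[[1]], type = "decision"))
})
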