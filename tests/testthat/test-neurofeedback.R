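test_that("the offline schedule yields the documented trial counts", {
  sch <- offline_schedule()
  expect_equal(sum(sch$label %in% c("H", "M")), 80)       # per session
  run1 <- sch[sch$run == 1, ]
  expect_equal(sum(run1$label == "H"), 8)                 # per run per condition
  # 8 cycles x (4 x 5 s stimuli + 4 x 2 s pauses) = 224 s, a ~4-minute run
  expect_equal(max(run1$onset + run1$duration), 224)
  tiny <- offline_schedule(n_runs = 1, reps_per_run = 1)
  expect_equal(sum(tiny$label %in% c("H", "M")), 2)
})

test_that("the online schedule has 8 regulation blocks per run, 96 total", {
  sch <- online_schedule()
  expect_equal(sum(sch$label %in% c("H", "M")), 96)
  for (r in unique(sch$run))
    expect_equal(sum(sch$label[sch$run == r] %in% c("H", "M")), 8)
  expect_equal(sum(sch$label %in% c("H", "M") & sch$session == 1), 32)
  # two fixation blocks per run, the second after the 4th regulation block
  run1 <- sch[sch$run == 1, ]
  expect_equal(sum(run1$label == "FIX"), 2)
  reg_before_fix2 <- sum(run1$label[seq_len(which(run1$label == "FIX")[2])]
                         %in% c("H", "M"))
  expect_equal(reg_before_fix2, 4)
  # documented run span: 2x20 fixation + 8x20 regulation + 8x10 rest = 280 s
  expect_equal(max(run1$onset + run1$duration) - min(run1$onset), 280)
  expect_error(paradigm_schedule(data.frame(label = "XX", onset = 0,
                                            duration = 1, run = 1)), "unknown")
})

test_that("the thermometer walks one bar per update and clips at bounds", {
  st <- thermometer_state()
  expect_equal(st$bars, 10L)
  st2 <- update_thermometer(st, +0.4, "H")
  expect_equal(st2$bars, 11L)
  expect_equal(update_thermometer(st, -0.4, "H")$bars, 9L)
  expect_equal(update_thermometer(st, -0.4, "M")$bars, 11L)  # cue-aware sign
  expect_equal(update_thermometer(st, -0.4, "M", cue_aware = FALSE)$bars, 9L)
  at_max <- thermometer_state(bars = 20)
  expect_equal(update_thermometer(at_max, 1, "H")$bars, 20L)
  # bounded unit-step random walk
  st <- thermometer_state()
  set.seed(51)
  for (i in 1:50) {
    nxt <- update_thermometer(st, rnorm(1), "H")
    expect_lte(abs(nxt$bars - st$bars), 1L)
    expect_true(nxt$bars >= 0 && nxt$bars <= 20)
    st <- nxt
  }
})

test_that("run accuracy discards burn-in windows and scores the rest", {
  # synthetic outputs: one default online run, 8 blocks x 20 windows
  out <- do.call(rbind, lapply(1:8, function(b)
    data.frame(time_s = 0, run = 1L, block = b, window = 1:20,
               cue = if (b %% 2) "H" else "M", decision = 0,
               predicted = if (b %% 2) "H" else "M")))
  acc <- run_accuracy(out, burn_in_windows = 1)
  expect_equal(as.numeric(acc), 1)
  expect_equal(as.integer(attr(acc, "n_scored")), 152L)    # 8 x 19 windows
  out$predicted <- rep(c("H", "M"), length.out = nrow(out))
  expect_equal(as.numeric(run_accuracy(out, burn_in_windows = 0, by_run = FALSE)),
               0.5)
  expect_error(run_accuracy(out, burn_in_windows = 20), "burn-in")
})

test_that("online classification follows the cue of a compliant stream", {
  cfg <- small_cfg(n_per_class = 10)
  subs <- lapply(1:2, function(s) generate_subject(cfg, s))
  model <- fuse_subjects(subs, select = c(TRUE, TRUE))
  sch <- online_schedule(n_sessions = 1, runs_per_session = 1)
  stream <- generate_online_stream(cfg, sch, compliance = 1, subject = 3)
  out <- online_classify(stream, model, sch)
  # one decision per second of regulation, 8 x 20 windows in the run
  expect_equal(nrow(out), 160L)
  expect_equal(unique(out$cue), c("H", "M"))
  acc <- run_accuracy(out, burn_in_windows = 1)
  expect_gt(unname(acc), 0.85)
  # thermometer trace stays within bounds and moves unit steps
  tr <- feedback_trace(out)
  expect_true(all(tr$bars >= 0 & tr$bars <= 20))
  expect_true(all(abs(diff(tr$bars)) <= 1))
})

test_that("a schedule without regulation blocks produces no decisions", {
  cfg <- small_cfg(n_per_class = 4)
  subs <- lapply(1:2, function(s) generate_subject(cfg, s))
  model <- fuse_subjects(subs, select = c(TRUE, TRUE))
  sch <- paradigm_schedule(data.frame(label = c("FIX", "REST"),
                                      onset = c(0, 20), duration = c(20, 10),
                                      run = 1L), variant = "online")
  stream <- generate_online_stream(cfg, sch, compliance = 0)
  out <- online_classify(stream, model, sch)
  expect_equal(nrow(out), 0L)
})

test_that("channel mismatch between stream and model is rejected", {
  model <- small_fit()
  stream <- continuous_eeg(matrix(rnorm(4 * 1000), 4), fs = 500)
  sch <- paradigm_schedule(data.frame(label = "H", onset = 0, duration = 2,
                                      run = 1L), variant = "online")
  expect_error(online_classify(stream, model, sch), "channels")
})
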