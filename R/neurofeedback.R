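# Simulated online classification and thermometer neurofeedback.
#
# The classifier consumes 1 s windows of the continuous stream (the last
# second of data at each update), causally filtered with per-run filter-state
# reset.  The SVM bias is (re-)estimated from the decision values of each
# fixation block and applied to all subsequent windows until the next
# fixation, mirroring the mid-run bias readjustment of the online protocol.

#' Simulate online classification over a continuous recording
#'
#' @param stream a [continuous_eeg()] covering the schedule.
#' @param model a fitted [fbcsp()] or [fuse_subjects()] model.
#' @param schedule an [online_schedule()] (or compatible
#'   [paradigm_schedule()]).
#' @param window_s update interval in seconds (default 1; at 500 Hz each
#'   classification consumes 500 samples).
#' @param normalize normalize the stream amplitudes with its own pooled
#'   quantiles before classification (default `TRUE`, matching how a fused
#'   model treats a new subject).
#' @return data.frame of class `online_run`: one row per regulation window
#'   with `time_s` (window end), `run`, `block` (regulation block index within
#'   run), `window` (window index within block), `cue` ("H"/"M"), `decision`
#'   (bias-corrected value) and `predicted` ("H"/"M").
#' @export
online_classify <- function(stream, model, schedule, window_s = 1,
                            normalize = TRUE) {
  stopifnot(inherits(stream, "continuous_eeg"), inherits(model, "fbcsp"))
  if (nrow(stream$samples) != length(model$channel_names))
    stopf("stream has %d channels, model expects %d",
          nrow(stream$samples), length(model$channel_names))
  fs <- stream$fs
  wlen <- sec_to_sample(window_s, fs)
  if (max(schedule$onset + schedule$duration) * fs > ncol(stream$samples) + 1e-6)
    stopf("stream shorter than schedule span")
  if (normalize)
    stream <- normalize_subject(stream, clip_frac = model$clip_frac %||% 0.015)
  filters <- build_filters(model$bands, fs)
  n_bands <- model$bands$n_bands
  C <- nrow(stream$samples)
  out <- list()
  for (r in unique(schedule$run)) {
    blocks <- schedule[schedule$run == r, , drop = FALSE]
    r0 <- sec_to_sample(min(blocks$onset), fs)
    r1 <- sec_to_sample(max(blocks$onset + blocks$duration), fs)
    seg <- stream$samples[, (r0 + 1L):r1, drop = FALSE]
    # causal filtering of the whole run, state reset at run start
    filt <- array(0, c(n_bands, C, ncol(seg)))
    for (b in seq_len(n_bands))
      for (ch in seq_len(C))
        filt[b, ch, ] <- sos_filter(filters[[b]], seg[ch, ])
    window_features <- function(a, w) {   # w windows starting at sample a (run-rel)
      t(vapply(seq_len(w), function(j) {
        s0 <- a + (j - 1L) * wlen
        unlist(lapply(seq_len(n_bands), function(b) {
          S <- trial_covariance(filt[b, , (s0 + 1L):(s0 + wlen), drop = TRUE])
          csp_features_cov(S, model$csp[[b]], model$m)
        }))
      }, numeric(n_bands * 2L * model$m)))[, model$selection$selected, drop = FALSE]
    }
    bias <- model$bias_offset %||% 0
    reg_i <- 0L
    for (bi in seq_len(nrow(blocks))) {
      lab <- blocks$label[bi]
      a <- sec_to_sample(blocks$onset[bi], fs) - r0
      nw <- floor(blocks$duration[bi] / window_s)
      if (lab == "FIX" && nw > 0L) {
        feats <- window_features(a, nw)
        bias <- mean(decision_value(model$svm, feats))
      } else if (lab %in% c("H", "M") && nw > 0L) {
        reg_i <- reg_i + 1L
        feats <- window_features(a, nw)
        dv <- decision_value(model$svm, feats, bias)
        pred <- ifelse(dv >= 0, "H", "M")
        out[[length(out) + 1L]] <- data.frame(
          time_s = blocks$onset[bi] + seq_len(nw) * window_s,
          run = r, block = reg_i, window = seq_len(nw),
          cue = lab, decision = dv, predicted = pred,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(time_s = numeric(0), run = integer(0), block = integer(0),
                         window = integer(0), cue = character(0),
                         decision = numeric(0), predicted = character(0))
  class(res) <- c("online_run", "data.frame")
  res
}

#' Per-run classification accuracy of an online simulation
#'
#' The first `burn_in_windows` windows of each regulation block are discarded
#' (the filter and imagery onset transient), then accuracy is the fraction of
#' windows whose predicted class matches the cue.  With the default online
#' protocol (8 x 20 s regulation blocks, 1 s updates) and `burn_in_windows =
#' 1` each run scores 8 x 19 = 152 windows.
#'
#' @param outputs an [online_classify()] result.
#' @param burn_in_windows windows discarded at each block start (default 1).
#' @param by_run return one accuracy per run (default) instead of the pooled
#'   fraction.
#' @return named numeric vector of per-run accuracies (or a single pooled
#'   value when `by_run = FALSE`), with attribute `n_scored`.
#' @export
run_accuracy <- function(outputs, burn_in_windows = 1, by_run = TRUE) {
  keep <- outputs[outputs$window > burn_in_windows, , drop = FALSE]
  if (!nrow(keep)) stopf("no scored windows remain after burn-in")
  ok <- keep$predicted == keep$cue
  if (by_run) {
    parts <- split(ok, keep$run)
    acc <- vapply(parts, mean, 0)
    n <- vapply(parts, length, 0L)
  } else {
    acc <- mean(ok)
    n <- length(ok)
  }
  attr(acc, "n_scored") <- n
  acc
}

#' Initialize thermometer feedback state
#'
#' The display starts at the baseline level of 10 bars (half of a 20-bar
#' thermometer).
#'
#' @param bars initial bar count (default 10).
#' @param min_bars,max_bars display bounds (defaults 0 and 20).
#' @return an object of class `feedback_state`.
#' @export
thermometer_state <- function(bars = 10L, min_bars = 0L, max_bars = 20L) {
  stopifnot(min_bars <= bars, bars <= max_bars)
  structure(list(bars = as.integer(bars), baseline_bars = as.integer(bars),
                 min_bars = as.integer(min_bars), max_bars = as.integer(max_bars),
                 last_decision = NA_real_),
            class = "feedback_state")
}

#' @export
print.feedback_state <- function(x, ...) {
  cat(sprintf("Thermometer: %d bars (baseline %d, range %d-%d)\n",
              x$bars, x$baseline_bars, x$min_bars, x$max_bars))
  invisible(x)
}

#' Advance the thermometer by one feedback update
#'
#' One bar is added or removed per update according to the sign of the SVM
#' decision value interpreted relative to the cued class: during an "H" block
#' a positive decision adds a bar, during an "M" block a negative decision
#' does (both cues instruct the participant to drive the thermometer up).
#' `cue_aware = FALSE` follows the raw decision sign instead.  The count is
#' clipped at the display bounds.
#'
#' @param state a [thermometer_state()].
#' @param decision bias-corrected SVM decision value.
#' @param cue the active regulation cue, `"H"` or `"M"`.
#' @param cue_aware interpret the sign relative to the cue (default `TRUE`).
#' @return the updated `feedback_state`.
#' @export
update_thermometer <- function(state, decision, cue = c("H", "M"),
                               cue_aware = TRUE) {
  stopifnot(inherits(state, "feedback_state"))
  cue <- match.arg(cue)
  up <- if (cue_aware) (decision >= 0) == (cue == "H") else decision >= 0
  state$bars <- min(max(state$bars + if (up) 1L else -1L, state$min_bars),
                    state$max_bars)
  state$last_decision <- decision
  state
}

#' Replay a simulated run through the thermometer display
#'
#' @param outputs an [online_classify()] result.
#' @param state initial [thermometer_state()] (re-initialized at each run).
#' @param cue_aware see [update_thermometer()].
#' @return `outputs` with an added integer `bars` column.
#' @export
feedback_trace <- function(outputs, state = thermometer_state(),
                           cue_aware = TRUE) {
  bars <- integer(nrow(outputs))
  st <- state
  last_run <- NA
  for (i in seq_len(nrow(outputs))) {
    if (!identical(outputs$run[i], last_run)) { st <- state; last_run <- outputs$run[i] }
    st <- update_thermometer(st, outputs$decision[i], outputs$cue[i], cue_aware)
    bars[i] <- st$bars
  }
  outputs$bars <- bars
  outputs
}
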