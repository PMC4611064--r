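# Ground-truth synthetic EEG: band-limited Gaussian sources mixed into
# channels through smooth spatial profiles, plus white sensor noise.  Class
# structure enters through the variance of designated discriminative sources:
# a frontal source in the alpha band (6-12 Hz) is stronger during happy
# imagery (class "H") and a central source in the beta band (18-24 Hz) is
# stronger during motor imagery (class "M"), emulating the frontal-vs-central
# contrast the classifier is meant to recover.  Sources are band-limited with
# the package's own Chebyshev filters so generated spectra align with the
# analysis bands.

#' Configuration for the synthetic EEG generator
#'
#' The defaults emulate the recording conditions the pipeline targets:
#' 28 channels at 500 Hz, 5 s trials, 40 trials per class (80 per session).
#' Six band-limited unit-variance sources occupy the six analysis bands; two
#' of them are discriminative.
#'
#' @param n_channels channels (default 28).
#' @param fs sampling rate in Hz (default 500).
#' @param trial_s trial duration in seconds (default 5).
#' @param n_trials_per_class trials per class (default 40).
#' @param source_bands list of `c(low, high)` Hz per source; defaults to the
#'   six analysis bands.
#' @param source_peaks channel index where each source's spatial profile
#'   peaks; defaults spread the sources across the array with source 2
#'   "frontal" (channel 4) and source 4 "central" (channel 14).
#' @param source_width spatial profile standard deviation in channels
#'   (default 3).
#' @param source_amp_uv source standard deviation at its peak channel in muV
#'   (default 20).
#' @param discriminative data.frame with columns `source`, `class`
#'   (`"H"`/`"M"`) and `variance_ratio`: the source's variance is multiplied
#'   by `variance_ratio` in trials of that class.  Default: source 2 (frontal,
#'   6-12 Hz) ratio 4 in "H"; source 4 (central, 18-24 Hz) ratio 4 in "M".
#' @param noise_sigma white sensor noise standard deviation in muV
#'   (default 10).
#' @param subject_jitter_sd standard deviation of per-subject Gaussian jitter
#'   added to the mixing columns (default 0; set > 0 to make fusion and
#'   leave-one-subject-out tests meaningful).
#' @param seed RNG seed; all generated data are reproducible from it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 28, fs = 500, trial_s = 5,
                         n_trials_per_class = 40,
                         source_bands = NULL, source_peaks = NULL,
                         source_width = 3, source_amp_uv = 20,
                         discriminative = NULL, noise_sigma = 10,
                         subject_jitter_sd = 0, seed = 1) {
  if (is.null(source_bands))
    source_bands <- lapply(0:5, function(b) c(6 * b, 6 * (b + 1)))
  n_src <- length(source_bands)
  if (is.null(source_peaks))
    source_peaks <- round(seq(1, n_channels, length.out = n_src))
  if (length(source_peaks) != n_src) stopf("one peak channel per source required")
  if (anyDuplicated(source_peaks))
    stopf("source peaks collide: %d channels cannot host %d distinct sources",
          n_channels, n_src)
  if (is.null(discriminative)) {
    frontal <- if (n_src >= 2L) 2L else 1L
    central <- if (n_src >= 4L) 4L else n_src
    discriminative <- data.frame(source = c(frontal, central),
                                 class = c("H", "M"),
                                 variance_ratio = c(4, 4))
  }
  if (any(discriminative$variance_ratio <= 0)) stopf("variance_ratio must be positive")
  hi <- vapply(source_bands, max, 0)
  if (any(hi > fs / 2)) stopf("source band exceeds Nyquist frequency")
  structure(list(n_channels = n_channels, fs = fs, trial_s = trial_s,
                 n_trials_per_class = n_trials_per_class,
                 source_bands = source_bands, source_peaks = source_peaks,
                 source_width = source_width, source_amp_uv = source_amp_uv,
                 discriminative = discriminative, noise_sigma = noise_sigma,
                 subject_jitter_sd = subject_jitter_sd, seed = seed),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("Synthetic EEG config: %d channels at %g Hz, %d sources, %d+%d trials of %g s, seed %d\n",
              x$n_channels, x$fs, length(x$source_bands),
              x$n_trials_per_class, x$n_trials_per_class, x$trial_s, x$seed))
  invisible(x)
}

# smooth spatial mixing matrix (channels x sources), unit peak gain
synth_mixing <- function(cfg, jitter_seed = NULL) {
  A <- sapply(seq_along(cfg$source_peaks), function(j)
    exp(-((seq_len(cfg$n_channels) - cfg$source_peaks[j])^2) /
          (2 * cfg$source_width^2)))
  if (cfg$subject_jitter_sd > 0 && !is.null(jitter_seed)) {
    set.seed(jitter_seed)
    A <- A + matrix(stats::rnorm(length(A), 0, cfg$subject_jitter_sd),
                    nrow(A), ncol(A))
  }
  if (qr(A)$rank < ncol(A)) stopf("mixing matrix is rank-deficient")
  A
}

# band-limited unit-variance source signals: white noise through the package's
# own Chebyshev band filter, warm-up padding trimmed, rescaled to unit sd
synth_sources <- function(cfg, n_samples, pad_s = 1) {
  pad <- sec_to_sample(pad_s, cfg$fs)
  src <- matrix(0, length(cfg$source_bands), n_samples)
  for (j in seq_along(cfg$source_bands)) {
    b <- cfg$source_bands[[j]]
    flt <- design_band_filter(b[1L], b[2L], cfg$fs)
    x <- stats::rnorm(n_samples + pad)
    y <- sos_filter(flt, x)[-seq_len(pad)]
    src[j, ] <- y / stats::sd(y)
  }
  src
}

#' Generate one synthetic subject's trial set
#'
#' Each trial is `mixing %*% sources + noise`; discriminative sources have
#' their amplitude scaled by `sqrt(variance_ratio)` in trials of their class.
#' Labels are balanced and trials are generated in interleaved class order
#' then returned shuffled (reproducibly from the seed).
#'
#' @param cfg a [synth_config()].
#' @param subject subject index; offsets the seed substream and, when
#'   `subject_jitter_sd > 0`, the per-subject mixing jitter.
#' @return a [trial_set()] with attribute `ground_truth` (mixing matrix,
#'   discriminative table, config).
#' @export
generate_subject <- function(cfg, subject = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  A <- synth_mixing(cfg, jitter_seed = if (cfg$subject_jitter_sd > 0)
    sub_seed(cfg$seed, "mixjit", subject) else NULL)
  n <- 2L * cfg$n_trials_per_class
  n_samp <- sec_to_sample(cfg$trial_s, cfg$fs)
  set.seed(sub_seed(cfg$seed, "subject", subject))
  labels <- sample(rep(c("H", "M"), cfg$n_trials_per_class))
  trials <- array(0, c(n, cfg$n_channels, n_samp))
  gain <- matrix(1, length(cfg$source_bands), 2L,
                 dimnames = list(NULL, c("H", "M")))
  for (d in seq_len(nrow(cfg$discriminative)))
    gain[cfg$discriminative$source[d], cfg$discriminative$class[d]] <-
      sqrt(cfg$discriminative$variance_ratio[d])
  for (i in seq_len(n)) {
    src <- synth_sources(cfg, n_samp) * cfg$source_amp_uv * gain[, labels[i]]
    trials[i, , ] <- A %*% src +
      matrix(stats::rnorm(cfg$n_channels * n_samp, 0, cfg$noise_sigma),
             cfg$n_channels, n_samp)
  }
  ts <- trial_set(trials, factor(labels, levels = c("H", "M")), cfg$fs)
  attr(ts, "ground_truth") <- list(mixing = A, discriminative = cfg$discriminative,
                                   config = cfg, subject = subject)
  ts
}

#' Generate a continuous online-session stream
#'
#' Produces a continuous recording following an [online_schedule()].  Source
#' signals run continuously (so band-limited structure is unbroken across
#' block boundaries); during regulation blocks the cued class's
#' discriminative gain is applied per 1 s window with probability
#' `compliance`, otherwise (and during FIX/REST) neutral statistics hold.
#'
#' @param cfg a [synth_config()].
#' @param schedule a [paradigm_schedule()] (typically [online_schedule()]).
#' @param compliance probability per regulation window that the subject
#'   produces the cued class's statistics (default 1).
#' @param subject subject index for the seed substream / mixing jitter.
#' @param window_s modulation window in seconds (default 1, the feedback
#'   update interval).
#' @return a [continuous_eeg()] spanning the schedule, with the schedule's
#'   regulation blocks as events and attribute `ground_truth`.
#' @export
generate_online_stream <- function(cfg, schedule, compliance = 1, subject = 1L,
                                   window_s = 1) {
  stopifnot(inherits(cfg, "synth_config"), compliance >= 0, compliance <= 1)
  A <- synth_mixing(cfg, jitter_seed = if (cfg$subject_jitter_sd > 0)
    sub_seed(cfg$seed, "mixjit", subject) else NULL)
  fs <- cfg$fs
  span <- max(schedule$onset + schedule$duration)
  n_samp <- sec_to_sample(span, fs)
  set.seed(sub_seed(cfg$seed, "stream", subject))
  src <- synth_sources(cfg, n_samp) * cfg$source_amp_uv
  gain <- matrix(1, length(cfg$source_bands), 2L,
                 dimnames = list(NULL, c("H", "M")))
  for (d in seq_len(nrow(cfg$discriminative)))
    gain[cfg$discriminative$source[d], cfg$discriminative$class[d]] <-
      sqrt(cfg$discriminative$variance_ratio[d])
  wlen <- sec_to_sample(window_s, fs)
  mod <- matrix(1, nrow(src), n_samp)   # per-sample source gain
  reg <- schedule[schedule$label %in% c("H", "M"), , drop = FALSE]
  for (bi in seq_len(nrow(reg))) {
    a <- sec_to_sample(reg$onset[bi], fs)
    nw <- floor(reg$duration[bi] / window_s)
    for (w in seq_len(nw)) {
      if (stats::runif(1) <= compliance) {
        s0 <- a + (w - 1L) * wlen
        mod[, (s0 + 1L):(s0 + wlen)] <- gain[, reg$label[bi]]
      }
    }
  }
  samples <- A %*% (src * mod) +
    matrix(stats::rnorm(cfg$n_channels * n_samp, 0, cfg$noise_sigma),
           cfg$n_channels, n_samp)
  ev <- data.frame(onset = schedule$onset, duration = schedule$duration,
                   label = schedule$label)
  out <- continuous_eeg(samples, fs, events = ev)
  attr(out, "ground_truth") <- list(mixing = A, discriminative = cfg$discriminative,
                                    config = cfg, compliance = compliance)
  out
}
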