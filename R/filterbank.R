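# Band-pass filter bank: Chebyshev type-2 filters applied as cascaded
# second-order sections.  Direct polynomial forms of these narrow bands
# (relative bandwidth ~2% of fs) are numerically unstable, so filters are
# designed in zero-pole-gain form and factored into biquads.

#' Filter-bank specification
#'
#' Contiguous equal-width analysis bands spanning `[f_low, f_high]`.  The
#' defaults are six 6 Hz bands over 0-36 Hz, which cover delta through low
#' gamma and bracket the mu/beta rhythms that carry motor-imagery
#' desynchronization.  The lowest band, when it touches 0 Hz, is realized as a
#' low-pass preceded by per-trial DC removal (a band-pass with a 0 Hz edge is
#' ill-posed).
#'
#' @param f_low,f_high band range in Hz; `f_high - f_low` must divide evenly
#'   into `n_bands` widths and `f_high` must stay below the Nyquist frequency.
#' @param n_bands number of bands.
#' @param order Chebyshev type-2 prototype order (default 8).
#' @param stop_atten_db stopband attenuation in dB (default 30).
#' @param transition_hz transition bandwidth added outside each band edge when
#'   placing the stopband edges (default 2 Hz, so 6 Hz bands abut without
#'   gaps).
#' @param mode `"causal"` (default; single-pass, usable online) or
#'   `"zero_phase"` (forward-backward, offline only).
#' @return an object of class `filter_bank_spec`.
#' @export
filter_bank <- function(f_low = 0, f_high = 36, n_bands = 6, order = 8,
                        stop_atten_db = 30, transition_hz = 2,
                        mode = c("causal", "zero_phase")) {
  mode <- match.arg(mode)
  if (f_high <= f_low) stopf("f_high must exceed f_low")
  if (!is_count(n_bands)) stopf("n_bands must be a positive integer")
  width <- (f_high - f_low) / n_bands
  if (abs(width - round(width)) > 1e-9)
    stopf("range %g-%g Hz does not divide into %d equal-width (integer Hz) bands",
          f_low, f_high, n_bands)
  structure(list(f_low = f_low, f_high = f_high, n_bands = as.integer(n_bands),
                 order = order, stop_atten_db = stop_atten_db,
                 transition_hz = transition_hz, mode = mode),
            class = "filter_bank_spec")
}

#' @export
print.filter_bank_spec <- function(x, ...) {
  e <- band_edges(x)
  cat(sprintf("Filter bank: %d Chebyshev type-2 bands (%s Hz), order %d, %g dB stopband, %s\n",
              x$n_bands, paste(sprintf("%g-%g", e[, 1], e[, 2]), collapse = ", "),
              x$order, x$stop_atten_db, x$mode))
  invisible(x)
}

#' Band edges of a filter bank
#'
#' @param spec a [filter_bank()] specification.
#' @return an `n_bands` x 2 matrix of (low, high) edges in Hz.
#' @export
band_edges <- function(spec) {
  stopifnot(inherits(spec, "filter_bank_spec"))
  w <- (spec$f_high - spec$f_low) / spec$n_bands
  lo <- spec$f_low + w * (seq_len(spec$n_bands) - 1L)
  cbind(low = lo, high = lo + w)
}

# --- Chebyshev type-2 design in zero-pole-gain form ------------------------

# analog low-pass prototype with stopband edge at 1 rad/s
cheb2_prototype <- function(n, rs) {
  de <- 1 / sqrt(10^(0.1 * rs) - 1)
  mu <- asinh(1 / de) / n
  theta <- pi * (2 * seq_len(n) - 1) / (2 * n)
  p <- 1 / (-sinh(mu) * sin(theta) + 1i * cosh(mu) * cos(theta))
  ct <- cos(theta)
  z <- 1i / ct[abs(ct) > 1e-12]
  g <- Re(prod(-p) / prod(-z))
  signal::Zpg(zero = z, pole = p, gain = g)
}

# digital design; w in (0, 1] with 1 = Nyquist.  Low-pass when length(w) == 1.
cheb2_design <- function(n, rs, w) {
  zpg <- cheb2_prototype(n, rs)
  T <- 2
  wa <- 2 / T * tan(pi * w / T)
  s <- signal::sftrans(zpg, W = wa, stop = FALSE)
  signal::bilinear(s, T = T)
}

# pair poles/zeros into second-order sections: conjugate pairs, poles ordered
# by decreasing modulus, each matched with its nearest zero pair.
zpg_to_sos <- function(zpg) {
  conj_pairs <- function(v) {
    if (length(v) %% 2L == 1L) v <- c(v, 0)   # pad odd counts with z = 0
    used <- rep(FALSE, length(v))
    pairs <- list()
    for (i in order(-Mod(v))) {
      if (used[i]) next
      used[i] <- TRUE
      cand <- which(!used)
      j <- cand[which.min(abs(v[cand] - Conj(v[i])))]
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(v[i], v[j])
    }
    pairs
  }
  pp <- conj_pairs(zpg$pole)
  zz <- conj_pairs(zpg$zero)
  while (length(zz) < length(pp)) zz[[length(zz) + 1L]] <- c(0, 0)
  zdone <- rep(FALSE, length(zz))
  sos <- matrix(0, length(pp), 6L)
  for (s in seq_along(pp)) {
    d <- vapply(seq_along(zz), function(j)
      if (zdone[j]) Inf else abs(zz[[j]][1L] - pp[[s]][1L]), 0)
    j <- which.min(d)
    zdone[j] <- TRUE
    sos[s, ] <- c(Re(signal::poly(zz[[j]])), Re(signal::poly(pp[[s]])))
  }
  list(sos = sos, gain = zpg$gain)
}

# filter design for one analysis band; bands touching 0 Hz become a low-pass
design_band_filter <- function(lo, hi, fs, order = 8, rs = 30, trans = 2) {
  nyq <- fs / 2
  s_hi <- min(hi + trans, nyq * 0.999)
  if (lo <= 0) {
    zpg <- cheb2_design(order, rs, s_hi / nyq)
    dc_remove <- TRUE
  } else {
    s_lo <- max(lo - trans, 1e-3)
    zpg <- cheb2_design(order, rs, c(s_lo, s_hi) / nyq)
    dc_remove <- FALSE
  }
  c(zpg_to_sos(zpg), list(dc_remove = dc_remove))
}

# cascaded biquad filtering (compiled hot path); per-trial DC removal for the
# low-pass band happens before the cascade
sos_filter <- function(flt, x) {
  if (flt$dc_remove) x <- x - mean(x)
  .Call(C_sosfilt, flt$sos, flt$gain, as.numeric(x))
}

# compiled filterbank: per-band SOS cascades for a given sampling rate
build_filters <- function(spec, fs) {
  if (spec$f_high >= fs / 2)
    stopf("f_high = %g Hz must lie below Nyquist (%g Hz)", spec$f_high, fs / 2)
  e <- band_edges(spec)
  lapply(seq_len(spec$n_bands), function(b)
    design_band_filter(e[b, 1L], e[b, 2L], fs, spec$order,
                       spec$stop_atten_db, spec$transition_hz))
}

#' Apply a filter bank to one trial
#'
#' Decomposes a channels x samples trial into `n_bands` band-limited copies of
#' the same shape.  Causal mode filters forward only (what the online loop
#' uses); zero-phase mode filters forward and backward.
#'
#' @param trial numeric matrix, channels x samples.
#' @param spec a [filter_bank()].
#' @param fs sampling rate in Hz.
#' @return numeric array `n_bands x channels x samples`.
#' @export
apply_filter_bank <- function(trial, spec, fs) {
  trial <- as.matrix(trial)
  filters <- build_filters(spec, fs)
  min_len <- 3L * spec$order
  if (ncol(trial) < min_len)
    stopf("trial length %d below filter warm-up length %d", ncol(trial), min_len)
  out <- array(0, c(spec$n_bands, nrow(trial), ncol(trial)))
  for (b in seq_len(spec$n_bands)) {
    for (ch in seq_len(nrow(trial))) {
      y <- sos_filter(filters[[b]], trial[ch, ])
      if (spec$mode == "zero_phase")
        y <- rev(sos_filter(filters[[b]], rev(y)))
      out[b, ch, ] <- y
    }
  }
  out
}
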