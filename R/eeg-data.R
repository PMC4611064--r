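# Data model and I/O for continuous and epoched EEG.
#
# Amplitudes are microvolts (muV) throughout; EDF physical dimensions are
# converted on read.  Event onsets and durations are seconds; conversion to
# sample indices rounds half-up and trials are half-open windows
# [start, start + duration * fs) so adjacent blocks never overlap.

#' Continuous multichannel EEG recording
#'
#' A lightweight container for a continuous recording: a channels x time
#' amplitude matrix in microvolts, the sampling rate, ordered channel names and
#' a table of timed events.
#'
#' @param samples numeric matrix, channels x time, amplitudes in muV.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector, one name per channel; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param events data.frame with columns `onset`, `duration` (seconds) and
#'   `label`, or `NULL` for none.
#' @return an object of class `continuous_eeg`.
#' @export
continuous_eeg <- function(samples, fs, channel_names = NULL, events = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stopf("samples must be numeric")
  if (nrow(samples) < 2L) stopf("need at least 2 channels, got %d", nrow(samples))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stopf("fs must be a single positive number")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_names) != nrow(samples))
    stopf("channel_names length %d != channel count %d", length(channel_names), nrow(samples))
  if (is.null(events)) {
    events <- data.frame(onset = numeric(0), duration = numeric(0),
                         label = character(0), stringsAsFactors = FALSE)
  } else {
    events <- as.data.frame(events)
    need <- c("onset", "duration", "label")
    if (!all(need %in% names(events)))
      stopf("events must have columns %s", paste(need, collapse = ", "))
    events <- events[need]
    events$label <- as.character(events$label)
    if (is.unsorted(events$onset)) stopf("event onsets must be non-decreasing")
    len_s <- ncol(samples) / fs
    if (nrow(events) && any(events$onset + events$duration > len_s + 1e-9))
      stopf("event extends past end of recording (%.3f s)", len_s)
  }
  structure(list(samples = samples, fs = fs,
                 channel_names = as.character(channel_names), events = events),
            class = "continuous_eeg")
}

#' @export
print.continuous_eeg <- function(x, ...) {
  cat(sprintf("Continuous EEG: %d channels x %d samples (%.1f s at %g Hz), %d events\n",
              nrow(x$samples), ncol(x$samples), ncol(x$samples) / x$fs, x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Epoched two-class EEG trials
#'
#' Trials of equal length with a class label each.  Class A (first level of
#' `labels`, `"H"` = happy imagery by convention) maps to positive SVM decision
#' values everywhere in the package; class B (`"M"` = motor imagery) to
#' negative ones.
#'
#' @param trials numeric array, n_trials x channels x n_samples, in muV.
#' @param labels per-trial class labels (two-level factor or character).
#' @param fs sampling rate in Hz.
#' @param channel_names optional channel names.
#' @return an object of class `trial_set`.
#' @export
trial_set <- function(trials, labels, fs, channel_names = NULL) {
  if (length(dim(trials)) != 3L) stopf("trials must be a 3-d array: trials x channels x samples")
  n <- dim(trials)[1L]
  if (n < 1L) stopf("trial set must contain at least one trial")
  if (length(labels) != n) stopf("labels length %d != trial count %d", length(labels), n)
  # single-class sets are legal containers (class_covariance needs them);
  # two-class operations check class presence themselves
  if (!is.factor(labels)) labels <- factor(as.character(labels))
  if (nlevels(labels) > 2L)
    stopf("labels outside the two-class alphabet: %s",
          paste(levels(labels), collapse = ", "))
  if (anyNA(labels)) stopf("missing labels")
  if (!is.numeric(fs) || fs <= 0) stopf("fs must be positive")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dim(trials)[2L]))
  if (length(channel_names) != dim(trials)[2L]) stopf("channel_names length mismatch")
  structure(list(trials = trials, labels = labels, fs = fs,
                 channel_names = as.character(channel_names)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("Trial set: %d trials (%s) x %d channels x %d samples at %g Hz\n",
              dim(x$trials)[1L], paste(names(tab), tab, sep = "=", collapse = ", "),
              dim(x$trials)[2L], dim(x$trials)[3L], x$fs))
  invisible(x)
}

n_trials <- function(x) dim(x$trials)[1L]

# concatenate trial sets (same channels / fs / sample count)
bind_trial_sets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  d <- dim(sets[[1L]]$trials)
  for (s in sets[-1L]) {
    if (!all(dim(s$trials)[2:3] == d[2:3]) || s$fs != sets[[1L]]$fs)
      stopf("trial sets have incompatible shapes or sampling rates")
  }
  trials <- array(0, c(sum(vapply(sets, n_trials, 0L)), d[2L], d[3L]))
  labels <- character(0)
  at <- 0L
  for (s in sets) {
    trials[at + seq_len(n_trials(s)), , ] <- s$trials
    labels <- c(labels, as.character(s$labels))
    at <- at + n_trials(s)
  }
  trial_set(trials, as_class_factor(labels, levels(sets[[1L]]$labels)),
            sets[[1L]]$fs, sets[[1L]]$channel_names)
}

sec_to_sample <- function(t_s, fs) as.integer(floor(t_s * fs + 0.5))

#' Cut a continuous recording into labelled trials
#'
#' Extracts one trial per schedule block whose cue label is in `keep_labels`.
#' All kept blocks must have equal duration; each trial is the half-open sample
#' window `[onset * fs, (onset + duration) * fs)` (boundaries rounded half-up),
#' so adjacent blocks never share samples.
#'
#' @param cont a [continuous_eeg()].
#' @param schedule a [paradigm_schedule()] (or any data.frame with `onset`,
#'   `duration`, `label` columns in seconds).
#' @param keep_labels character vector of cue labels to keep,
#'   default `c("H", "M")` (the two regulation conditions).
#' @return a [trial_set()] with labels taken from the kept cue labels.
#' @export
epoch_trials <- function(cont, schedule, keep_labels = c("H", "M")) {
  stopifnot(inherits(cont, "continuous_eeg"))
  blocks <- as.data.frame(schedule)
  if (length(keep_labels) == 0L) stopf("keep_labels must name at least one cue")
  keep <- blocks[blocks$label %in% keep_labels, , drop = FALSE]
  if (nrow(keep) == 0L) stopf("no schedule blocks match keep_labels")
  if (length(unique(keep$duration)) != 1L)
    stopf("kept blocks have unequal durations: %s",
          paste(sort(unique(keep$duration)), collapse = ", "))
  fs <- cont$fs
  n_samp <- sec_to_sample(keep$duration[1L], fs)
  ends <- sec_to_sample(keep$onset, fs) + n_samp
  if (any(ends > ncol(cont$samples)))
    stopf("schedule block extends past end of recording")
  n <- nrow(keep)
  trials <- array(0, c(n, nrow(cont$samples), n_samp))
  for (i in seq_len(n)) {
    a <- sec_to_sample(keep$onset[i], fs)
    trials[i, , ] <- cont$samples[, (a + 1L):(a + n_samp), drop = FALSE]
  }
  lv <- keep_labels[keep_labels %in% unique(keep$label)]
  trial_set(trials, factor(keep$label, levels = lv), fs, cont$channel_names)
}

#' Read continuous EEG from disk
#'
#' Two formats are supported: European Data Format (`"edf"`, including EDF+C
#' annotations which become events) and a delimited text format
#' (`"delimited"`): a tab-separated channels x samples matrix, one row per
#' channel, with a JSON sidecar `<path>.json` carrying
#' `{fs, channel_names, events:[{onset, duration, label}]}`.
#'
#' @param path file path.
#' @param format `"edf"` or `"delimited"`; default guesses from the extension.
#' @return a [continuous_eeg()] with amplitudes in muV.
#' @export
read_eeg <- function(path, format = c("auto", "edf", "delimited")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  switch(format, edf = read_edf(path), delimited = read_delimited_eeg(path))
}

read_delimited_eeg <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stopf("missing JSON sidecar for delimited EEG: %s", sidecar)
  meta <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs)) stopf("sidecar lacks required key 'fs'")
  rows <- readLines(path)
  rows <- rows[nzchar(rows)]
  parsed <- lapply(strsplit(rows, "\t", fixed = TRUE), as.numeric)
  lens <- lengths(parsed)
  if (length(unique(lens)) != 1L)
    stopf("inconsistent sample counts across channel rows: %s",
          paste(unique(lens), collapse = ", "))
  samples <- do.call(rbind, parsed)
  if (anyNA(samples)) stopf("non-numeric values in delimited EEG")
  ev <- NULL
  if (!is.null(meta$events) && NROW(meta$events))
    ev <- as.data.frame(meta$events)
  if (!is.null(meta$channel_names) && length(meta$channel_names) != nrow(samples))
    stopf("sidecar channel_names length %d != %d data rows",
          length(meta$channel_names), nrow(samples))
  continuous_eeg(samples, meta$fs, meta$channel_names, ev)
}

#' Write continuous EEG in the delimited + sidecar format
#'
#' Inverse of `read_eeg(..., format = "delimited")`; used by the synthetic
#' generator CLI and for exchanging recordings as plain text.
#'
#' @param x a [continuous_eeg()].
#' @param path output path for the tab-separated matrix; the sidecar is written
#'   to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(x, path) {
  stopifnot(inherits(x, "continuous_eeg"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x$samples)))
    writeLines(paste(format(x$samples[i, ], digits = 17), collapse = "\t"), con)
  meta <- list(fs = x$fs, channel_names = x$channel_names,
               events = x$events)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

# --- minimal EDF / EDF+C reader -------------------------------------------
# 256-byte fixed header, 256 bytes per signal header field block, data records
# of 2-byte little-endian integers mapped to physical units per signal.  An
# "EDF Annotations" signal, if present, is parsed for timestamped annotation
# lists (TALs) and returned as events; it is excluded from the sample matrix.

edf_field <- function(raw, at, len) {
  trimws(rawToChar(raw[(at + 1L):(at + len)]))
}

read_edf <- function(path) {
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  if (length(raw) < 256L) stopf("not an EDF file (header truncated): %s", path)
  n_rec <- as.integer(edf_field(raw, 236, 8))
  rec_dur <- as.numeric(edf_field(raw, 244, 8))
  ns <- as.integer(edf_field(raw, 252, 4))
  if (is.na(ns) || ns < 1L) stopf("not an EDF file (bad signal count): %s", path)
  hdr_bytes <- as.integer(edf_field(raw, 184, 8))
  if (length(raw) < hdr_bytes) stopf("EDF header truncated: %s", path)
  # EDF signal-header layout (per-field blocks of ns entries):
  # label 16, transducer 80, dim 8, physmin 8, physmax 8, digmin 8, digmax 8,
  # prefilter 80, samples-per-record 8, reserved 32
  off <- c(label = 0, transducer = 16, dim = 96, physmin = 104, physmax = 112,
           digmin = 120, digmax = 128, prefilter = 136, spr = 216)
  get <- function(name, len) vapply(seq_len(ns), function(i)
    edf_field(raw, 256L + off[[name]] * ns + (i - 1L) * len, len), "")
  lab   <- get("label", 16L)
  dimu  <- get("dim", 8L)
  phmin <- as.numeric(get("physmin", 8L))
  phmax <- as.numeric(get("physmax", 8L))
  dgmin <- as.numeric(get("digmin", 8L))
  dgmax <- as.numeric(get("digmax", 8L))
  spr   <- as.integer(get("spr", 8L))
  if (anyNA(c(phmin, phmax, dgmin, dgmax, spr))) stopf("malformed EDF signal headers: %s", path)

  rec_len <- sum(spr) * 2L
  avail <- (length(raw) - hdr_bytes) %/% rec_len
  if (n_rec < 0L) n_rec <- avail
  if (avail < n_rec) stopf("EDF data truncated: %d of %d records present", avail, n_rec)

  is_annot <- lab == "EDF Annotations"
  data_idx <- which(!is_annot)
  if (length(data_idx) < 2L) stopf("EDF has fewer than 2 data signals")
  if (length(unique(spr[data_idx])) != 1L)
    stopf("EDF signals have differing sampling rates; not supported")
  fs <- spr[data_idx[1L]] / rec_dur

  ints <- readBin(raw[(hdr_bytes + 1L):(hdr_bytes + n_rec * rec_len)],
                  "integer", n = n_rec * rec_len / 2L, size = 2L,
                  endian = "little", signed = TRUE)
  samples <- matrix(0, length(data_idx), n_rec * spr[data_idx[1L]])
  annot_txt <- character(0)
  sig_off <- c(0L, cumsum(spr))
  for (r in seq_len(n_rec)) {
    base <- (r - 1L) * sum(spr)
    for (j in seq_along(data_idx)) {
      s <- data_idx[j]
      v <- ints[base + sig_off[s] + seq_len(spr[s])]
      # digital -> physical
      g <- (phmax[s] - phmin[s]) / (dgmax[s] - dgmin[s])
      phys <- phmin[s] + (v - dgmin[s]) * g
      if (dimu[s] %in% c("mV")) phys <- phys * 1000
      if (dimu[s] %in% c("V"))  phys <- phys * 1e6
      samples[j, (r - 1L) * spr[s] + seq_len(spr[s])] <- phys
    }
    for (s in which(is_annot)) {
      b <- raw[hdr_bytes + (r - 1L) * rec_len + sig_off[s] * 2L + seq_len(spr[s] * 2L)]
      annot_txt <- c(annot_txt, rawToChar(b[b != as.raw(0)]))
    }
  }
  events <- parse_edf_annotations(annot_txt)
  continuous_eeg(samples, fs, lab[data_idx], events)
}

# TALs: "+onset\x15duration\x14label\x14...\x14\x00"; duration may be absent.
parse_edf_annotations <- function(txt) {
  if (!length(txt)) return(NULL)
  tals <- unlist(strsplit(paste(txt, collapse = ""), "\x14\\+", perl = TRUE))
  out <- list()
  for (t in tals) {
    t <- sub("^\\+", "", t)
    parts <- strsplit(t, "\x14", fixed = TRUE)[[1L]]
    if (!length(parts)) next
    head <- strsplit(parts[1L], "\x15", fixed = TRUE)[[1L]]
    onset <- suppressWarnings(as.numeric(head[1L]))
    if (is.na(onset)) next
    dur <- if (length(head) > 1L) suppressWarnings(as.numeric(head[2L])) else 0
    labs <- parts[-1L]
    labs <- labs[nzchar(labs)]
    for (l in labs)
      out[[length(out) + 1L]] <- data.frame(onset = onset,
                                            duration = if (is.na(dur)) 0 else dur,
                                            label = l, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  ev <- do.call(rbind, out)
  ev[order(ev$onset), , drop = FALSE]
}
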