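# Independent byte-level EDF writer for fixtures: constructed directly from
# the published EDF header layout, deliberately not sharing code with the
# package's reader.

edf_pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) stop("EDF field overflow")
  paste0(x, strrep(" ", n - nchar(x)))
}

# samples: channels x time physical values; annotations: data.frame(onset,
# duration, label) or NULL.  One data record per second.
write_edf_fixture <- function(path, samples, fs, phys_range = c(-200, 200),
                              labels = NULL, annotations = NULL) {
  nch <- nrow(samples)
  n_rec <- ncol(samples) / fs
  stopifnot(n_rec == round(n_rec))
  if (is.null(labels)) labels <- paste0("EEG ", seq_len(nch))
  has_ann <- !is.null(annotations)
  ns <- nch + has_ann
  ann_spr <- 32L   # 64 bytes of annotation text per record

  header <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("X", 80),
    edf_pad("01.01.20", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad(if (has_ann) "EDF+C" else "", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4))
  field <- function(vals, width) paste(vapply(vals, edf_pad, "", n = width), collapse = "")
  sig_labels <- c(labels, if (has_ann) "EDF Annotations")
  header <- paste0(header,
    field(sig_labels, 16), field(rep("", ns), 80),
    field(c(rep("uV", nch), if (has_ann) ""), 8),
    field(c(rep(phys_range[1], nch), if (has_ann) -1), 8),
    field(c(rep(phys_range[2], nch), if (has_ann) 1), 8),
    field(c(rep(-32768, nch), if (has_ann) -32768), 8),
    field(c(rep(32767, nch), if (has_ann) 32767), 8),
    field(rep("", ns), 80),
    field(c(rep(fs, nch), if (has_ann) ann_spr), 8),
    field(rep("", ns), 32))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  to_dig <- function(v) {
    d <- round((v - phys_range[1]) / diff(phys_range) * 65535 - 32768)
    as.integer(pmin(pmax(d, -32768), 32767))
  }
  for (r in seq_len(n_rec)) {
    idx <- (r - 1) * fs + seq_len(fs)
    for (ch in seq_len(nch))
      writeBin(to_dig(samples[ch, idx]), con, size = 2, endian = "little")
    if (has_ann) {
      tal <- sprintf("+%d\x14\x14", r - 1)  # record timestamp
      in_rec <- which(annotations$onset >= r - 1 & annotations$onset < r)
      for (i in in_rec)
        tal <- paste0(tal, sprintf("+%g\x15%g\x14%s\x14", annotations$onset[i],
                                   annotations$duration[i], annotations$label[i]))
      buf <- charToRaw(tal)
      if (length(buf) > 2 * ann_spr) stop("annotation overflow")
      writeBin(c(buf, raw(2 * ann_spr - length(buf))), con)
    }
  }
  invisible(path)
}
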