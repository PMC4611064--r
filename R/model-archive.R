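# Stable single-file serialization for trained models: a JSON manifest
# followed by named little-endian float64 array blocks.
#
# Layout: magic "FBMA" | uint32 LE manifest byte length | manifest JSON
# (UTF-8) | concatenated float64 LE arrays in manifest order.  The manifest
# records each array's name, dimensions and value checksum (the plain sum of
# its elements), plus all scalar/string metadata needed to rebuild the model.
# Float64 blocks round-trip bit-exactly.

archive_magic <- charToRaw("FBMA")

model_to_archive <- function(model) {
  stopifnot(inherits(model, "fbcsp"))
  arrays <- list()
  put <- function(name, x) arrays[[name]] <<- x
  for (b in seq_along(model$csp)) {
    put(sprintf("csp%02d.P", b), model$csp[[b]]$P)
    put(sprintf("csp%02d.patterns", b), model$csp[[b]]$patterns)
    put(sprintf("csp%02d.eigvals_A", b), model$csp[[b]]$eigvals_A)
    put(sprintf("csp%02d.eigvals_B", b), model$csp[[b]]$eigvals_B)
  }
  put("selection.mi_scores", model$selection$mi_scores)
  put("selection.selected", as.numeric(model$selection$selected))
  put("svm.w", model$svm$w)
  put("svm.b", model$svm$b)
  if (!is.null(model$bias_offset)) put("bias_offset", model$bias_offset)
  if (!is.null(model$norm_params)) {
    inc <- model$included
    put("norm.bounds", t(vapply(inc, function(s)
      c(model$norm_params[[s]]$lo, model$norm_params[[s]]$hi), c(0, 0))))
    put("included", as.numeric(inc))
  }
  if (!is.null(model$subject_accuracy) && all(is.finite(model$subject_accuracy)))
    put("subject_accuracy", model$subject_accuracy)
  meta <- list(
    format = "fbcsp-model-archive", version = 1L,
    fused = inherits(model, "fbcsp_fused"),
    bands = model$bands[c("f_low", "f_high", "n_bands", "order",
                          "stop_atten_db", "transition_hz", "mode")],
    fs = model$fs, channel_names = model$channel_names,
    m = model$m, k = model$k, C = model$C,
    svm_C = model$svm$C, levels = model$levels,
    pair_completion = isTRUE(model$selection$pair_completion),
    clip_frac = model$clip_frac, threshold = model$threshold,
    n_train = model$n_train)
  list(manifest = meta, arrays = arrays)
}

#' Write a trained model to a single-file archive
#'
#' @param model a fitted [fbcsp()] or [fuse_subjects()] model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_model()] for the inverse; the round trip is bit-exact.
#' @export
write_model <- function(model, path) {
  ar <- model_to_archive(model)
  descr <- lapply(names(ar$arrays), function(nm) {
    x <- ar$arrays[[nm]]
    list(name = nm, dim = if (is.null(dim(x))) length(x) else dim(x),
         n = length(x), sum = sum(as.numeric(x)))
  })
  manifest <- c(ar$manifest, list(arrays = descr))
  mjson <- charToRaw(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(archive_magic, con)
  writeBin(length(mjson), con, size = 4L, endian = "little")
  writeBin(mjson, con)
  for (nm in names(ar$arrays))
    writeBin(as.numeric(ar$arrays[[nm]]), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a model archive back into a fitted model object
#'
#' Validates the magic number, manifest/array consistency, array sizes and
#' value checksums; truncated or inconsistent files raise a corruption error.
#'
#' @param path archive written by [write_model()].
#' @return the reconstructed `fbcsp` / `fbcsp_fused` model.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readBin(con, "raw", 4L), archive_magic))
    stopf("not a model archive (bad magic): %s", path)
  mlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (is.na(mlen) || mlen <= 0L || 8L + mlen > sz)
    stopf("corrupt model archive (manifest length): %s", path)
  manifest <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", mlen)),
                                 simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(manifest$format, "fbcsp-model-archive"))
    stopf("unrecognized archive format")
  arrays <- list()
  for (d in manifest$arrays) {
    need <- d$n
    vals <- readBin(con, "numeric", need, size = 8L, endian = "little")
    if (length(vals) != need)
      stopf("corrupt model archive: array '%s' truncated (%d of %d values)",
            d$name, length(vals), need)
    if (!isTRUE(all.equal(sum(vals), d$sum, tolerance = 1e-12)))
      stopf("corrupt model archive: checksum mismatch in array '%s'", d$name)
    if (length(d$dim) > 1L) dim(vals) <- unlist(d$dim)
    arrays[[d$name]] <- vals
  }
  archive_to_model(manifest, arrays)
}

archive_to_model <- function(meta, arrays) {
  need <- function(nm) {
    if (is.null(arrays[[nm]])) stopf("model archive manifest names missing array '%s'", nm)
    arrays[[nm]]
  }
  bands <- do.call(filter_bank, meta$bands)
  n_bands <- bands$n_bands
  csp <- lapply(seq_len(n_bands), function(b)
    structure(list(P = need(sprintf("csp%02d.P", b)),
                   patterns = need(sprintf("csp%02d.patterns", b)),
                   eigvals_A = need(sprintf("csp%02d.eigvals_A", b)),
                   eigvals_B = need(sprintf("csp%02d.eigvals_B", b))),
              class = "csp_model"))
  m <- meta$m
  column_ids <- data.frame(band = rep(seq_len(n_bands), each = 2L * m),
                           filter = rep(seq_len(2L * m), n_bands))
  selection <- structure(list(mi_scores = need("selection.mi_scores"),
                              selected = as.integer(need("selection.selected")),
                              k = meta$k, column_ids = column_ids,
                              pair_completion = isTRUE(meta$pair_completion)),
                         class = "feature_selection")
  feat_names <- paste0("b", rep(seq_len(n_bands), each = 2L * m),
                       ".f", rep(seq_len(2L * m), n_bands))
  w <- need("svm.w")
  names(w) <- feat_names[selection$selected]
  svm <- structure(list(w = w, b = as.numeric(need("svm.b")),
                        C = meta$svm_C, levels = unlist(meta$levels)),
                   class = "svm_model")
  model <- structure(list(bands = bands, fs = meta$fs,
                          channel_names = unlist(meta$channel_names),
                          m = m, k = meta$k, C = meta$C, csp = csp,
                          selection = selection, svm = svm,
                          column_ids = column_ids,
                          features = matrix(numeric(0), 0L, n_bands * 2L * m,
                                            dimnames = list(NULL, feat_names)),
                          levels = unlist(meta$levels),
                          n_train = meta$n_train, call = NULL),
                     class = "fbcsp")
  if (isTRUE(meta$fused)) {
    inc <- as.integer(need("included"))
    bounds <- need("norm.bounds")
    if (is.null(dim(bounds))) dim(bounds) <- c(1L, 2L)
    np <- vector("list", max(inc))
    for (i in seq_along(inc))
      np[[inc[i]]] <- list(lo = bounds[i, 1L], hi = bounds[i, 2L],
                           clip_frac = meta$clip_frac)
    model$norm_params <- np
    model$included <- inc
    model$clip_frac <- meta$clip_frac
    model$threshold <- meta$threshold
    model$bias_offset <- as.numeric(need("bias_offset"))
    if (!is.null(arrays[["subject_accuracy"]]))
      model$subject_accuracy <- arrays[["subject_accuracy"]]
    class(model) <- c("fbcsp_fused", class(model))
  }
  model
}
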