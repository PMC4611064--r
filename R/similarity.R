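# Similarity between a subject's per-run CSP patterns and the fused model's,
# and regression of similarity against run accuracy.
#
# Pattern sign is arbitrary, so absolute values are taken and each vector is
# scaled to [0, 1] before comparison; similarity is then invariant to positive
# rescaling of either pattern.

#' Extract the two most prominent CSP patterns from one run
#'
#' Fits a CSP decomposition to the run's broadband data (band-pass over the
#' full filter-bank range) and returns the spatial patterns of the first and
#' last components: the "H" pattern maximizes class-A variance, the "M"
#' pattern class-B variance.
#'
#' @param run_data a [trial_set()] containing both classes.
#' @param bands a [filter_bank()]; only its overall range is used for the
#'   broadband filter.
#' @return channels x 2 matrix with columns `"H"` and `"M"`.
#' @export
extract_run_csp <- function(run_data, bands = filter_bank()) {
  stopifnot(inherits(run_data, "trial_set"))
  if (nlevels(droplevels(run_data$labels)) < 2L)
    stopf("both classes must be present in the run")
  flt <- design_band_filter(bands$f_low, bands$f_high, run_data$fs,
                            bands$order, bands$stop_atten_db, bands$transition_hz)
  C <- dim(run_data$trials)[2L]
  n <- n_trials(run_data)
  covs <- array(0, c(n, 1L, C, C))
  for (i in seq_len(n)) {
    E <- run_data$trials[i, , ]
    Eb <- t(vapply(seq_len(C), function(ch) sos_filter(flt, E[ch, ]),
                   numeric(ncol(E))))
    covs[i, 1L, , ] <- trial_covariance(Eb)
  }
  lv <- levels(run_data$labels)
  S_A <- colMeans(covs[run_data$labels == lv[1L], 1L, , , drop = FALSE], dims = 2L)
  S_B <- colMeans(covs[run_data$labels == lv[2L], 1L, , , drop = FALSE], dims = 2L)
  mod <- fit_csp(S_A, S_B)
  out <- cbind(H = mod$patterns[, 1L], M = mod$patterns[, C])
  rownames(out) <- run_data$channel_names
  out
}

#' Model-side CSP patterns for similarity analysis
#'
#' The fused model's most prominent patterns, taken from its broadband
#' training data representation: the first pattern of the first selected
#' band's CSP for each condition is a reasonable proxy, but for comparability
#' with [extract_run_csp()] the patterns are recomputed from pooled band
#' covariances when trial data are supplied.
#'
#' @param model a fitted [fbcsp()] model.
#' @return channels x 2 matrix with columns `"H"` and `"M"`: the first and
#'   last pattern columns averaged (absolute values) over the model's bands,
#'   weighted by each band's selected-feature count.
#' @export
model_csp_patterns <- function(model) {
  stopifnot(inherits(model, "fbcsp"))
  C <- length(model$channel_names)
  sel_bands <- model$selection$column_ids$band[model$selection$selected]
  w <- tabulate(sel_bands, nbins = model$bands$n_bands)
  if (all(w == 0)) w <- rep(1, model$bands$n_bands)
  H <- M <- numeric(C)
  for (b in seq_len(model$bands$n_bands)) {
    H <- H + w[b] * abs(model$csp[[b]]$patterns[, 1L])
    M <- M + w[b] * abs(model$csp[[b]]$patterns[, C])
  }
  cbind(H = H / sum(w), M = M / sum(w))
}

scale01 <- function(v) {
  v <- abs(v)
  rng <- range(v)
  if (diff(rng) < .Machine$double.eps) return(rep(0, length(v)))
  (v - rng[1L]) / diff(rng)
}

#' Similarity index between two CSP pattern vectors
#'
#' Both vectors are reduced to absolute values and scaled to `[0, 1]` first.
#' `"correlation"` is the Pearson coefficient, `"euclidean"` the L2 distance
#' (0 for identical patterns), `"mutual_information"` a binned MI in bits
#' (`bins` equal-width bins over `[0, 1]`).
#'
#' @param a,b equal-length pattern vectors.
#' @param method one of `"correlation"`, `"mutual_information"`,
#'   `"euclidean"`.
#' @param bins histogram bins for the MI method (default 16).
#' @return scalar similarity index.
#' @export
csp_similarity <- function(a, b,
                           method = c("correlation", "mutual_information", "euclidean"),
                           bins = 16) {
  method <- match.arg(method)
  if (length(a) != length(b)) stopf("pattern lengths differ")
  sa <- scale01(a); sb <- scale01(b)
  if (method == "correlation") {
    if (stats::sd(sa) == 0 || stats::sd(sb) == 0) {
      warnf("zero-variance pattern: correlation undefined")
      return(NA_real_)
    }
    return(stats::cor(sa, sb))
  }
  if (method == "euclidean") return(sqrt(sum((sa - sb)^2)))
  # binned mutual information
  cut01 <- function(v) pmin(pmax(ceiling(v * bins), 1L), bins)
  joint <- table(factor(cut01(sa), levels = seq_len(bins)),
                 factor(cut01(sb), levels = seq_len(bins))) / length(sa)
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in seq_len(bins)) for (j in seq_len(bins))
    if (joint[i, j] > 0)
      mi <- mi + joint[i, j] * log2(joint[i, j] / (px[i] * py[j]))
  mi
}

#' Ordinary least-squares regression of accuracy on similarity
#'
#' @param similarities per-run similarity indices (>= 3 points).
#' @param accuracies matching per-run classification accuracies.
#' @return named vector `c(slope, intercept, r_squared)`;
#'   `r_squared = 1 - SSE/SST`, `NA` with a warning for a constant predictor.
#' @export
similarity_accuracy_regression <- function(similarities, accuracies) {
  if (length(similarities) != length(accuracies)) stopf("length mismatch")
  if (length(similarities) < 3L) stopf("need at least 3 paired points")
  if (stats::sd(similarities) == 0) {
    warnf("constant predictor: regression undefined")
    return(c(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_))
  }
  fit <- stats::lm(accuracies ~ similarities)
  co <- stats::coef(fit)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((accuracies - mean(accuracies))^2)
  c(slope = unname(co[2L]), intercept = unname(co[1L]),
    r_squared = if (sst > 0) 1 - sse / sst else NA_real_)
}

#' Per-run similarity report against a fused model
#'
#' For each run, extracts the run's most prominent CSP patterns, computes
#' their similarity with the model's patterns per condition and method, and
#' regresses the supplied run accuracies on the similarity indices.
#'
#' @param runs list of per-run [trial_set()] objects.
#' @param model a fitted [fbcsp()]/[fuse_subjects()] model.
#' @param accuracies per-run classification accuracies (same length as
#'   `runs`); regression is skipped when missing.
#' @param methods similarity methods to apply.
#' @return an object of class `similarity_report`: `per_run` data.frame
#'   (run, condition, method, similarity) and `regression` data.frame
#'   (condition, method, slope, intercept, r_squared).
#' @export
similarity_report <- function(runs, model, accuracies = NULL,
                              methods = c("correlation", "mutual_information",
                                          "euclidean")) {
  ref <- model_csp_patterns(model)
  rows <- list()
  for (r in seq_along(runs)) {
    pats <- extract_run_csp(runs[[r]], model$bands)
    for (cond in c("H", "M"))
      for (mth in methods)
        rows[[length(rows) + 1L]] <- data.frame(
          run = r, condition = cond, method = mth,
          similarity = csp_similarity(pats[, cond], ref[, cond], mth),
          stringsAsFactors = FALSE)
  }
  per_run <- do.call(rbind, rows)
  regression <- NULL
  if (!is.null(accuracies)) {
    regs <- list()
    for (cond in c("H", "M"))
      for (mth in methods) {
        s <- per_run$similarity[per_run$condition == cond & per_run$method == mth]
        fitv <- similarity_accuracy_regression(s, accuracies)
        regs[[length(regs) + 1L]] <- data.frame(
          condition = cond, method = mth, slope = fitv["slope"],
          intercept = fitv["intercept"], r_squared = fitv["r_squared"],
          row.names = NULL, stringsAsFactors = FALSE)
      }
    regression <- do.call(rbind, regs)
  }
  structure(list(per_run = per_run, regression = regression),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("Similarity report: %d runs x %d method/condition pairs\n",
              length(unique(x$per_run$run)),
              nrow(unique(x$per_run[c("condition", "method")]))))
  if (!is.null(x$regression)) {
    cat("Accuracy ~ similarity regression:\n")
    print(x$regression, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
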