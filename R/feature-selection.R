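# Mutual-information scoring of CSP features against class labels, and top-k
# selection across all (band, filter) feature columns.
#
# I(F, w) = H(w) - H(w|F) with p(F|w) estimated by a per-class univariate
# Gaussian kernel density (normal-reference bandwidth 1.06 * sigma * n^-1/5),
# Bayes' rule for p(w|F), and H(w|F) averaged over the empirical sample.
# Two classes bound the score at 1 bit.

#' Empirical class entropy in bits
#'
#' @param labels per-trial class labels.
#' @return `-sum(p * log2(p))` over the empirical class frequencies.
#' @export
class_entropy <- function(labels) {
  if (!length(labels)) stopf("empty labels")
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between one feature column and the class labels
#'
#' @param column numeric per-trial feature values.
#' @param labels per-trial class labels (two classes).
#' @param bandwidth_rule multiplier in the normal-reference kernel bandwidth
#'   `rule * sd * n^(-1/5)` (default 1.06).
#' @return mutual information in bits, clipped to `[0, H(labels)]`; a constant
#'   column scores 0.
#' @export
mutual_information <- function(column, labels, bandwidth_rule = 1.06) {
  labels <- as_class_factor(labels)
  if (length(column) != length(labels)) stopf("feature/label length mismatch")
  if (any(table(labels) < 2L)) stopf("need at least 2 trials per class")
  Hw <- class_entropy(labels)
  if (stats::sd(column) < .Machine$double.eps) return(0)
  lv <- levels(labels)
  pw <- as.numeric(table(labels)[lv]) / length(labels)
  # per-class KDE evaluated at every training point
  dens <- sapply(lv, function(cl) {
    xs <- column[labels == cl]
    h <- bandwidth_rule * stats::sd(xs) * length(xs)^(-1 / 5)
    if (h < .Machine$double.eps) h <- .Machine$double.eps^0.5 * (1 + abs(mean(xs)))
    rowMeans(outer(column, xs, function(a, b) stats::dnorm(a, b, h)))
  })
  joint <- sweep(dens, 2L, pw, `*`)          # p(F|w) p(w)
  pf <- pmax(rowSums(joint), .Machine$double.xmin)
  post <- joint / pf                         # p(w|F) by Bayes
  hterm <- -rowSums(ifelse(post > 0, post * log2(post), 0))
  HwF <- mean(hterm)
  min(max(Hw - HwF, 0), Hw)
}

#' Score all feature columns and select the k most informative
#'
#' Columns are ranked by descending mutual information with the class labels;
#' ties break deterministically on ascending column order (band index, then
#' filter index).  Optional pair completion additionally pulls in the mirror
#' CSP filter of each selected column (the filter from the opposite end of the
#' eigenvalue spectrum in the same band), as in the original filter-bank CSP
#' selection; it is off by default.
#'
#' @param features n_trials x n_columns feature matrix.
#' @param labels per-trial class labels.
#' @param k number of columns to select (default 4).
#' @param column_ids optional data.frame with per-column `band` and `filter`
#'   indices (filter indices `1..2m` per band); required for pair completion.
#' @param pair_completion also select each chosen column's mirror filter
#'   (default `FALSE`).
#' @param bandwidth_rule passed to [mutual_information()].
#' @return an object of class `feature_selection`: `mi_scores` (bits, per
#'   column), `selected` (column indices in descending-score order) and
#'   `column_ids`.
#' @export
select_features <- function(features, labels, k = 4, column_ids = NULL,
                            pair_completion = FALSE, bandwidth_rule = 1.06) {
  features <- as.matrix(features)
  if (k > ncol(features))
    stopf("k = %d exceeds the %d available feature columns", k, ncol(features))
  mi <- vapply(seq_len(ncol(features)), function(j)
    mutual_information(features[, j], labels, bandwidth_rule), 0)
  ord <- order(-mi, seq_along(mi))
  if (!pair_completion) {
    sel <- ord[seq_len(k)]
  } else {
    if (is.null(column_ids)) stopf("pair_completion requires column_ids")
    two_m <- max(column_ids$filter)
    mirror <- function(j) {
      which(column_ids$band == column_ids$band[j] &
              column_ids$filter == two_m + 1L - column_ids$filter[j])
    }
    sel <- integer(0)
    for (j in ord) {
      if (length(sel) >= k) break
      if (!(j %in% sel)) sel <- c(sel, j, setdiff(mirror(j), c(sel, j)))
    }
    sel <- sel[seq_len(k)]
  }
  structure(list(mi_scores = mi, selected = sel, k = k,
                 column_ids = column_ids, pair_completion = pair_completion),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("Feature selection: %d of %d columns by mutual information\n",
              x$k, length(x$mi_scores)))
  for (j in x$selected) {
    id <- if (!is.null(x$column_ids))
      sprintf(" (band %d, filter %d)", x$column_ids$band[j], x$column_ids$filter[j])
    else ""
    cat(sprintf("  column %d%s: %.3f bits\n", j, id, x$mi_scores[j]))
  }
  invisible(x)
}
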