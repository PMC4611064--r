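# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a global seed
#'
#' Every stage that consumes randomness draws its own seed from the global one
#' through this rule, so adding a stage never perturbs the random stream of an
#' earlier stage.  The result is always a valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name (e.g. `"synthetic"`, `"cv"`).
#' @param index optional integer index for repeated stages (subject number,
#'   repetition number).
#' @return an integer in `[0, 2^31 - 1]`.
#' @export
sub_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  ((as.numeric(seed) %% 2^31) * 7919 + h * 104729 + as.numeric(index) * 65537) %% 2147483647
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x > 0

# labels coerced to a two-level factor; first level is class A ("H" / happy by
# convention), which the SVM maps to positive decision values.
as_class_factor <- function(labels, levels = NULL) {
  if (is.null(levels)) {
    levels <- if (is.factor(labels)) base::levels(labels) else sort(unique(as.character(labels)))
  }
  if (length(levels) != 2L)
    stopf("expected exactly 2 classes, found %d (%s)",
          length(levels), paste(levels, collapse = ", "))
  f <- factor(as.character(labels), levels = levels)
  if (anyNA(f)) stopf("labels outside the two-class alphabet {%s}", paste(levels, collapse = ", "))
  f
}
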