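# Shared synthetic fixtures.  Small configurations keep unit tests fast; the
# acceptance tests use the full-scale study conditions.  Expensive fixtures
# are memoized so multiple test files can share them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small but realistic: 12 channels, 2 s trials, one strong frontal alpha
# source (ratio 8) for class H and a central beta source for class M
small_cfg <- function(seed = 11, ratio = 8, n_per_class = 15, ...) {
  synth_config(n_channels = 12, trial_s = 2, n_trials_per_class = n_per_class,
               discriminative = data.frame(source = c(2L, 4L),
                                           class = c("H", "M"),
                                           variance_ratio = ratio),
               seed = seed, ...)
}

small_subject <- function() memo("small_subject", generate_subject(small_cfg()))

small_covs <- function() memo("small_covs",
                              fbcsp:::band_covariances(small_subject(), filter_bank()))

small_fit <- function() memo("small_fit", fbcsp(small_subject()))

# null data: no class information at all
null_subject <- function() memo("null_subject", {
  cfg <- small_cfg(seed = 21, ratio = 1)
  generate_subject(cfg)
})

random_spd <- function(n, seed) {
  set.seed(seed)
  M <- matrix(rnorm(n * n), n)
  S <- crossprod(M) + diag(n) * 0.1
  S / sum(diag(S))
}
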