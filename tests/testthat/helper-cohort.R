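# Shared fixtures, computed once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Default-profile cohort (20 per group, 1800 beats) and its feature table;
# used by the screening, classification and pipeline tests.
fixture_features <- function() {
  if (is.null(.fixture_env$features)) {
    coh <- generate_cohort(default_profiles(), n_per_group = 20,
                           n_beats = 1800, seed = 42)
    .fixture_env$features <- cohort_features(coh)
  }
  .fixture_env$features
}

fixture_small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_cohort(default_profiles(),
                                          n_per_group = 3, n_beats = 400,
                                          seed = 7)
  }
  .fixture_env$small
}

# Separable two-class toy features for classifier tests
blob_data <- function(n = 20, gap = 3, seed = 11) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             matrix(rnorm(2 * n, mean = gap), n, 2))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = factor(rep(c("A", "B"), each = n)))
}
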