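# Shared fixtures: all randomness is locally seeded so tests are
# order-independent.

random_image <- function(n = 16L, m = n, seed = NULL, levels = 256L) {
  if (!is.null(seed)) set.seed(seed)
  gray_image(matrix(sample(0:(levels - 1L), n * m, replace = TRUE), n, m),
             levels)
}

random_mask <- function(n = 8L, m = n, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(n * m) < p, n, m)
}

stub_mean_scorer <- function() {
  scorer_spec("stub", fun = function(img) mean(as.numeric(img)))
}
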