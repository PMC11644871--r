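# ---- local Gaussian filtering --------------------------------------------

# Normalized 1-D Gaussian kernel of length k (default 7, sigma = 7/6), the
# window conventionally used for MSCN computation.
gauss_kernel1d <- function(k = 7L, sigma = 7 / 6) {
  half <- (k - 1) / 2
  x <- seq(-half, half)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# Separable 2-D Gaussian filter with symmetric (reflect) border padding.
gauss_filter <- function(x, k = 7L, sigma = 7 / 6) {
  w <- gauss_kernel1d(k, sigma)
  half <- (k - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  if (n < k || m < k) stop("image is smaller than the filter window")
  ridx <- c(rev(seq_len(half)), seq_len(n), n + 1L - seq_len(half))
  cidx <- c(rev(seq_len(half)), seq_len(m), m + 1L - seq_len(half))
  xp <- x[ridx, cidx, drop = FALSE]
  # filter rows
  acc <- matrix(0, n, ncol(xp))
  for (t in seq_len(k)) acc <- acc + w[t] * xp[(t - 1L) + seq_len(n), , drop = FALSE]
  out <- matrix(0, n, m)
  for (t in seq_len(k)) out <- out + w[t] * acc[, (t - 1L) + seq_len(m), drop = FALSE]
  out
}

#' Mean-subtracted contrast-normalized (MSCN) coefficients
#'
#' Locally normalizes luminance: `(I - mu) / (sigma + C)` with `mu` and
#' `sigma` the Gaussian-weighted local mean and standard deviation (7x7
#' window, `sigma_w = 7/6`, symmetric border padding) and `C = 1` on the
#' 0-255 intensity scale. MSCN statistics of natural images are close to a
#' unit-variance generalized Gaussian; distortions shift them, which is
#' what the BRISQUE features measure.
#'
#' @param img A [gray_image()] at least as large as the 7x7 window.
#' @return Real matrix of the same shape (all zeros for a constant image).
#' @export
mscn <- function(img) {
  img <- as_gray_image(img)
  x <- matrix(as.numeric(img), nrow(img), ncol(img))
  mscn_of(x)
}

mscn_of <- function(x) {
  mu <- gauss_filter(x)
  sigma <- sqrt(pmax(gauss_filter(x * x) - mu * mu, 0))
  num <- x - mu
  # flush float-rounding residue of the normalized kernel (locally
  # constant regions must give exactly zero)
  num[abs(num) < 1e-9 * (1 + max(abs(x)))] <- 0
  num / (sigma + 1)
}

# ---- generalized Gaussian fitting ----------------------------------------

# Lookup table for the moment-matching shape estimate: the ratio
# r(alpha) = gamma(2/a)^2 / (gamma(1/a) * gamma(3/a)) is monotone in alpha.
ggd_alpha_grid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      a <- seq(0.2, 10, by = 0.001)
      r <- exp(2 * lgamma(2 / a) - lgamma(1 / a) - lgamma(3 / a))
      cache <<- list(alpha = a, r = r)
    }
    cache
  }
})

ggd_alpha_lookup <- function(rho) {
  g <- ggd_alpha_grid()
  g$alpha[which.min((g$r - rho)^2)]
}

#' Fit a symmetric generalized Gaussian by moment matching
#'
#' @param x Numeric samples (at least 100, not all identical).
#' @return List with `alpha` (shape) and `sigma` (scale,
#'   `sqrt(mean(x^2))`). Gaussian data give `alpha ~ 2`, Laplacian
#'   `alpha ~ 1`.
#' @export
fit_ggd <- function(x) {
  if (length(x) < 100L) stop("need at least 100 samples")
  m2 <- mean(x^2)
  if (m2 == 0) stop("degenerate samples (all zero)")
  rho <- mean(abs(x))^2 / m2
  list(alpha = ggd_alpha_lookup(rho), sigma = sqrt(m2))
}

#' Fit an asymmetric generalized Gaussian by moment matching
#'
#' Standard BRISQUE estimator for the pairwise-product coefficients: the
#' left/right scales come from one-sided second moments and the shape from
#' the generalized-Gaussian moment ratio corrected for asymmetry.
#'
#' @param x Numeric samples (at least 100, not all identical).
#' @return List with `alpha`, `sigma_left`, `sigma_right` and `eta` (the
#'   AGGD mean feature `(sigma_right - sigma_left) *
#'   gamma(2/alpha)/gamma(1/alpha)`).
#' @export
fit_aggd <- function(x) {
  if (length(x) < 100L) stop("need at least 100 samples")
  if (all(x == x[1L])) stop("degenerate samples (all identical)")
  neg <- x[x < 0]; pos <- x[x > 0]
  sigma_l <- if (length(neg)) sqrt(mean(neg^2)) else 0
  sigma_r <- if (length(pos)) sqrt(mean(pos^2)) else 0
  if (sigma_l == 0 || sigma_r == 0)
    stop("degenerate samples (one-sided)")
  gam <- sigma_l / sigma_r
  rhat <- mean(abs(x))^2 / mean(x^2)
  Rhat <- rhat * (gam^3 + 1) * (gam + 1) / (gam^2 + 1)^2
  alpha <- ggd_alpha_lookup(Rhat)
  eta <- (sigma_r - sigma_l) * exp(lgamma(2 / alpha) - lgamma(1 / alpha))
  list(alpha = alpha, sigma_left = sigma_l, sigma_right = sigma_r, eta = eta)
}

# ---- BRISQUE features ----------------------------------------------------

# Half-scale reduction by 2x2 block averaging.
halve_image <- function(x) {
  n <- 2L * (nrow(x) %/% 2L); m <- 2L * (ncol(x) %/% 2L)
  x <- x[seq_len(n), seq_len(m), drop = FALSE]
  0.25 * (x[seq(1, n, 2), seq(1, m, 2)] + x[seq(2, n, 2), seq(1, m, 2)] +
          x[seq(1, n, 2), seq(2, m, 2)] + x[seq(2, n, 2), seq(2, m, 2)])
}

brisque_scale_features <- function(x) {
  z <- mscn_of(x)
  if (all(z == 0)) {
    # constant (or numerically constant) input: sentinel features
    return(c(2, 0, rep(c(2, 0, 0, 0), 4)))
  }
  g <- fit_ggd(as.vector(z))
  feats <- c(g$alpha, g$sigma^2)
  n <- nrow(z); m <- ncol(z)
  pairs <- list(
    z[, -m] * z[, -1L],                    # horizontal
    z[-n, ] * z[-1L, ],                    # vertical
    z[-n, -m] * z[-1L, -1L],               # main diagonal
    z[-n, -1L] * z[-1L, -m]                # anti-diagonal
  )
  for (p in pairs) {
    p <- as.vector(p)
    if (all(p == 0)) {
      feats <- c(feats, 2, 0, 0, 0)
    } else {
      a <- fit_aggd(p)
      feats <- c(feats, a$alpha, a$eta, a$sigma_left^2, a$sigma_right^2)
    }
  }
  feats
}

#' BRISQUE natural-scene-statistics features
#'
#' Computes the standard 36-element BRISQUE feature vector: at each of two
#' scales (original and 2x2-block-averaged half size), 2 generalized
#' Gaussian parameters of the MSCN field plus 4 asymmetric-generalized-
#' Gaussian parameters for each of 4 orientations of pairwise MSCN
#' products. Degenerate (constant) inputs yield sentinel values
#' (`alpha = 2`, scales 0) rather than NaN.
#'
#' @param img A [gray_image()] of size at least 32 x 32.
#' @return Numeric vector of exactly 36 finite values.
#' @export
brisque_features <- function(img) {
  img <- as_gray_image(img)
  if (nrow(img) < 32L || ncol(img) < 32L)
    stop("image must be at least 32 x 32")
  x <- matrix(as.numeric(img), nrow(img), ncol(img))
  feats <- c(brisque_scale_features(x), brisque_scale_features(halve_image(x)))
  stopifnot(length(feats) == 36L, all(is.finite(feats)))
  feats
}

# ---- scorers -------------------------------------------------------------

#' Specify a no-reference quality scorer
#'
#' Three kinds are supported. `"fallback"` (default) scores an image by a
#' Mahalanobis-style distance (diagonal covariance) of its BRISQUE features
#' to a feature Gaussian fitted to clean synthetic CT-like phantoms (lower
#' = more natural); it needs no external model. `"reference-brisque"`
#' evaluates a regression model loaded from a JSON coefficients file (see
#' Details). `"stub"` wraps a caller-supplied deterministic function of the
#' image, used to make optimizer behaviour exactly checkable in tests.
#'
#' In every case lower scores mean higher quality.
#'
#' @details The `reference-brisque` coefficients file is JSON with fields
#' `kind` (`"linear"`), `intercept` (scalar) and `weights` (36 numbers);
#' the score is `intercept + weights . features`. Feature normalization, if
#' any, must be baked into the weights.
#'
#' @param kind One of `"fallback"`, `"reference-brisque"`, `"stub"`.
#' @param model_path Path to the coefficients JSON (reference-brisque only).
#' @param fun Scoring function `function(img) -> numeric` (stub only).
#' @return A list of class `scorer_spec`.
#' @export
scorer_spec <- function(kind = c("fallback", "reference-brisque", "stub"),
                        model_path = NULL, fun = NULL) {
  kind <- match.arg(kind)
  if (kind == "reference-brisque") {
    if (is.null(model_path))
      stop("reference-brisque requires a coefficients file (model_path)")
    if (!file.exists(model_path))
      stop("coefficients file not found: ", model_path)
  }
  if (kind == "stub" && !is.function(fun))
    stop("stub scorer requires `fun`")
  structure(list(kind = kind, model_path = model_path, fun = fun),
            class = "scorer_spec")
}

# Reference feature Gaussian for the fallback scorer: per-feature mean and
# scale of BRISQUE features over a fixed population of clean-ish
# synthetic phantoms (varied contrast, light noise and bias). The
# covariance is taken diagonal — 24 reference images cannot support a full
# 36x36 covariance, and near-singular directions would dominate the
# distance — with a floor on the per-feature scale. Built once per
# session; fully deterministic (internal seeds).
fallback_reference <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    specs <- expand.grid(contrast = c(60, 80, 100, 140),
                         noise_sd = c(4, 6, 8),
                         bias = c(0, 8))
    feats <- t(vapply(seq_len(nrow(specs)), function(i) {
      sp <- phantom_spec(side = 64L, contrast = specs$contrast[i],
                         noise_sd = specs$noise_sd[i],
                         bias_amplitude = specs$bias[i],
                         seed = 90000L + i)
      brisque_features(generate_phantom(sp)$image)
    }, numeric(36L)))
    mu <- colMeans(feats)
    sd <- apply(feats, 2, stats::sd)
    cache <<- list(mu = mu, sd = pmax(sd, 0.05 * abs(mu) + 1e-3))
    cache
  }
})

#' Score image quality (lower is better)
#'
#' Applies the scorer described by a [scorer_spec()]. Scoring is a pure,
#' deterministic function of the image and the spec.
#'
#' @param img A [gray_image()].
#' @param spec A [scorer_spec()]; defaults to the fallback scorer.
#' @return A single finite numeric score; lower means higher quality.
#' @export
quality_score <- function(img, spec = scorer_spec("fallback")) {
  stopifnot(inherits(spec, "scorer_spec"))
  img <- as_gray_image(img)
  switch(spec$kind,
    "stub" = as.numeric(spec$fun(img)),
    "reference-brisque" = {
      model <- jsonlite::read_json(spec$model_path, simplifyVector = TRUE)
      if (!identical(model$kind, "linear"))
        stop("unsupported coefficients kind: ", model$kind)
      f <- brisque_features(img)
      as.numeric(model$intercept + sum(model$weights * f))
    },
    "fallback" = {
      ref <- fallback_reference()
      d <- (brisque_features(img) - ref$mu) / ref$sd
      sqrt(mean(d^2))
    })
}
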