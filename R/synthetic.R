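#' Specify a synthetic CT-like phantom
#'
#' Phantoms emulate the failure modes of abdominal CT that motivate
#' contrast enhancement: a low foreground/background contrast gap,
#' additive Gaussian noise, and a smooth intensity bias field. Each phantom
#' contains one or two kidney-like ellipses with a known ground-truth mask.
#'
#' Defaults describe a low-contrast, noisy slice: background mean 90
#' levels, contrast gap 40 levels, noise sd 8 levels, bias amplitude 10
#' levels on a 64 px side. Axis ranges keep every ellipse fully inside the
#' frame.
#'
#' @param side Image side length in pixels.
#' @param n_ellipses Number of kidney-like ellipses (1 or 2).
#' @param axis_range Semi-axis range in pixels, `c(min, max)`.
#' @param background Background mean intensity (levels).
#' @param contrast Foreground-background contrast gap (levels, > 0).
#' @param noise_sd Additive Gaussian noise standard deviation (levels).
#' @param bias_amplitude Peak amplitude of the smooth bias field (levels).
#' @param seed Integer seed; phantoms are bit-reproducible given the spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(side = 64L, n_ellipses = 1L,
                         axis_range = c(round(side / 8), round(side / 4)),
                         background = 90, contrast = 40,
                         noise_sd = 8, bias_amplitude = 10, seed = 1L) {
  side <- as.integer(side)
  n_ellipses <- as.integer(n_ellipses)
  if (side < 16L) stop("side must be at least 16")
  if (!n_ellipses %in% 1:2) stop("n_ellipses must be 1 or 2")
  if (contrast <= 0) stop("contrast gap must be positive")
  if (noise_sd < 0 || bias_amplitude < 0) stop("noise and bias must be >= 0")
  if (axis_range[2] >= side / 2 - 1)
    stop("ellipse axes too large for the frame")
  structure(list(side = side, n_ellipses = n_ellipses,
                 axis_range = axis_range, background = background,
                 contrast = contrast, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one phantom image with its ground-truth mask
#'
#' The mask is the union of the ellipse interiors; the image is the
#' background mean plus the contrast gap inside the mask, a low-frequency
#' cosine bias field, and Gaussian noise, rounded and clamped to
#' `[0, 255]`. Identical specs (including seed) give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (a [gray_image()]) and `mask` (logical
#'   matrix).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$side
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(spec$seed)

  mask <- matrix(FALSE, s, s)
  amax <- spec$axis_range[2]
  for (e in seq_len(spec$n_ellipses)) {
    a <- stats::runif(1, spec$axis_range[1], spec$axis_range[2])
    b <- stats::runif(1, spec$axis_range[1], spec$axis_range[2])
    theta <- stats::runif(1, 0, pi)
    margin <- amax + 1
    cx <- stats::runif(1, margin, s - margin)
    cy <- stats::runif(1, margin, s - margin)
    xs <- matrix(rep(seq_len(s), each = s), s)   # column coords
    ys <- matrix(rep(seq_len(s), times = s), s)  # row coords
    xr <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
    yr <- -(xs - cx) * sin(theta) + (ys - cy) * cos(theta)
    mask <- mask | ((xr / a)^2 + (yr / b)^2 <= 1)
  }

  img <- matrix(spec$background, s, s) + spec$contrast * mask
  if (spec$bias_amplitude > 0) {
    fx <- stats::runif(1, 0.5, 1.5); fy <- stats::runif(1, 0.5, 1.5)
    px <- stats::runif(1, 0, 2 * pi); py <- stats::runif(1, 0, 2 * pi)
    u <- seq(0, 2 * pi, length.out = s)
    bias <- spec$bias_amplitude *
      outer(sin(fy * u + py), sin(fx * u + px)) / 2
    img <- img + bias
  }
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(s * s, 0, spec$noise_sd), s, s)
  img <- pmin(pmax(round_half_up(img), 0), 255)
  list(image = gray_image(matrix(as.integer(img), s, s)), mask = mask)
}

#' Named phantom study conditions
#'
#' Fixed specs used throughout the package's experiments and tests:
#' `"default"` — a moderately degraded CT-like slice (contrast gap 40,
#' noise sd 8, bias 10); `"easy"` — high contrast, no noise, no bias
#' (contrast 100), the condition for the scaled-down segmentation
#' benchmark; `"low_contrast"` — contrast gap 15 with noise sd 3 and bias
#' 10, the contrast-starved condition under which enhancement is expected
#' to help (noise is 20% of the contrast gap and the absolute intensity
#' scale is small, so local activity is damped relative to natural
#' statistics).
#'
#' @param name One of `"default"`, `"easy"`, `"low_contrast"`.
#' @param side Image side length in pixels.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name = c("default", "easy", "low_contrast"),
                           side = 64L) {
  switch(match.arg(name),
    "default" = phantom_spec(side = side),
    "easy" = phantom_spec(side = side, contrast = 100, noise_sd = 0,
                          bias_amplitude = 0),
    "low_contrast" = phantom_spec(side = side, contrast = 15, noise_sd = 3,
                                  bias_amplitude = 10))
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a phantom dataset with a train/validation/test split
#'
#' Draws `n` independent phantoms from per-phantom seeds derived
#' deterministically from `seed`, and splits them 70/15/15 in order of a
#' seeded permutation.
#'
#' @param n Number of phantoms (`>= 3`).
#' @param spec Base [phantom_spec()]; its `seed` field is overridden per
#'   phantom.
#' @param seed Master seed for the per-phantom seeds and the split.
#' @return List with `images`, `masks` (lists of length `n`), `split`
#'   (list of index vectors `train`, `val`, `test`) and `seeds`.
#' @export
generate_dataset <- function(n, spec = phantom_spec(), seed = 1L) {
  if (n < 3L) stop("n must be at least 3")
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  perm <- sample.int(n)
  images <- vector("list", n); masks <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec; sp$seed <- seeds[i]
    ph <- generate_phantom(sp)
    images[[i]] <- ph$image; masks[[i]] <- ph$mask
  }
  n_train <- max(1L, floor(0.70 * n))
  n_val <- max(1L, floor(0.15 * n))
  n_test <- n - n_train - n_val
  if (n_test < 1L) { n_train <- n_train - (1L - n_test); n_test <- 1L }
  split <- list(train = sort(perm[seq_len(n_train)]),
                val = sort(perm[n_train + seq_len(n_val)]),
                test = sort(perm[n_train + n_val + seq_len(n_test)]))
  list(images = images, masks = masks, split = split, seeds = seeds)
}
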