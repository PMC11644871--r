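# Round half away from zero (half-up for non-negative input). Base round()
# uses banker's rounding, which would make intensity maps depend on parity.
round_half_up <- function(x) floor(x + 0.5)

#' Construct and validate a grayscale image
#'
#' A grayscale image is an integer-valued matrix with intensities in
#' \code{[0, levels - 1]}. All enhancement and segmentation routines in this
#' package operate on this representation; CT slices are first windowed to
#' 8-bit with [window_to_8bit()].
#'
#' @param pixels Numeric matrix of integer-valued intensities.
#' @param levels Number of gray levels \code{L} (default 256 for 8-bit).
#' @return A matrix of class \code{gray_image} with attribute \code{levels}.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16))
#' @export
gray_image <- function(pixels, levels = 256L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (anyNA(pixels) || any(pixels != floor(pixels)))
    stop("pixel values must be integers (no NA, no fractional values)")
  if (any(pixels < 0) || any(pixels > levels - 1L))
    stop("pixel values must lie in [0, levels - 1]")
  storage.mode(pixels) <- "integer"
  structure(pixels, levels = as.integer(levels), class = c("gray_image", "matrix"))
}

img_levels <- function(img) {
  lv <- attr(img, "levels")
  if (is.null(lv)) 256L else as.integer(lv)
}

as_gray_image <- function(img, levels = 256L) {
  if (inherits(img, "gray_image")) return(img)
  gray_image(img, levels)
}

#' Intensity histogram of an image
#'
#' Tallies `h(r_k) = n_k`, the number of pixels at each gray level
#' `r_k`, for `k = 0, ..., L-1`.
#'
#' @param img A [gray_image()] (or plain integer matrix).
#' @return Integer vector of length `L`; element `k + 1` is the count of
#'   pixels with value `k`. The counts sum to the pixel count `M * N`.
#' @export
compute_histogram <- function(img) {
  img <- as_gray_image(img)
  L <- img_levels(img)
  counts <- tabulate(as.integer(img) + 1L, nbins = L)
  storage.mode(counts) <- "integer"
  counts
}

#' Normalize a histogram to a probability distribution
#'
#' Divides each count by the total number of pixels `M * N`, giving
#' `p(r_k) = n_k / (M N)`.
#'
#' @param counts Integer histogram (length `L`).
#' @param M,N Image width and height in pixels.
#' @return Numeric vector of probabilities summing to 1.
#' @export
normalize_histogram <- function(counts, M, N) {
  total <- as.numeric(M) * as.numeric(N)
  if (total <= 0) stop("M * N must be positive")
  if (any(counts < 0)) stop("histogram counts must be non-negative")
  if (sum(counts) != total)
    stop("histogram counts must sum to M * N")
  counts / total
}

#' Histogram-equalization intensity map
#'
#' Builds the monotone transfer function
#' `s_k = (L - 1) * sum_{j <= k} p(r_j)`, rounded half-up to the nearest
#' integer level. Applying it redistributes intensities so the output
#' histogram is approximately uniform.
#'
#' Rounding is half-up (0.5 rounds towards +Inf), fixed here so results are
#' bit-reproducible. A constant image maps to level `L - 1`: its cumulative
#' distribution reaches 1 at the occupied level, so the formula sends every
#' pixel to the top of the range.
#'
#' @param probs Normalized histogram (sums to 1).
#' @param L Number of gray levels.
#' @return Integer vector of length `L`, monotone non-decreasing, in
#'   `[0, L - 1]`.
#' @export
equalization_map <- function(probs, L = length(probs)) {
  if (L < 2L) stop("L must be at least 2")
  if (any(probs < 0)) stop("probabilities must be non-negative")
  s <- round_half_up((L - 1) * cumsum(probs))
  s <- pmin(pmax(s, 0), L - 1L)
  s <- cummax(s)  # guard against float non-monotonicity at the last ulp
  as.integer(s)
}

#' Global histogram equalization
#'
#' Composes [compute_histogram()], [normalize_histogram()] and
#' [equalization_map()] and applies the resulting map pixel-wise over the
#' whole image. This is the degenerate case of [apply_clahe()] with a single
#' tile and no clipping, and serves as its exact oracle.
#'
#' @param img A [gray_image()].
#' @return A [gray_image()] of the same shape.
#' @export
apply_global_equalization <- function(img) {
  img <- as_gray_image(img)
  L <- img_levels(img)
  counts <- compute_histogram(img)
  p <- normalize_histogram(counts, ncol(img), nrow(img))
  s <- equalization_map(p, L)
  out <- matrix(s[as.integer(img) + 1L], nrow(img), ncol(img))
  gray_image(out, L)
}

#' Linear brightness/contrast adjustment
#'
#' Applies the affine transform `out = clamp(round(gain * in + bias), 0, L-1)`
#' with half-up rounding. Gain scales contrast about zero; bias shifts
#' brightness in gray levels.
#'
#' @param img A [gray_image()].
#' @param gain Non-negative multiplicative factor.
#' @param bias Additive offset in gray levels.
#' @return Adjusted [gray_image()].
#' @export
adjust_brightness_contrast <- function(img, gain = 1, bias = 0) {
  img <- as_gray_image(img)
  if (gain < 0) stop("gain must be non-negative")
  L <- img_levels(img)
  out <- round_half_up(gain * as.numeric(img) + bias)
  out <- pmin(pmax(out, 0), L - 1L)
  gray_image(matrix(out, nrow(img), ncol(img)), L)
}

#' Write a histogram as CSV
#'
#' @param counts Histogram vector.
#' @param path Output CSV path; columns `level,count`.
#' @export
write_histogram_csv <- function(counts, path) {
  utils::write.csv(
    data.frame(level = seq_along(counts) - 1L, count = as.vector(counts)),
    path, row.names = FALSE)
  invisible(path)
}
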