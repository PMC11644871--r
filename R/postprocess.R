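#' Structuring elements for binary morphology
#'
#' Builds the boolean kernel (with centered origin) used by the
#' morphological operators. The default, a full 3x3 square, is what the
#' mask-refinement step uses unless overridden.
#'
#' @param shape `"square"` or `"disk"`.
#' @param size Side length (square) or diameter (disk); odd, `>= 1`.
#' @return Logical matrix of class `structuring_element`.
#' @export
structuring_element <- function(shape = c("square", "disk"), size = 3L) {
  shape <- match.arg(shape)
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop("size must be odd and >= 1")
  if (shape == "square") {
    S <- matrix(TRUE, size, size)
  } else {
    r <- (size - 1L) / 2
    d <- outer(seq_len(size) - r - 1L, seq_len(size) - r - 1L,
               function(i, j) sqrt(i^2 + j^2))
    S <- d <= r + 1e-9
  }
  structure(S, class = c("structuring_element", "matrix"))
}

selem_offsets <- function(S) {
  if (!any(S)) stop("structuring element must contain at least one TRUE cell")
  origin <- (dim(S) + 1L) %/% 2L
  w <- which(S, arr.ind = TRUE)
  cbind(di = w[, 1L] - origin[1L], dj = w[, 2L] - origin[2L])
}

shift_mask <- function(B, di, dj, fill = FALSE) {
  n <- nrow(B); m <- ncol(B)
  out <- matrix(fill, n, m)
  src_r <- max(1L, 1L + di):min(n, n + di)
  src_c <- max(1L, 1L + dj):min(m, m + dj)
  if (length(src_r) < 1L || length(src_c) < 1L) return(out)
  out[src_r - di, src_c - dj] <- B[src_r, src_c]
  out
}

#' Binary erosion
#'
#' The eroded mask keeps a pixel iff the structuring element, translated
#' there, fits entirely inside the foreground. Pixels outside the image
#' count as background, so foreground touching the border erodes.
#'
#' @param B Logical mask matrix.
#' @param S A [structuring_element()] (default 3x3 square).
#' @return Logical mask of the same shape.
#' @export
erode_mask <- function(B, S = structuring_element()) {
  off <- selem_offsets(S)
  out <- matrix(TRUE, nrow(B), ncol(B))
  for (t in seq_len(nrow(off)))
    out <- out & shift_mask(B, off[t, 1L], off[t, 2L], fill = FALSE)
  out
}

#' Binary dilation
#'
#' A pixel is set iff the reflected structuring element translated there
#' intersects the foreground. Dual of erosion under complement.
#'
#' @inheritParams erode_mask
#' @return Logical mask of the same shape.
#' @export
dilate_mask <- function(B, S = structuring_element()) {
  off <- selem_offsets(S)
  out <- matrix(FALSE, nrow(B), ncol(B))
  for (t in seq_len(nrow(off)))
    out <- out | shift_mask(B, -off[t, 1L], -off[t, 2L], fill = FALSE)
  out
}

#' Morphological opening
#'
#' Erosion followed by dilation with the same element: removes foreground
#' structures smaller than the element while approximately preserving the
#' rest. Anti-extensive (result is a subset of the input) and idempotent.
#'
#' @inheritParams erode_mask
#' @return Logical mask of the same shape.
#' @export
open_mask <- function(B, S = structuring_element()) {
  dilate_mask(erode_mask(B, S), S)
}

#' Two-step mask refinement
#'
#' The postprocessing sequence applied to CNN output masks: an erosion
#' that removes small noise, followed by a morphological opening that
#' smooths the remaining boundary. The two steps are applied literally in
#' that order (the opening performs its own erosion internally). Never
#' adds foreground.
#'
#' @inheritParams erode_mask
#' @return Refined logical mask.
#' @export
refine_mask <- function(B, S = structuring_element()) {
  open_mask(erode_mask(B, S), S)
}

#' Apply a binary mask to an image
#'
#' Keeps foreground intensities and zeroes the background, isolating the
#' segmented region for downstream measurement.
#'
#' @param img A [gray_image()].
#' @param B Logical mask of the same shape.
#' @return Masked [gray_image()].
#' @export
apply_mask <- function(img, B) {
  img <- as_gray_image(img)
  if (!all(dim(img) == dim(B))) stop("image and mask shapes differ")
  out <- matrix(as.integer(img) * as.integer(B), nrow(img), ncol(img))
  gray_image(out, img_levels(img))
}
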