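#' Read / write an 8-bit grayscale PNG slice
#'
#' @param path PNG file path.
#' @return `read_png_image`: a [gray_image()]. `write_png_image`: the
#'   path, invisibly.
#' @export
read_png_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]  # drop extra channels
  gray_image(matrix(as.integer(round_half_up(x * 255)), nrow(x), ncol(x)))
}

#' @rdname read_png_image
#' @param img A [gray_image()].
#' @export
write_png_image <- function(img, path) {
  img <- as_gray_image(img)
  png::writePNG(matrix(as.numeric(img) / 255, nrow(img), ncol(img)), path)
  invisible(path)
}

#' Read / write a binary mask PNG (0 = background, 255 = foreground)
#'
#' @param path PNG file path.
#' @return `read_png_mask`: a logical matrix. `write_png_mask`: the path,
#'   invisibly.
#' @export
read_png_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x >= 0.5
}

#' @rdname read_png_mask
#' @param mask Logical matrix.
#' @export
write_png_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Hounsfield-unit display window
#'
#' Defaults to the soft-tissue window (center 50 HU, width 400 HU) used to
#' map CT attenuation to 8-bit display intensities. The source data never
#' state their normalization, so this is a configurable default.
#'
#' @param center Window center in HU.
#' @param width Window width in HU (`> 0`).
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(center = 50, width = 400) {
  if (width <= 0) stop("window width must be positive")
  structure(list(center = center, width = width), class = "window_spec")
}

#' Window an HU slice to an 8-bit image
#'
#' Linearly maps `[center - width/2, center + width/2]` to `[0, 255]`,
#' clamps, and rounds half-up.
#'
#' @param huslice Numeric matrix of Hounsfield units.
#' @param w A [window_spec()].
#' @return A [gray_image()].
#' @export
window_to_8bit <- function(huslice, w = window_spec()) {
  stopifnot(inherits(w, "window_spec"))
  lo <- w$center - w$width / 2
  x <- (huslice - lo) / w$width * 255
  x <- pmin(pmax(round_half_up(x), 0), 255)
  gray_image(matrix(as.integer(x), nrow(huslice), ncol(huslice)))
}

strip_attrs <- function(a) {
  attributes(a) <- list(dim = dim(a))
  a
}

#' Read a CT volume (NIfTI) with optional paired labels
#'
#' Loads a KiTS19-style case: an imaging volume and, when present, its
#' segmentation volume. Slices are returned in acquisition (array) order;
#' anomalous in-plane sizes are accepted as-is and resized downstream.
#'
#' @param imaging_path NIfTI imaging volume (`.nii` / `.nii.gz`).
#' @param segmentation_path Optional NIfTI label volume.
#' @param case_id Optional identifier.
#' @return List of class `volume_ref` with `case_id`, `imaging` (3-D HU
#'   array), `segmentation` (3-D integer array or `NULL`), `n_slices`,
#'   `slice_shape`.
#' @export
read_volume <- function(imaging_path, segmentation_path = NULL,
                        case_id = basename(imaging_path)) {
  img <- tryCatch(RNifti::readNifti(imaging_path),
                  error = function(e) stop("cannot read NIfTI volume: ",
                                           conditionMessage(e)))
  img <- strip_attrs(as.array(img))
  if (length(dim(img)) != 3L) stop("expected a 3-D imaging volume")
  seg <- NULL
  if (!is.null(segmentation_path)) {
    seg <- strip_attrs(as.array(RNifti::readNifti(segmentation_path)))
    if (!all(dim(seg) == dim(img)))
      stop("imaging and segmentation volume shapes differ")
  }
  structure(list(case_id = case_id, imaging = img, segmentation = seg,
                 n_slices = dim(img)[3L], slice_shape = dim(img)[1:2]),
            class = "volume_ref")
}

#' Binarize a KiTS19-style label slice
#'
#' Labels are 0 = background, 1 = kidney, 2 = tumor. The default mode
#' merges kidney and tumor into the foreground, since evaluation treats
#' the whole renal region as one class; `"kidney-only"` keeps label 1
#' alone. Unknown labels above 2 trigger a warning and count as
#' foreground under the default mode.
#'
#' @param labelslice Integer-valued matrix of labels.
#' @param mode `"kidney+tumor"` (default) or `"kidney-only"`.
#' @return Logical mask.
#' @export
binarize_labels <- function(labelslice, mode = c("kidney+tumor", "kidney-only")) {
  mode <- match.arg(mode)
  if (any(labelslice != floor(labelslice))) stop("labels must be integers")
  if (any(labelslice > 2)) warning("labels greater than 2 present")
  if (mode == "kidney+tumor") labelslice > 0 else labelslice == 1
}

#' Resize helpers used when feeding slices to the model
#'
#' Images are resampled bilinearly and re-quantized; masks use
#' nearest-neighbour so labels stay binary.
#'
#' @param img A [gray_image()].
#' @param side Target side length (square output).
#' @return Resized [gray_image()] / logical matrix.
#' @export
resize_image <- function(img, side) {
  img <- as_gray_image(img)
  x <- matrix(as.numeric(img), nrow(img), ncol(img))
  out <- bilinear_resize(x, side, side)
  gray_image(matrix(as.integer(pmin(pmax(round_half_up(out), 0), 255)),
                    side, side), img_levels(img))
}

#' @rdname resize_image
#' @param mask Logical matrix.
#' @export
resize_mask <- function(mask, side) {
  ridx <- pmin(pmax(floor(((0:(side - 1)) + 0.5) * nrow(mask) / side) + 1L,
                    1L), nrow(mask))
  cidx <- pmin(pmax(floor(((0:(side - 1)) + 0.5) * ncol(mask) / side) + 1L,
                    1L), ncol(mask))
  mask[ridx, cidx, drop = FALSE]
}

bilinear_resize <- function(x, th, tw) {
  n <- nrow(x); m <- ncol(x)
  rf <- ((0:(th - 1)) + 0.5) * n / th - 0.5
  cf <- ((0:(tw - 1)) + 0.5) * m / tw - 0.5
  r0 <- pmin(pmax(floor(rf), 0), n - 1L); r1 <- pmin(r0 + 1L, n - 1L)
  c0 <- pmin(pmax(floor(cf), 0), m - 1L); c1 <- pmin(c0 + 1L, m - 1L)
  wr <- pmin(pmax(rf - r0, 0), 1); wc <- pmin(pmax(cf - c0, 0), 1)
  a <- x[r0 + 1L, c0 + 1L, drop = FALSE]; b <- x[r1 + 1L, c0 + 1L, drop = FALSE]
  ce <- x[r0 + 1L, c1 + 1L, drop = FALSE]; e <- x[r1 + 1L, c1 + 1L, drop = FALSE]
  WR <- matrix(wr, th, tw); WC <- matrix(wc, th, tw, byrow = TRUE)
  (1 - WR) * ((1 - WC) * a + WC * ce) + WR * ((1 - WC) * b + WC * e)
}
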