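#' CLAHE parameters
#'
#' The two tunables of contrast-limited adaptive histogram equalization:
#' `nt`, the number of tiles per image axis (an `nt x nt` grid), and `cl`,
#' the normalized contrast limit. `cl` is the maximum fraction of a tile's
#' pixels any single histogram bin may hold before clipping; the clip
#' threshold is `T = max(1, ceiling(cl * tile_pixels))`, so `cl = 1`
#' disables clipping and recovers plain per-tile equalization.
#'
#' @param nt Tiles per axis, integer `>= 1`.
#' @param cl Contrast limit in `(0, 1]`.
#' @return A list of class `clahe_params`.
#' @export
clahe_params <- function(nt, cl) {
  nt <- as.integer(nt)
  if (is.na(nt) || nt < 1L) stop("nt must be an integer >= 1")
  if (!is.finite(cl) || cl <= 0 || cl > 1) stop("cl must lie in (0, 1]")
  structure(list(nt = nt, cl = cl), class = "clahe_params")
}

#' Partition an image into a tile grid
#'
#' Tiles are delimited by floor-spaced edges `floor(i * N / nt)` so that
#' non-divisible image sizes yield near-equal tiles with no padding, no
#' overlap and no gap.
#'
#' @param img A [gray_image()].
#' @param nt Tiles per axis; must not exceed `min(nrow, ncol)`.
#' @return List with `row_edges`, `col_edges` (0-based boundary sequences of
#'   length `nt + 1`) and `tile_pixels` (an `nt x nt` matrix of tile areas).
#' @export
partition_tiles <- function(img, nt) {
  img <- as_gray_image(img)
  N <- nrow(img); M <- ncol(img)
  nt <- as.integer(nt)
  if (nt < 1L || nt > min(M, N))
    stop("nt must lie in [1, min(image dimensions)]")
  row_edges <- floor((0:nt) * N / nt)
  col_edges <- floor((0:nt) * M / nt)
  heights <- diff(row_edges); widths <- diff(col_edges)
  list(row_edges = as.integer(row_edges),
       col_edges = as.integer(col_edges),
       tile_pixels = outer(heights, widths))
}

#' Clip a histogram and redistribute the excess
#'
#' Bins above the threshold `T = max(1, ceiling(cl * tile_pixels))` are cut
#' to `T` and the total excess is spread uniformly over all `L` bins in a
#' single pass. Re-overflow after redistribution is tolerated (no iterative
#' re-clipping); total mass is conserved exactly up to float rounding.
#'
#' @param counts Histogram (integer or real-valued bins).
#' @param cl Contrast limit in `(0, 1]`.
#' @param tile_pixels Number of pixels in the tile (`sum(counts)`).
#' @return Real-valued clipped histogram of the same length.
#' @export
clip_and_redistribute <- function(counts, cl, tile_pixels = sum(counts)) {
  if (!is.finite(cl) || cl <= 0 || cl > 1) stop("cl must lie in (0, 1]")
  threshold <- max(1, ceiling(cl * tile_pixels))
  clipped <- pmin(counts, threshold)
  excess <- sum(counts) - sum(clipped)
  clipped + excess / length(counts)
}

#' Equalization map of a (clipped) tile histogram
#'
#' Normalizes a possibly real-valued clipped histogram by its mass and
#' applies the cumulative-distribution map of [equalization_map()].
#'
#' @param clipped_counts Clipped histogram with positive mass.
#' @param L Number of gray levels.
#' @return Integer monotone map of length `L`.
#' @export
tile_mapping <- function(clipped_counts, L = length(clipped_counts)) {
  mass <- sum(clipped_counts)
  if (mass <= 0) stop("histogram mass must be positive")
  equalization_map(clipped_counts / mass, L)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Divides the image into an `nt x nt` tile grid, computes each tile's
#' clipped-histogram equalization map, and sets every output pixel to the
#' bilinear blend of the four nearest tile-center maps evaluated at the
#' pixel's input level. Pixels outside the outer lattice of tile centers
#' fall back to the nearest available map (edge/corner rows and columns).
#'
#' With `nt = 1, cl = 1` the result equals [apply_global_equalization()]
#' exactly, pixel for pixel.
#'
#' @param img A [gray_image()].
#' @param params A [clahe_params()] object (or `nt`/`cl` given separately).
#' @param nt,cl Convenience scalar alternatives to `params`.
#' @return Enhanced [gray_image()] of the same shape.
#' @export
apply_clahe <- function(img, params = NULL, nt = NULL, cl = NULL) {
  img <- as_gray_image(img)
  if (is.null(params)) params <- clahe_params(nt, cl)
  stopifnot(inherits(params, "clahe_params"))
  L <- img_levels(img)
  N <- nrow(img); M <- ncol(img)
  ntile <- params$nt
  grid <- partition_tiles(img, ntile)

  # Per-tile equalization maps: maps[k, i, j] = map of tile (i,j) at level k-1
  maps <- array(0L, c(L, ntile, ntile))
  for (i in seq_len(ntile)) {
    rows <- (grid$row_edges[i] + 1L):grid$row_edges[i + 1L]
    for (j in seq_len(ntile)) {
      cols <- (grid$col_edges[j] + 1L):grid$col_edges[j + 1L]
      tile <- img[rows, cols, drop = FALSE]
      h <- tabulate(as.integer(tile) + 1L, nbins = L)
      hc <- clip_and_redistribute(h, params$cl, length(tile))
      maps[, i, j] <- tile_mapping(hc, L)
    }
  }

  # Tile centers (0-based pixel coordinates).
  centers_r <- (grid$row_edges[-1L] + grid$row_edges[-(ntile + 1L)] - 1) / 2
  centers_c <- (grid$col_edges[-1L] + grid$col_edges[-(ntile + 1L)] - 1) / 2

  ax <- interp_axis(N, centers_r)   # rows
  ay <- interp_axis(M, centers_c)   # cols
  v <- as.integer(img) + 1L         # level index, column-major over pixels

  i0 <- rep(ax$lo, times = M); i1 <- rep(ax$hi, times = M)
  wr <- rep(ax$w,  times = M)
  j0 <- rep(ay$lo, each = N); j1 <- rep(ay$hi, each = N)
  wc <- rep(ay$w,  each = N)

  f00 <- maps[cbind(v, i0, j0)]; f10 <- maps[cbind(v, i1, j0)]
  f01 <- maps[cbind(v, i0, j1)]; f11 <- maps[cbind(v, i1, j1)]
  out <- (1 - wr) * ((1 - wc) * f00 + wc * f01) +
         wr * ((1 - wc) * f10 + wc * f11)
  out <- pmin(pmax(round_half_up(out), 0), L - 1L)
  gray_image(matrix(as.integer(out), N, M), L)
}

# For each 0-based pixel coordinate along one axis, the bracketing tile
# center indices (lo, hi) and interpolation weight w towards hi. Coordinates
# outside the center lattice clamp to the nearest center (w = 0, lo = hi).
interp_axis <- function(n, centers) {
  x <- 0:(n - 1)
  k <- length(centers)
  if (k == 1L) return(list(lo = rep(1L, n), hi = rep(1L, n), w = rep(0, n)))
  hi <- findInterval(x, centers) + 1L   # first center strictly above x... see below
  lo <- hi - 1L
  # findInterval gives count of centers <= x; adjust for exact hits
  lo <- pmax(pmin(lo, k), 1L)
  hi <- pmax(pmin(hi, k), 1L)
  w <- numeric(n)
  inside <- hi > lo
  w[inside] <- (x[inside] - centers[lo[inside]]) /
    (centers[hi[inside]] - centers[lo[inside]])
  list(lo = lo, hi = hi, w = w)
}
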