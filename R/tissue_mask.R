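#' Otsu's threshold
#'
#' Classical histogram thresholding: the value range is split into 256
#' equal-width bins and the cut maximizing the between-class variance of
#' the two resulting classes is returned. Pixels strictly greater than the
#' threshold are foreground. Constant input has no two classes to separate
#' and is rejected.
#'
#' @param values numeric vector or matrix (e.g. a density map) of
#'   non-negative values.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold value (an internal bin edge).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) < 2L || length(unique(v)) < 2L)
    stop("degenerate histogram: need at least 2 distinct values")
  lo <- min(v); hi <- max(v)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  h <- as.numeric(tabulate(bin, nbins = n_bins))
  # exact per-bin value sums, so class means are exact, not bin centers
  vs <- vapply(split(v, factor(bin, levels = seq_len(n_bins))), sum,
               numeric(1))
  w <- cumsum(h)                      # class-0 weight at cut after bin t
  m <- cumsum(vs)                     # class-0 unnormalized mean
  wt <- w[n_bins]; mt <- m[n_bins]
  t_idx <- seq_len(n_bins - 1L)
  w0 <- w[t_idx]; w1 <- wt - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[t_idx] / w0
  mu1 <- (mt - m[t_idx]) / w1
  sb <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  best <- which.max(sb)
  edges[best + 1L]                    # upper edge of the last class-0 bin
}

#' Rasterize a closed contour onto the grid
#'
#' Draws each polygon edge with a supercover (conservative 4-connected)
#' line so that the resulting curve has no diagonal holes and therefore
#' bounds an 8-connected flood fill. The polygon is closed implicitly
#' between the last and first vertex.
#'
#' @param vertices two-column matrix of (x_bin, y_bin) vertices, 0-based.
#' @param grid a [grid_spec()].
#' @return Logical matrix, `TRUE` on contour pixels.
#' @export
rasterize_contour <- function(vertices, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  vertices <- round(as.matrix(vertices))
  if (nrow(vertices) < 3L) stop("degenerate contour: need >= 3 vertices")
  if (any(vertices[, 1] < 0) || any(vertices[, 1] >= grid$width_bins) ||
      any(vertices[, 2] < 0) || any(vertices[, 2] >= grid$height_bins))
    stop("contour vertex outside grid")
  img <- matrix(FALSE, grid$height_bins, grid$width_bins)
  n <- nrow(vertices)
  for (i in seq_len(n)) {
    a <- vertices[i, ]
    b <- vertices[if (i == n) 1L else i + 1L, ]
    px <- supercover_line(a[1], a[2], b[1], b[2])
    img[cbind(px[, 2] + 1L, px[, 1] + 1L)] <- TRUE
  }
  img
}

# 4-connected digital line from (x0,y0) to (x1,y1): visits dx+dy+1 cells,
# stepping one axis at a time in the order the ideal segment crosses the
# pixel midlines, so consecutive pixels always share an edge.
supercover_line <- function(x0, y0, x1, y1) {
  nx <- abs(x1 - x0); ny <- abs(y1 - y0)
  sx <- sign(x1 - x0); sy <- sign(y1 - y0)
  out <- matrix(0L, nx + ny + 1L, 2L)
  out[1L, ] <- c(x0, y0)
  x <- x0; y <- y0; ix <- 0L; iy <- 0L; k <- 2L
  while (ix < nx || iy < ny) {
    if (iy >= ny || (ix < nx && (1 + 2 * ix) * ny < (1 + 2 * iy) * nx)) {
      x <- x + sx; ix <- ix + 1L
    } else {
      y <- y + sy; iy <- iy + 1L
    }
    out[k, ] <- c(x, y); k <- k + 1L
  }
  out
}

#' Binary dilation / erosion / closing with a square structuring element
#'
#' Implemented by shift-accumulation; `closing = erode(dilate(mask))` with
#' the same k x k square element (default 5 x 5), matching the mask
#' post-processing of the tissue-boundary protocol. Closing never removes
#' a pixel that was set in the input.
#'
#' @param mask logical matrix.
#' @param k odd structuring-element size in pixels.
#' @return Logical matrix.
#' @export
binary_dilate <- function(mask, k = 5L) {
  stopifnot(is.logical(mask), k %% 2L == 1L)
  r <- (k - 1L) %/% 2L
  acc <- matrix(FALSE, nrow(mask), ncol(mask))
  for (dy in -r:r) for (dx in -r:r)
    acc <- acc | shift_mat(mask, dy, dx, fill = FALSE)
  acc
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, k = 5L) {
  !binary_dilate(!mask, k)
}

#' @rdname binary_dilate
#' @export
binary_closing <- function(mask, k = 5L) {
  binary_erode(binary_dilate(mask, k), k)
}

# shift a matrix by (dy, dx), padding with `fill`
shift_mat <- function(m, dy, dx, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Tissue mask from a manually outlined contour
#'
#' The manual-contour protocol: rasterize the closed contour, bridge small
#' annotation gaps by morphological closing of the contour raster, flood
#' fill the interior from a seed point with 8-neighbourhood connectivity,
#' then close the filled mask with a 5 x 5 square element. The returned
#' mask covers interior plus contour pixels.
#'
#' @param vertices two-column (x_bin, y_bin) vertex matrix, closed
#'   implicitly.
#' @param grid a [grid_spec()].
#' @param seed_point length-2 (x_bin, y_bin) strictly inside the contour.
#' @param closing_k structuring-element size (default 5).
#' @return Logical matrix of class-tagged provenance `manual_contour`.
#' @export
mask_from_contour <- function(vertices, grid, seed_point, closing_k = 5L) {
  contour <- rasterize_contour(vertices, grid)
  contour <- binary_closing(contour, closing_k)
  sx <- as.integer(round(seed_point[1])); sy <- as.integer(round(seed_point[2]))
  if (sx < 0L || sx >= grid$width_bins || sy < 0L || sy >= grid$height_bins)
    stop("seed point outside grid")
  if (contour[sy + 1L, sx + 1L])
    stop("seed point lies on the contour")
  fill <- cpp_flood_fill(contour, sy, sx)
  if (any(fill[1L, ] | fill[nrow(fill), ] | fill[, 1L] | fill[, ncol(fill)]))
    stop("flood fill escaped to the grid border: contour is not closed")
  mask <- binary_closing(fill | contour, closing_k)
  attr(mask, "provenance") <- "manual_contour"
  mask
}

#' Tissue mask by threshold binarization
#'
#' The automatic path used when no manual contour is drawn: Otsu threshold
#' on the total-density map, then 5 x 5 morphological closing.
#'
#' @param density a density matrix (see [build_density()]).
#' @param closing_k structuring-element size (default 5).
#' @return Logical mask with provenance `threshold`.
#' @export
mask_from_threshold <- function(density, closing_k = 5L) {
  thr <- otsu_threshold(density)
  mask <- binary_closing(density > thr, closing_k)
  attr(mask, "provenance") <- "threshold"
  mask
}

#' Subset a spot table to a mask
#'
#' Keeps records whose bin lies on a `TRUE` pixel. Idempotent.
#'
#' @param spots a [spot_table()].
#' @param mask logical matrix matching the grid.
#' @return The subset, still a [spot_table()].
#' @export
barcodes_in_mask <- function(spots, mask) {
  grid <- attr(spots, "grid")
  if (nrow(mask) != grid$height_bins || ncol(mask) != grid$width_bins)
    stop("mask shape does not match grid")
  keep <- mask[cbind(spots$y_bin + 1L, spots$x_bin + 1L)]
  out <- spots[keep]
  setattr(out, "grid", grid)
  setattr(out, "class", class(spots))
  out[]
}
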