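#' Grid specification for a spatial chip
#'
#' Defines the pixel-bin raster every other structure refers to. The origin
#' is the top-left corner; `x_bin` grows rightward, `y_bin` downward, and
#' both are 0-based integer bin indices. `pitch_nm` is the physical edge
#' length of one square pixel bin (250 nm by default, i.e. each bin covers
#' 250 nm x 250 nm).
#'
#' @param width_bins,height_bins positive integers, grid extent in bins.
#' @param pitch_nm positive real, physical edge of one bin in nanometres.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(512, 512)
#' bins_to_um2(4750, g)
#' @export
grid_spec <- function(width_bins, height_bins, pitch_nm = 250) {
  stopifnot(length(width_bins) == 1, length(height_bins) == 1,
            length(pitch_nm) == 1)
  if (!is.finite(pitch_nm) || pitch_nm <= 0)
    stop("pitch_nm must be a positive real")
  width_bins <- as.integer(width_bins)
  height_bins <- as.integer(height_bins)
  if (is.na(width_bins) || is.na(height_bins) ||
      width_bins < 1L || height_bins < 1L)
    stop("width_bins and height_bins must be integers >= 1")
  structure(list(width_bins = width_bins, height_bins = height_bins,
                 pitch_nm = as.numeric(pitch_nm)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d bins, pitch %g nm (origin top-left, 0-based)\n",
              x$width_bins, x$height_bins, x$pitch_nm))
  invisible(x)
}

#' Convert an area in pixel bins to square micrometres
#'
#' One bin covers `(pitch_nm / 1000)^2` square micrometres; at the default
#' 250 nm pitch, 16 bins make 1 um^2.
#'
#' @param area_bins non-negative number of pixel bins (vectorized).
#' @param grid a [grid_spec()].
#' @return Area in um^2.
#' @export
bins_to_um2 <- function(area_bins, grid = grid_spec(1, 1)) {
  stopifnot(inherits(grid, "grid_spec"))
  if (any(!is.finite(area_bins)) || any(area_bins < 0))
    stop("area_bins must be non-negative")
  area_bins * (grid$pitch_nm / 1000)^2
}

#' Equivalent circle radius and square side of a pixel area
#'
#' The radius of the circle (or side of the square) whose area equals
#' `area_bins` pixel bins. Both are returned in pixel units without
#' rounding; round at the call site if an integer pixel count is wanted.
#'
#' @param area_bins non-negative area in pixel bins (vectorized).
#' @return Radius (or side) in pixels.
#' @export
equivalent_circle_radius <- function(area_bins) {
  if (any(!is.finite(area_bins)) || any(area_bins < 0))
    stop("area_bins must be non-negative")
  sqrt(area_bins / pi)
}

#' @rdname equivalent_circle_radius
#' @export
equivalent_square_side <- function(area_bins) {
  if (any(!is.finite(area_bins)) || any(area_bins < 0))
    stop("area_bins must be non-negative")
  sqrt(area_bins)
}
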