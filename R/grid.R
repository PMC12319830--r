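#' Square visual-field sampling grid
#'
#' Defines the raster on which stimulus apertures and receptive-field
#' Gaussians are evaluated. Coordinates are in degrees of visual angle with
#' the origin at fixation, x positive rightward and y positive upward. Cell
#' centres are symmetric about zero.
#'
#' @param extent_deg width/height of the mapped field in degrees (the bar
#'   stimulus covers a circular aperture of this diameter; default 12).
#' @param n_cells number of raster cells per axis (default 101).
#' @return An object of class \code{visual_field_grid} with elements
#'   \code{extent_deg}, \code{n_cells}, \code{x}, \code{y} (cell-centre
#'   coordinates) and \code{in_aperture} (logical matrix, cells whose centre
#'   lies inside the circular aperture of diameter \code{extent_deg}).
#' @export
visual_field_grid <- function(extent_deg = 12, n_cells = 101L) {
  stopifnot(extent_deg > 0, n_cells >= 8)
  x <- seq(-extent_deg / 2, extent_deg / 2, length.out = n_cells)
  y <- x
  ecc2 <- outer(x^2, y^2, "+") # [i, j] = x_i^2 + y_j^2
  structure(
    list(extent_deg = extent_deg, n_cells = as.integer(n_cells),
         x = x, y = y, in_aperture = ecc2 <= (extent_deg / 2)^2),
    class = "visual_field_grid"
  )
}

# unnormalised 2-D Gaussian rasterised on the grid, returned as an
# n_cells x n_cells matrix (rows index x, columns index y)
gaussian_on_grid <- function(grid, x0, y0, sigma) {
  stopifnot(inherits(grid, "visual_field_grid"), sigma > 0)
  gx <- exp(-(grid$x - x0)^2 / (2 * sigma^2))
  gy <- exp(-(grid$y - y0)^2 / (2 * sigma^2))
  outer(gx, gy)
}

#' Rasterise a Gaussian activation bump on the visual-field grid
#'
#' Used by the synthetic-data generator to give each task event a latent
#' spatial activation profile. The bump is clipped to the circular aperture
#' and is non-negative everywhere.
#'
#' @param grid a [visual_field_grid()].
#' @param x0,y0 bump centre in degrees.
#' @param sigma bump width in degrees.
#' @return An \code{n_cells x n_cells} non-negative matrix, zero outside the
#'   aperture.
#' @export
field_bump <- function(grid, x0, y0, sigma) {
  g <- gaussian_on_grid(grid, x0, y0, sigma)
  g[!grid$in_aperture] <- 0
  g
}
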