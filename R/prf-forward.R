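#' Construct a signed-amplitude 2-D Gaussian pRF model
#'
#' A population receptive field is an isotropic 2-D Gaussian in the visual
#' field with centre \code{(x_deg, y_deg)} and width \code{sigma_deg}. The
#' response amplitude is signed: positive amplitudes describe voxels that
#' activate when the stimulus enters the receptive field, negative
#' amplitudes voxels that deactivate.
#'
#' @param x_deg,y_deg centre in degrees of visual angle.
#' @param sigma_deg Gaussian width in degrees (> 0).
#' @param amplitude signed response scale in percent-signal-change units.
#' @param baseline constant timeseries offset (default 0).
#' @param r_squared optional fit quality in \code{[0, 1]} (NA for a model
#'   that was specified rather than fitted).
#' @return An object of class \code{prf_model}.
#' @export
prf_model <- function(x_deg, y_deg, sigma_deg, amplitude = 1, baseline = 0,
                      r_squared = NA_real_) {
  stopifnot(is.finite(x_deg), is.finite(y_deg), sigma_deg > 0)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must lie in [0, 1]")
  structure(list(x_deg = x_deg, y_deg = y_deg, sigma_deg = sigma_deg,
                 amplitude = amplitude, baseline = baseline,
                 r_squared = r_squared),
            class = "prf_model")
}

#' @export
print.prf_model <- function(x, ...) {
  cat(sprintf("pRF: centre (%.2f, %.2f) deg, sigma %.2f deg, amplitude %+.3f%s\n",
              x$x_deg, x$y_deg, x$sigma_deg, x$amplitude,
              if (is.na(x$r_squared)) "" else sprintf(", R^2 = %.3f", x$r_squared)))
  invisible(x)
}

# overlap of one Gaussian RF with one stimulus field S on the grid:
# sum(S * G) / sum(G), with sum(G) taken over the full square grid.
# Separable in x and y when S is given as a cells-x-cells matrix.
.overlap_one <- function(grid, S, x0, y0, sigma) {
  gx <- exp(-(grid$x - x0)^2 / (2 * sigma^2))
  gy <- exp(-(grid$y - y0)^2 / (2 * sigma^2))
  denom <- sum(gx) * sum(gy)
  if (denom == 0 || !is.finite(denom))
    stop("Gaussian underflows on every grid cell (sigma = ", sigma,
         " deg); increase n_cells or sigma so the RF spans at least one cell")
  drop(crossprod(gx, S %*% gy)) / denom
}

#' Per-TR overlap of a pRF with the stimulus aperture sequence
#'
#' For each TR, the overlap is the mask-weighted mean of the unnormalised
#' receptive-field Gaussian over the grid: \eqn{\sum m G / \sum G}, a
#' unitless value in \code{[0, 1]}. This is the neural drive of the forward
#' model before hemodynamic convolution.
#'
#' @param prf a [prf_model()].
#' @param apertures an \code{aperture_sequence} from [make_bar_masks()].
#' @return Numeric vector of overlaps, one per TR.
#' @export
rf_overlap_series <- function(prf, apertures) {
  stopifnot(inherits(prf, "prf_model"), inherits(apertures, "aperture_sequence"))
  grid <- apertures$grid
  gx <- exp(-(grid$x - prf$x_deg)^2 / (2 * prf$sigma_deg^2))
  gy <- exp(-(grid$y - prf$y_deg)^2 / (2 * prf$sigma_deg^2))
  denom <- sum(gx) * sum(gy)
  if (denom == 0 || !is.finite(denom))
    stop("Gaussian underflows on every grid cell (sigma = ", prf$sigma_deg,
         " deg); increase n_cells or sigma so the RF spans at least one cell")
  n_tr <- dim(apertures$masks)[3]
  M <- matrix(apertures$masks, nrow = grid$n_cells^2, ncol = n_tr)
  g <- as.vector(outer(gx, gy))
  drop(crossprod(M, g)) / denom
}

#' Overlap of pRFs with arbitrary stimulus field maps
#'
#' Generalises [rf_overlap_series()] from binary apertures to non-negative
#' latent activation fields (one per task event label), as used by the
#' synthetic task generator.
#'
#' @param prfs list of [prf_model()] objects.
#' @param field_maps named list of \code{n_cells x n_cells} matrices.
#' @param grid the [visual_field_grid()] the maps are rasterised on.
#' @return Matrix of overlaps, voxels x labels.
#' @export
rf_field_overlap <- function(prfs, field_maps, grid) {
  S <- vapply(field_maps, as.vector, numeric(grid$n_cells^2))
  O <- t(vapply(prfs, function(p) {
    gx <- exp(-(grid$x - p$x_deg)^2 / (2 * p$sigma_deg^2))
    gy <- exp(-(grid$y - p$y_deg)^2 / (2 * p$sigma_deg^2))
    drop(crossprod(S, as.vector(outer(gx, gy)))) / (sum(gx) * sum(gy))
  }, numeric(length(field_maps))))
  dimnames(O) <- list(NULL, names(field_maps))
  O
}

#' Noiseless predicted mapping timeseries of a pRF
#'
#' baseline + amplitude x (overlap series convolved with the HRF),
#' truncated to the run length.
#'
#' @param prf a [prf_model()].
#' @param apertures an \code{aperture_sequence}.
#' @param hrf an [gam_hrf()] kernel (defaults to the standard kernel at the
#'   aperture TR).
#' @return Numeric vector, one value per TR, in the units of
#'   \code{amplitude} about \code{baseline}.
#' @export
predict_timeseries <- function(prf, apertures, hrf = gam_hrf(tr_s = apertures$tr_s)) {
  ov <- rf_overlap_series(prf, apertures)
  prf$baseline + prf$amplitude * conv_truncate(ov, hrf$values)
}

#' Scale a raw voxel timeseries to percent signal change
#'
#' Divides the signal by its mean and multiplies by 100, so values read as a
#' percentage of the voxel's mean signal and the output mean is exactly 100.
#'
#' @param raw numeric vector of raw signal values with non-zero mean.
#' @return Numeric vector of the same length with mean 100.
#' @export
scale_to_psc <- function(raw) {
  stopifnot(is.numeric(raw), all(is.finite(raw)))
  m <- mean(raw)
  if (m == 0) stop("cannot scale a zero-mean timeseries to percent signal change")
  100 * raw / m
}
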