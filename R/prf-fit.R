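#' Candidate grid for pRF fitting
#'
#' The fit enumerates every combination of centre (x, y) and size (sigma)
#' on a regular grid. Centres span the full screen on each axis; sigma is
#' sampled at \code{n_sigma} even intervals over (0, \code{sigma_max_deg}]
#' (zero itself is excluded as degenerate). The \code{"full"} preset
#' (200 x 200 x 100 = 4,000,000 candidates) reproduces the full-fidelity
#' search of the AFNI-style fitter; the \code{"desk"} preset
#' (40 x 40 x 20 = 32,000) is the default for routine analysis and
#' simulation.
#'
#' @param preset \code{"desk"} or \code{"full"}, or \code{NULL} when the
#'   sizes are given explicitly.
#' @param n_x,n_y centre samples per axis.
#' @param n_sigma size samples.
#' @param sigma_max_deg largest sigma, in degrees; defaults to half the
#'   mapped extent at fit time when \code{NA}.
#' @return An object of class \code{grid_spec}.
#' @export
grid_spec <- function(preset = c("desk", "full"), n_x = NULL, n_y = NULL,
                      n_sigma = NULL, sigma_max_deg = NA_real_) {
  if (is.null(n_x)) {
    preset <- match.arg(preset)
    dims <- switch(preset, desk = c(40L, 40L, 20L), full = c(200L, 200L, 100L))
    n_x <- dims[1]; n_y <- dims[2]; n_sigma <- dims[3]
  } else {
    preset <- "custom"
    stopifnot(n_x >= 1, n_y >= 1, n_sigma >= 1)
  }
  structure(list(preset = preset, n_x = as.integer(n_x), n_y = as.integer(n_y),
                 n_sigma = as.integer(n_sigma), sigma_max_deg = sigma_max_deg),
            class = "grid_spec")
}

#' Total number of candidate pRFs a grid enumerates
#' @param grid a [grid_spec()].
#' @return \code{n_x * n_y * n_sigma} as a double (the full-fidelity preset
#'   exceeds the integer range comfortably countable in tests).
#' @export
n_candidates <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  as.numeric(grid$n_x) * grid$n_y * grid$n_sigma
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("pRF candidate grid (%s): %d x %d centres x %d sigmas = %s candidates\n",
              x$preset, x$n_x, x$n_y, x$n_sigma,
              format(n_candidates(x), big.mark = ",")))
  invisible(x)
}

# candidate parameter samples for a grid over a given field extent
.grid_samples <- function(grid, extent_deg) {
  smax <- if (is.na(grid$sigma_max_deg)) extent_deg / 2 else grid$sigma_max_deg
  list(x = seq(-extent_deg / 2, extent_deg / 2, length.out = grid$n_x),
       y = seq(-extent_deg / 2, extent_deg / 2, length.out = grid$n_y),
       sigma = seq_len(grid$n_sigma) / grid$n_sigma * smax,
       sigma_max = smax)
}

# Convolved candidate regressors for all centres at one sigma.
# Exploits separability of the isotropic Gaussian: the overlap
# sum(m * G) / sum(G) at TR t for centre (xi, yj) is
# gx_i' M_t gy_j / (sum gx_i * sum gy_j), computed for all centre pairs at
# once as t(Gx) %*% M_t %*% Gy. Returns an (n_x*n_y) x n_tr matrix of
# HRF-convolved overlaps; candidate order is x-fastest, then y.
.candidate_regressors <- function(apertures, hrf, xs, ys, sigma) {
  grid <- apertures$grid
  n_tr <- dim(apertures$masks)[3]
  Gx <- exp(-outer(grid$x, xs, "-")^2 / (2 * sigma^2))
  Gy <- exp(-outer(grid$y, ys, "-")^2 / (2 * sigma^2))
  denom <- as.vector(outer(colSums(Gx), colSums(Gy)))
  O <- matrix(0, length(xs) * length(ys), n_tr)
  for (t in seq_len(n_tr))
    O[, t] <- as.vector(crossprod(Gx, apertures$masks[, , t] %*% Gy))
  O <- O / denom
  O[denom == 0 | !is.finite(denom), ] <- 0
  H <- conv_matrix(hrf$values, n_tr)
  O %*% t(H)
}

#' Fit signed-amplitude 2-D Gaussian pRF models by grid search
#'
#' For every voxel timeseries, every candidate (x, y, sigma) on the grid is
#' scored: the candidate's HRF-convolved aperture-overlap regressor is fit
#' to the timeseries by closed-form least squares (amplitude and baseline
#' free, amplitude sign unconstrained), and the candidate with the highest
#' R-squared (1 - SS_res/SS_tot about the voxel mean) is returned. Ties are
#' broken by the lowest linear candidate index (sigma slowest, then y, then
#' x), so the fit is deterministic.
#'
#' @param y numeric vector (one voxel) or matrix (TRs x voxels) of mapping
#'   timeseries, typically in percent-signal-change units.
#' @param apertures the \code{aperture_sequence} the voxels were mapped with.
#' @param hrf hemodynamic kernel (default [gam_hrf()] at the aperture TR).
#' @param grid a [grid_spec()] (default the desk preset).
#' @return An object of class \code{prf_fit}: a per-voxel parameter table
#'   (see [coef.prf_fit()]) plus the inputs needed by \code{predict} and
#'   \code{residuals}. Voxels with constant timeseries are flagged invalid
#'   (\code{valid = FALSE}, \code{r2 = NA}).
#' @seealso [filter_suprathreshold()], [percent_negative()]
#' @examples
#' ap <- make_bar_masks(visual_field_grid(n_cells = 41), n_steps = 6)
#' y <- predict_timeseries(prf_model(2, 0, 1.5, amplitude = -0.8), ap)
#' fit <- fit_prf(y, ap, grid = grid_spec(n_x = 9, n_y = 9, n_sigma = 4))
#' coef(fit)
#' @export
fit_prf <- function(y, apertures, hrf = gam_hrf(tr_s = apertures$tr_s),
                    grid = grid_spec("desk")) {
  stopifnot(inherits(apertures, "aperture_sequence"),
            inherits(hrf, "hrf_kernel"), inherits(grid, "grid_spec"))
  Y <- as.matrix(y)
  n_tr <- dim(apertures$masks)[3]
  if (nrow(Y) != n_tr)
    stop("timeseries length (", nrow(Y), ") does not match the mapping design (",
         n_tr, " TRs)")
  n_vox <- ncol(Y)
  smp <- .grid_samples(grid, apertures$grid$extent_deg)

  y_mean <- colMeans(Y)
  Yc <- sweep(Y, 2, y_mean)
  y_ss <- colSums(Yc^2)
  valid <- y_ss > 0 & apply(is.finite(Y), 2, all)

  best <- list(r2 = rep(-Inf, n_vox), idx = rep(NA_integer_, n_vox),
               slope = rep(NA_real_, n_vox), pm = rep(NA_real_, n_vox))
  cand_x <- rep(smp$x, times = grid$n_y)
  cand_y <- rep(smp$y, each = grid$n_x)
  n_xy <- grid$n_x * grid$n_y

  for (si in seq_len(grid$n_sigma)) {
    P <- .candidate_regressors(apertures, hrf, smp$x, smp$y, smp$sigma[si])
    p_mean <- rowMeans(P)
    Pc <- P - p_mean
    p_ss <- rowSums(Pc^2)
    ok <- p_ss > 0
    cp <- Pc %*% Yc                       # candidates x voxels cross-products
    r2 <- cp^2 / outer(p_ss, y_ss)
    r2[!ok, ] <- 0
    r2[, !valid] <- 0
    top <- apply(r2, 2, which.max)        # first (lowest) index on ties
    top_r2 <- r2[cbind(top, seq_len(n_vox))]
    gain <- top_r2 > best$r2              # strict: earlier sigma wins ties
    if (any(gain)) {
      g <- which(gain)
      best$r2[g] <- top_r2[g]
      best$idx[g] <- (si - 1L) * n_xy + top[g]
      best$slope[g] <- cp[cbind(top[g], g)] / p_ss[top[g]]
      best$pm[g] <- p_mean[top[g]]
    }
  }

  xy_idx <- (best$idx - 1L) %% n_xy + 1L
  si_idx <- (best$idx - 1L) %/% n_xy + 1L
  par <- data.frame(
    voxel = colnames(Y) %||% sprintf("v%03d", seq_len(n_vox)),
    x_deg = cand_x[xy_idx], y_deg = cand_y[xy_idx],
    sigma_deg = smp$sigma[si_idx],
    amplitude = best$slope, baseline = y_mean - best$slope * best$pm,
    r2 = ifelse(valid, best$r2, NA_real_),
    cand_index = best$idx, valid = valid,
    stringsAsFactors = FALSE
  )
  par$x_deg[!valid] <- NA_real_
  par$y_deg[!valid] <- NA_real_
  par$sigma_deg[!valid] <- NA_real_
  par$amplitude[!valid] <- NA_real_

  structure(list(par = par, grid = grid, sigma_max_deg = smp$sigma_max,
                 apertures = apertures, hrf = hrf, y = Y),
            class = "prf_fit")
}

#' @export
print.prf_fit <- function(x, ...) {
  n <- nrow(x$par)
  cat("pRF grid fit:", n, "voxel(s),",
      format(n_candidates(x$grid), big.mark = ","), "candidates (",
      x$grid$preset, "grid )\n")
  ok <- x$par$valid
  if (any(ok))
    cat(sprintf("  amplitude sign: %d positive, %d negative; median R^2 = %.3f\n",
                sum(x$par$amplitude[ok] > 0), sum(x$par$amplitude[ok] < 0),
                stats::median(x$par$r2[ok])))
  if (any(!ok)) cat(" ", sum(!ok), "voxel(s) flagged invalid (constant input)\n")
  invisible(x)
}

#' @export
summary.prf_fit <- function(object, r2_min = 0.08, sigma_frac_max = 0.95, ...) {
  supra <- filter_suprathreshold(object, r2_min, sigma_frac_max, quiet = TRUE)
  out <- list(n_voxels = nrow(object$par),
              n_invalid = sum(!object$par$valid),
              n_suprathreshold = nrow(supra$par),
              r2_min = r2_min, sigma_frac_max = sigma_frac_max,
              percent_negative = if (nrow(supra$par) > 0)
                percent_negative(supra) else NA_real_)
  class(out) <- "summary.prf_fit"
  out
}

#' @export
print.summary.prf_fit <- function(x, ...) {
  cat("pRF fit summary\n")
  cat("  voxels:", x$n_voxels, "(", x$n_invalid, "invalid )\n")
  cat(sprintf("  suprathreshold (R^2 > %g, sigma <= %g of max): %d\n",
              x$r2_min, x$sigma_frac_max, x$n_suprathreshold))
  if (!is.na(x$percent_negative))
    cat(sprintf("  negative pRFs among suprathreshold: %.2f%%\n",
                x$percent_negative))
  invisible(x)
}

#' Per-voxel pRF parameter estimates
#' @param object a \code{prf_fit}.
#' @param ... unused.
#' @return Numeric matrix with columns \code{x_deg}, \code{y_deg},
#'   \code{sigma_deg}, \code{amplitude}, \code{baseline}, \code{r2}; one row
#'   per voxel.
#' @export
coef.prf_fit <- function(object, ...) {
  m <- as.matrix(object$par[, c("x_deg", "y_deg", "sigma_deg", "amplitude",
                                "baseline", "r2")])
  rownames(m) <- object$par$voxel
  m
}

#' Predicted timeseries of fitted pRFs
#' @param object a \code{prf_fit}.
#' @param apertures aperture sequence to predict for (default the one used
#'   in fitting).
#' @param ... unused.
#' @return Matrix of noiseless predictions, TRs x voxels (NA columns for
#'   invalid voxels).
#' @export
predict.prf_fit <- function(object, apertures = object$apertures, ...) {
  n_tr <- dim(apertures$masks)[3]
  out <- matrix(NA_real_, n_tr, nrow(object$par))
  colnames(out) <- object$par$voxel
  for (v in which(object$par$valid)) {
    p <- object$par[v, ]
    out[, v] <- predict_timeseries(
      prf_model(p$x_deg, p$y_deg, p$sigma_deg, p$amplitude, p$baseline),
      apertures, object$hrf)
  }
  out
}

#' @export
fitted.prf_fit <- function(object, ...) predict(object)

#' @export
residuals.prf_fit <- function(object, ...) object$y - fitted(object)

#' Visual-field coverage plot of a fitted population
#'
#' Draws each suprathreshold pRF centre in the visual field, coloured by
#' amplitude sign (red = positive, blue = negative), with symbol size
#' proportional to sigma and the circular stimulus aperture overlaid.
#'
#' @param x a \code{prf_fit}.
#' @param r2_min,sigma_frac_max suprathreshold filters applied before
#'   plotting (defaults as in [filter_suprathreshold()]).
#' @param ... passed to [graphics::plot()].
#' @export
plot.prf_fit <- function(x, r2_min = 0.08, sigma_frac_max = 0.95, ...) {
  supra <- filter_suprathreshold(x, r2_min, sigma_frac_max, quiet = TRUE)$par
  e <- x$apertures$grid$extent_deg / 2
  graphics::plot(NA, xlim = c(-e, e) * 1.1, ylim = c(-e, e) * 1.1, asp = 1,
                 xlab = "x (deg)", ylab = "y (deg)",
                 main = "pRF visual-field coverage", ...)
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(e * cos(th), e * sin(th), col = "grey60")
  if (nrow(supra) > 0)
    graphics::symbols(supra$x_deg, supra$y_deg, circles = supra$sigma_deg / 2,
                      inches = FALSE, add = TRUE,
                      fg = ifelse(supra$amplitude >= 0, "firebrick", "steelblue"))
  invisible(x)
}

#' Keep only suprathreshold pRFs
#'
#' A fitted pRF is suprathreshold when its fit quality exceeds the R-squared
#' floor strictly (\code{r2 > r2_min}) and its size does not exceed the
#' stated fraction of the maximum searched sigma
#' (\code{sigma_deg / sigma_max_deg <= sigma_frac_max}); oversized fits are
#' treated as capturing the whole display rather than a receptive field.
#' Invalid voxels are dropped.
#'
#' @param fit a \code{prf_fit}, or a data frame with columns
#'   \code{sigma_deg}, \code{amplitude}, \code{r2}.
#' @param r2_min R-squared floor (default 0.08, exceeded strictly).
#' @param sigma_frac_max largest admissible sigma as a fraction of the
#'   maximum searched sigma (default 0.95).
#' @param sigma_max_deg required when \code{fit} is a bare data frame.
#' @param quiet suppress the empty-survivor warning.
#' @return An object of the same kind as \code{fit}, restricted to the
#'   surviving voxels (possibly empty, with a warning).
#' @export
filter_suprathreshold <- function(fit, r2_min = 0.08, sigma_frac_max = 0.95,
                                  sigma_max_deg = NULL, quiet = FALSE) {
  if (inherits(fit, "prf_fit")) {
    par <- fit$par
    smax <- fit$sigma_max_deg
  } else {
    par <- as.data.frame(fit)
    if (is.null(sigma_max_deg))
      stop("sigma_max_deg must be given when filtering a bare data frame")
    smax <- sigma_max_deg
    if (is.null(par$valid)) par$valid <- rep(TRUE, nrow(par))
  }
  keep <- !is.na(par$r2) & par$valid & par$r2 > r2_min &
    par$sigma_deg / smax <= sigma_frac_max
  keep[is.na(keep)] <- FALSE
  if (!any(keep) && !quiet)
    warning("no pRFs survive the suprathreshold filter")
  if (inherits(fit, "prf_fit")) {
    out <- fit
    out$par <- par[keep, , drop = FALSE]
    out$y <- fit$y[, keep, drop = FALSE]
    out
  } else {
    par[keep, , drop = FALSE]
  }
}

#' Percentage of negative pRFs in a suprathreshold population
#'
#' @param pop a (filtered) \code{prf_fit} or a data frame with an
#'   \code{amplitude} column.
#' @return \code{100 * n(amplitude < 0) / n(total)}.
#' @export
percent_negative <- function(pop) {
  amp <- if (inherits(pop, "prf_fit")) pop$par$amplitude else pop$amplitude
  if (length(amp) == 0)
    stop("percent_negative is undefined for an empty population")
  100 * sum(amp < 0, na.rm = TRUE) / length(amp)
}

#' Amplitude-sign class of each pRF
#'
#' @param pop a \code{prf_fit} or data frame with \code{amplitude}.
#' @return Character vector, \code{"positive"} / \code{"negative"}; an exact
#'   zero amplitude belongs to neither class and is returned as \code{NA}.
#' @export
amplitude_class <- function(pop) {
  amp <- if (inherits(pop, "prf_fit")) pop$par$amplitude else pop$amplitude
  ifelse(amp > 0, "positive", ifelse(amp < 0, "negative", NA_character_))
}
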