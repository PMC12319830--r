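#' @title Synthetic voxel populations with tunable opponency
#' @name synthetic_data
#' @description Ground-truth generator for end-to-end validation. Voxel
#'   populations mix positive and negative pRFs; mapping runs follow the
#'   forward model exactly, and task runs carry a tunable degree of opponent
#'   visuospatial structure controlled by the opponency strength kappa.
NULL

#' Sample a ground-truth voxel population
#'
#' Centres are uniform within the circular stimulus aperture, sigmas and
#' amplitude magnitudes uniform within their ranges. Amplitude signs are
#' assigned so the negative fraction matches \code{frac_negative} exactly
#' (after rounding), then shuffled across voxels.
#'
#' @param n_voxels number of voxels (>= 2).
#' @param frac_negative target proportion of negative-amplitude voxels.
#' @param extent_deg mapped field extent in degrees (default 12).
#' @param sigma_range_deg range of true sigmas (default 0.5-3 deg).
#' @param amp_range range of amplitude magnitudes in percent-signal-change
#'   units (default 0.5-1.5).
#' @param noise_sd additive noise SD in percent-signal-change units
#'   (default 0.3).
#' @param kappa opponency strength in \code{[0, 1]}: 1 makes task responses
#'   fully determined by visuospatial tuning, 0 makes them pure noise.
#' @param noise_model \code{"white"} or \code{"ar1"}.
#' @param ar1_coef AR(1) coefficient when \code{noise_model = "ar1"}
#'   (default 0.3).
#' @param seed integer seed (required).
#' @return An object of class \code{opponency_ground_truth}: list with
#'   \code{prfs} (list of [prf_model()]), \code{truth} (data frame of true
#'   parameters incl. \code{sign}), and the generator settings.
#' @export
sample_population <- function(n_voxels, frac_negative = 125 / 300,
                              extent_deg = 12, sigma_range_deg = c(0.5, 3),
                              amp_range = c(0.5, 1.5), noise_sd = 0.3,
                              kappa = 1, noise_model = c("white", "ar1"),
                              ar1_coef = 0.3, seed) {
  stopifnot(!missing(seed), n_voxels >= 2, frac_negative >= 0,
            frac_negative <= 1, kappa >= 0, kappa <= 1, noise_sd >= 0,
            diff(sigma_range_deg) >= 0, diff(amp_range) >= 0,
            sigma_range_deg[1] > 0, amp_range[1] >= 0)
  noise_model <- match.arg(noise_model)
  n_neg <- round(n_voxels * frac_negative)
  if (frac_negative > 0 && frac_negative < 1 && (n_neg == 0 || n_neg == n_voxels))
    stop("population too small to contain at least one voxel of each sign ",
         "at frac_negative = ", frac_negative)
  set.seed(seed)
  # uniform within the circular aperture by radius^2 inversion
  r <- (extent_deg / 2) * sqrt(stats::runif(n_voxels))
  th <- stats::runif(n_voxels, 0, 2 * pi)
  sig <- stats::runif(n_voxels, sigma_range_deg[1], sigma_range_deg[2])
  amp <- stats::runif(n_voxels, amp_range[1], amp_range[2])
  sign <- sample(rep(c(-1, 1), c(n_neg, n_voxels - n_neg)))
  truth <- data.frame(voxel = sprintf("v%03d", seq_len(n_voxels)),
                      x_deg = r * cos(th), y_deg = r * sin(th),
                      sigma_deg = sig, amplitude = sign * amp, sign = sign,
                      stringsAsFactors = FALSE)
  prfs <- lapply(seq_len(n_voxels), function(i)
    prf_model(truth$x_deg[i], truth$y_deg[i], truth$sigma_deg[i],
              amplitude = truth$amplitude[i]))
  structure(list(prfs = prfs, truth = truth, n_voxels = n_voxels,
                 frac_negative = frac_negative, extent_deg = extent_deg,
                 kappa = kappa, noise_sd = noise_sd,
                 noise_model = noise_model, ar1_coef = ar1_coef, seed = seed),
            class = "opponency_ground_truth")
}

#' @export
print.opponency_ground_truth <- function(x, ...) {
  cat("Synthetic ground truth:", x$n_voxels, "voxels (",
      sum(x$truth$sign < 0), "negative ), kappa =", x$kappa,
      ", noise sd =", x$noise_sd, "(", x$noise_model, ")\n")
  invisible(x)
}

# noise matrix (TRs x voxels) under the population's noise model
.noise_matrix <- function(gt, n_tr, n_vox) {
  if (gt$noise_sd == 0) return(matrix(0, n_tr, n_vox))
  eps <- matrix(stats::rnorm(n_tr * n_vox), n_tr, n_vox)
  if (gt$noise_model == "ar1") {
    eps <- apply(eps, 2, function(e)
      stats::filter(e, gt$ar1_coef, method = "recursive"))
    eps <- eps * sqrt(1 - gt$ar1_coef^2)   # restore unit marginal variance
  }
  gt$noise_sd * eps
}

#' Simulate a mapping run for a ground-truth population
#'
#' Each voxel's series is its noiseless forward-model prediction (about a
#' baseline of 100, i.e. percent-signal-change units) plus noise drawn under
#' the population's noise model.
#'
#' @param gt an [sample_population()] ground truth.
#' @param apertures the \code{aperture_sequence} of the mapping run.
#' @param hrf hemodynamic kernel.
#' @param seed integer seed (required).
#' @return Matrix of timeseries, TRs x voxels, with attribute
#'   \code{"noiseless"} holding the noise-free predictions.
#' @export
simulate_mapping_run <- function(gt, apertures,
                                 hrf = gam_hrf(tr_s = apertures$tr_s), seed) {
  stopifnot(!missing(seed), inherits(gt, "opponency_ground_truth"))
  n_tr <- dim(apertures$masks)[3]
  clean <- vapply(gt$prfs, function(p) {
    p$baseline <- 100
    predict_timeseries(p, apertures, hrf)
  }, numeric(n_tr))
  colnames(clean) <- gt$truth$voxel
  set.seed(seed)
  out <- clean + .noise_matrix(gt, n_tr, ncol(clean))
  attr(out, "noiseless") <- clean
  out
}

#' Latent spatial activation maps for task-event labels
#'
#' Each distinct event label receives a random Gaussian activation bump
#' (centre uniform in the aperture, width uniform in
#' \code{bump_sigma_range}), clipped to the aperture. These latent fields
#' couple task responses to visuospatial tuning; they stand in for whatever
#' spatial footprint a remembered or perceived stimulus evokes.
#'
#' @param labels character vector of event labels (non-empty; duplicates
#'   collapsed).
#' @param grid a [visual_field_grid()].
#' @param bump_sigma_range bump width range in degrees (default 0.5-2).
#' @param seed integer seed (required).
#' @return Named list of non-negative \code{n_cells x n_cells} matrices.
#' @export
make_field_maps <- function(labels, grid, bump_sigma_range = c(0.5, 2), seed) {
  stopifnot(!missing(seed), length(labels) > 0)
  labels <- unique(labels)
  set.seed(seed)
  maps <- lapply(labels, function(l) {
    r <- (grid$extent_deg / 2) * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    s <- stats::runif(1, bump_sigma_range[1], bump_sigma_range[2])
    field_bump(grid, r * cos(th), r * sin(th), s)
  })
  names(maps) <- labels
  maps
}

#' Simulate an event-related task run with opponent structure
#'
#' Per voxel v and event e, the response amplitude is
#' \deqn{\beta_{v,e} = a_v [\kappa\, O(RF_v, S_e) + (1-\kappa)\,\eta_{v,e}]}
#' where \eqn{a_v} is the voxel's signed true amplitude, \eqn{O} the
#' normalised overlap of its receptive field with the event's latent field
#' map \eqn{S_e}, and \eqn{\eta \sim N(0,1)} i.i.d. Overlaps are normalised
#' per voxel across the event set (zero mean, unit variance), so the two
#' mixture components share a common scale and kappa acts as a clean mixing
#' weight; what a voxel's tuning contributes to an event response is its
#' relative preference among the events, not its absolute overlap (which
#' would otherwise impose one shared response envelope on every voxel and
#' confound receptive-field size with responsiveness). The neural series is the
#' sum of event boxcars scaled by beta (sampled at TR resolution with
#' fractional occupancy), convolved with the HRF, offset to a baseline of
#' 100 and degraded with measurement noise. At kappa = 1 with zero noise,
#' voxels sharing a receptive field but differing in sign respond in exact
#' antiphase.
#'
#' @param gt an [sample_population()] ground truth.
#' @param design one \code{event_design} data frame.
#' @param field_maps named list from [make_field_maps()] covering every
#'   design label.
#' @param grid the [visual_field_grid()] the maps live on.
#' @param hrf hemodynamic kernel.
#' @param seed integer seed (required).
#' @return Matrix of timeseries, TRs x voxels.
#' @export
simulate_task_run <- function(gt, design, field_maps, grid,
                              hrf = gam_hrf(tr_s = attr(design, "tr_s")), seed) {
  stopifnot(!missing(seed), inherits(gt, "opponency_ground_truth"))
  missing_maps <- setdiff(unique(design$label), names(field_maps))
  if (length(missing_maps) > 0)
    stop("no field map for label(s): ", paste(missing_maps, collapse = ", "))
  tr <- attr(design, "tr_s") %||% 2
  n_tr <- as.integer(ceiling(attr(design, "total_duration_s") / tr))
  n_vox <- gt$n_voxels
  n_ev <- nrow(design)

  # boxcar occupancy of each TR bin by each event (fractional at edges)
  B <- matrix(0, n_tr, n_ev)
  tr_start <- (seq_len(n_tr) - 1) * tr
  for (e in seq_len(n_ev)) {
    a <- design$onset_s[e]; b <- a + design$duration_s[e]
    ov <- pmin(b, tr_start + tr) - pmax(a, tr_start)
    B[, e] <- pmax(ov, 0) / tr
  }

  O <- rf_field_overlap(gt$prfs, field_maps, grid)   # voxels x labels
  # per-voxel standardisation across the label set; a voxel with no
  # appreciable overlap with any map carries no spatial drive
  O <- O - rowMeans(O)
  o_sd <- apply(O, 1, stats::sd)
  O <- O / ifelse(o_sd > 1e-12, o_sd, Inf)
  set.seed(seed)
  eta <- matrix(stats::rnorm(n_vox * n_ev), n_vox, n_ev)
  drive <- gt$kappa * O[, design$label, drop = FALSE] + (1 - gt$kappa) * eta
  beta <- gt$truth$amplitude * drive                 # voxels x events
  neural <- B %*% t(beta)                            # TRs x voxels
  bold <- 100 + conv_truncate(neural, hrf$values) +
    .noise_matrix(gt, n_tr, n_vox)
  colnames(bold) <- gt$truth$voxel
  bold
}

#' Simulate all runs of a task session and return per-run series
#'
#' Convenience wrapper: one [simulate_task_run()] per run with a distinct
#' sub-seed, sharing one set of field maps.
#'
#' @inheritParams simulate_task_run
#' @param designs list of \code{event_design} data frames (one per run).
#' @return List of TRs x voxels matrices, one per run.
#' @export
simulate_task_session <- function(gt, designs, field_maps, grid,
                                  hrf = gam_hrf(tr_s = attr(designs[[1]], "tr_s")),
                                  seed) {
  stopifnot(!missing(seed))
  lapply(seq_along(designs), function(r)
    simulate_task_run(gt, designs[[r]], field_maps, grid, hrf,
                      seed = seed + r))
}
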