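#' @title Bar-sweep mapping stimulus and event-related task designs
#' @name stimulus_design
#' @description Generators for the retinotopic mapping aperture sequence and
#'   the event schedules of the memory-recall and scene-perception sessions.
NULL

# canonical sweep directions: unit motion vector per token
.sweep_directions <- list(
  left_to_right             = c(1, 0),
  bottom_right_to_top_left  = c(-1, 1) / sqrt(2),
  top_to_bottom             = c(0, -1),
  bottom_left_to_top_right  = c(1, 1) / sqrt(2),
  right_to_left             = c(-1, 0),
  top_left_to_bottom_right  = c(1, -1) / sqrt(2),
  bottom_to_top             = c(0, 1),
  top_right_to_bottom_left  = c(-1, -1) / sqrt(2)
)

#' Default sweep order of the bar-mapping run
#'
#' Eight sweeps: four orientations, each traversed in both directions,
#' in the fixed order used for every mapping run.
#'
#' @return Character vector of 8 direction tokens.
#' @export
default_sweep_order <- function() {
  c("left_to_right", "bottom_right_to_top_left", "top_to_bottom",
    "bottom_left_to_top_right", "right_to_left", "top_left_to_bottom_right",
    "bottom_to_top", "top_right_to_bottom_left")
}

#' Generate the bar-aperture mask sequence for a mapping run
#'
#' A bar aperture traverses the visual field in a series of sweeps. Within
#' each sweep the bar takes \code{n_steps} evenly spaced steps, one per TR,
#' spanning the full extent of the screen along the motion axis; the bar is
#' oriented perpendicular to its direction of motion. All masks are clipped
#' to the circular aperture whose diameter equals the grid extent.
#'
#' @param grid a [visual_field_grid()].
#' @param n_steps steps (TRs) per sweep (default 18).
#' @param tr_s repetition time in seconds (default 2).
#' @param bar_width_deg bar width in degrees (default 2).
#' @param sweep_order character vector of direction tokens drawn from the 8
#'   canonical directions (default [default_sweep_order()]).
#' @param blank_trs_between_sweeps TRs of blank screen inserted after each
#'   sweep (default 0; the canonical design has contiguous sweeps).
#' @return An object of class \code{aperture_sequence}: list with
#'   \code{masks} (\code{n_cells x n_cells x n_tr} binary array),
#'   \code{grid}, \code{tr_s}, \code{sweep_order}, \code{sweep_index}
#'   (integer per TR, \code{NA} for blanks) and \code{step_index}.
#' @export
make_bar_masks <- function(grid = visual_field_grid(), n_steps = 18L,
                           tr_s = 2, bar_width_deg = 2,
                           sweep_order = default_sweep_order(),
                           blank_trs_between_sweeps = 0L) {
  stopifnot(inherits(grid, "visual_field_grid"), n_steps >= 2,
            bar_width_deg > 0, tr_s > 0)
  unknown <- setdiff(sweep_order, names(.sweep_directions))
  if (length(unknown) > 0)
    stop("unknown sweep direction token(s): ", paste(unknown, collapse = ", "),
         "; valid tokens are: ", paste(names(.sweep_directions), collapse = ", "))
  if (bar_width_deg > grid$extent_deg)
    stop("bar_width_deg (", bar_width_deg, ") exceeds the grid extent (",
         grid$extent_deg, ")")

  half <- grid$extent_deg / 2
  steps <- seq(-half, half, length.out = n_steps)
  nb <- as.integer(blank_trs_between_sweeps)
  per_sweep <- n_steps + nb
  n_tr <- length(sweep_order) * per_sweep
  masks <- array(0L, dim = c(grid$n_cells, grid$n_cells, n_tr))
  sweep_index <- rep(NA_integer_, n_tr)
  step_index <- rep(NA_integer_, n_tr)

  # projection of every cell centre onto a motion axis is separable in x, y
  for (s in seq_along(sweep_order)) {
    u <- .sweep_directions[[sweep_order[s]]]
    proj <- outer(grid$x * u[1], grid$y * u[2], "+")
    for (k in seq_len(n_steps)) {
      m <- (abs(proj - steps[k]) <= bar_width_deg / 2) & grid$in_aperture
      t_idx <- (s - 1L) * per_sweep + k
      masks[, , t_idx] <- m + 0L
      sweep_index[t_idx] <- s
      step_index[t_idx] <- k
    }
  }
  structure(
    list(masks = masks, grid = grid, tr_s = tr_s, n_steps = as.integer(n_steps),
         bar_width_deg = bar_width_deg, sweep_order = sweep_order,
         sweep_index = sweep_index, step_index = step_index),
    class = "aperture_sequence"
  )
}

#' @export
print.aperture_sequence <- function(x, ...) {
  cat("Bar-aperture sequence:", length(x$sweep_order), "sweeps x",
      x$n_steps, "steps =", dim(x$masks)[3], "TRs (TR =", x$tr_s, "s)\n")
  cat("  field:", x$grid$extent_deg, "deg extent,", x$grid$n_cells,
      "cells/axis; bar width", x$bar_width_deg, "deg\n")
  invisible(x)
}

#' Number of TRs in an aperture sequence
#' @param apertures an \code{aperture_sequence}.
#' @return Integer TR count.
#' @export
n_trs <- function(apertures) dim(apertures$masks)[3]

# shared machinery: one run of shuffled events with jittered ITIs.
# Events start after an initial ITI; the run ends one trailing ITI after the
# final event, rounded up to a whole TR.
.event_run <- function(labels, dur_s, iti_range_s, run_id, tr_s = 2) {
  n <- length(labels)
  order <- sample.int(n)
  itis <- stats::runif(n + 1L, iti_range_s[1], iti_range_s[2])
  onsets <- cumsum(c(itis[1], rep(dur_s, n - 1) + itis[2:n]))
  total <- onsets[n] + dur_s + itis[n + 1L]
  total <- ceiling(total / tr_s) * tr_s
  design <- data.frame(run = run_id, onset_s = onsets, duration_s = dur_s,
                       label = labels[order], stringsAsFactors = FALSE)
  attr(design, "total_duration_s") <- total
  attr(design, "tr_s") <- tr_s
  class(design) <- c("event_design", "data.frame")
  design
}

#' Event schedule for the memory-recall session
#'
#' Each run presents every item \code{reps_per_run} times in seeded random
#' order. A trial is a brief word cue followed by a sustained covert-recall
#' period, modelled as a single event of duration \code{cue_s + recall_s};
#' inter-trial intervals are drawn uniformly from \code{iti_range_s}.
#'
#' @param n_items number of distinct recall items (default 12).
#' @param reps_per_run repetitions of each item per run (default 2).
#' @param n_runs number of runs (default 6).
#' @param cue_s cue duration in seconds (default 0.5).
#' @param recall_s recall-period duration in seconds (default 9.5).
#' @param iti_range_s inter-trial-interval range in seconds (default 2.5-7).
#' @param seed integer seed (required).
#' @return A list of \code{event_design} data frames (one per run) with
#'   columns \code{run}, \code{onset_s}, \code{duration_s}, \code{label} and
#'   a \code{total_duration_s} attribute.
#' @export
make_recall_design <- function(n_items = 12L, reps_per_run = 2L, n_runs = 6L,
                               cue_s = 0.5, recall_s = 9.5,
                               iti_range_s = c(2.5, 7), seed) {
  stopifnot(!missing(seed), length(iti_range_s) == 2,
            iti_range_s[1] <= iti_range_s[2], iti_range_s[1] >= 0)
  if (n_items < 1 || n_runs < 1 || reps_per_run < 1)
    stop("n_items, reps_per_run and n_runs must all be positive")
  labels <- rep(sprintf("item_%02d", seq_len(n_items)), each = reps_per_run)
  set.seed(seed)
  lapply(seq_len(n_runs), function(r)
    .event_run(labels, cue_s + recall_s, iti_range_s, r))
}

#' Event schedule for the slow event-related perception session
#'
#' Each run presents every stimulus exactly once, briefly, in seeded random
#' order with jittered inter-stimulus intervals.
#'
#' @param n_stimuli number of distinct stimuli (default 96).
#' @param dur_s stimulus duration in seconds (default 0.5).
#' @param isi_range_s inter-stimulus-interval range in seconds (default 3-7).
#' @param n_runs number of runs (default 2).
#' @param seed integer seed (required).
#' @return A list of \code{event_design} data frames, as
#'   [make_recall_design()].
#' @export
make_perception_design <- function(n_stimuli = 96L, dur_s = 0.5,
                                   isi_range_s = c(3, 7), n_runs = 2L, seed) {
  stopifnot(!missing(seed), length(isi_range_s) == 2,
            isi_range_s[1] <= isi_range_s[2], isi_range_s[1] >= 0)
  if (n_stimuli < 1 || n_runs < 1)
    stop("n_stimuli and n_runs must be positive")
  labels <- sprintf("stim_%03d", seq_len(n_stimuli))
  set.seed(seed)
  lapply(seq_len(n_runs), function(r)
    .event_run(labels, dur_s, isi_range_s, r))
}

#' Write a list of event designs to CSV
#'
#' @param designs list of \code{event_design} data frames.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_design_csv <- function(designs, path) {
  all <- do.call(rbind, lapply(designs, as.data.frame))
  utils::write.csv(all[, c("run", "onset_s", "duration_s", "label")],
                   path, row.names = FALSE)
  invisible(path)
}
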