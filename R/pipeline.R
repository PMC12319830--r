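#' Configuration for an end-to-end opponency pipeline run
#'
#' Collects every tunable of the simulate - fit - filter - RDM - match -
#' bootstrap chain with validated defaults. Per-stage seeds are derived
#' deterministically from the master seed via [stage_seed()] so stages can
#' be reproduced in isolation.
#'
#' @param seed master integer seed.
#' @param n_voxels synthetic population size (default 120).
#' @param frac_negative target negative fraction (default 125/300).
#' @param kappa opponency strength in \code{[0, 1]} (default 1).
#' @param noise_sd noise SD in percent-signal-change units (default 0.3).
#' @param noise_model \code{"white"} or \code{"ar1"}.
#' @param grid_preset candidate grid preset, \code{"desk"} or \code{"full"}.
#' @param n_cells raster cells per axis (default 101).
#' @param extent_deg field extent in degrees (default 12).
#' @param rdm_method RDM-RDM correlation, \code{"pearson"} or
#'   \code{"spearman"}.
#' @param n_iter_match,n_iter_boot iteration counts (defaults 1000).
#' @param recall_runs,perception_runs run counts (defaults 6 and 2).
#' @return A validated list of class \code{opponency_config}.
#' @export
opponency_config <- function(seed = 1L, n_voxels = 120L,
                             frac_negative = 125 / 300, kappa = 1,
                             noise_sd = 0.3,
                             noise_model = c("white", "ar1"),
                             grid_preset = c("desk", "full"),
                             n_cells = 101L, extent_deg = 12,
                             rdm_method = c("pearson", "spearman"),
                             n_iter_match = 1000L, n_iter_boot = 1000L,
                             recall_runs = 6L, perception_runs = 2L) {
  noise_model <- match.arg(noise_model)
  grid_preset <- match.arg(grid_preset)
  rdm_method <- match.arg(rdm_method)
  stopifnot(n_voxels >= 4, kappa >= 0, kappa <= 1, noise_sd >= 0,
            frac_negative > 0, frac_negative < 1,
            n_iter_match >= 1, n_iter_boot >= 1,
            recall_runs >= 2, perception_runs >= 1)
  cfg <- list(seed = as.integer(seed), n_voxels = as.integer(n_voxels),
              frac_negative = frac_negative, kappa = kappa,
              noise_sd = noise_sd, noise_model = noise_model,
              grid_preset = grid_preset, n_cells = as.integer(n_cells),
              extent_deg = extent_deg, rdm_method = rdm_method,
              n_iter_match = as.integer(n_iter_match),
              n_iter_boot = as.integer(n_iter_boot),
              recall_runs = as.integer(recall_runs),
              perception_runs = as.integer(perception_runs))
  cfg$stage_seeds <- vapply(
    c("population", "mapping", "recall", "perception", "fields_recall",
      "fields_perception", "matching", "bootstrap"),
    function(s) stage_seed(cfg$seed, s), integer(1))
  class(cfg) <- "opponency_config"
  cfg
}

#' Run the full opponency analysis on synthetic data
#'
#' Executes, in order: stimulus/design generation, ground-truth population
#' sampling, mapping-run simulation, pRF grid fitting, suprathreshold
#' filtering and sign classification, task-session simulation (recall and
#' perception), cross-RDM construction and correlation (with per-run
#' test-retest for recall), the visuospatial matching analysis, and the
#' label-shuffle bootstrap. All stages are seeded from the config.
#'
#' @param config an [opponency_config()].
#' @param out_dir optional directory; when given, tidy CSV tables of every
#'   stage output are written there.
#' @return An object of class \code{opponency_manifest} holding all stage
#'   results, the config, and (when written) the output paths.
#' @export
run_opponency_pipeline <- function(config = opponency_config(),
                                   out_dir = NULL) {
  stopifnot(inherits(config, "opponency_config"))
  ss <- config$stage_seeds
  t0 <- Sys.time()

  grid <- visual_field_grid(config$extent_deg, config$n_cells)
  apertures <- make_bar_masks(grid)
  hrf <- gam_hrf(tr_s = apertures$tr_s)
  recall_design <- make_recall_design(n_runs = config$recall_runs,
                                      seed = ss[["recall"]])
  percept_design <- make_perception_design(n_runs = config$perception_runs,
                                           seed = ss[["perception"]])

  gt <- sample_population(config$n_voxels, config$frac_negative,
                          config$extent_deg, noise_sd = config$noise_sd,
                          kappa = config$kappa,
                          noise_model = config$noise_model,
                          seed = ss[["population"]])
  mapping <- simulate_mapping_run(gt, apertures, hrf, seed = ss[["mapping"]])

  fit <- fit_prf(mapping, apertures, hrf, grid_spec(config$grid_preset))
  supra <- filter_suprathreshold(fit)
  if (nrow(supra$par) < 4 || length(unique(sign(supra$par$amplitude))) < 2)
    stop("pipeline aborted at stage 'filter': too few suprathreshold pRFs ",
         "of each sign (", nrow(supra$par), " survivors)")
  sgn <- ifelse(supra$par$amplitude > 0, 1, -1)
  keep <- supra$par$voxel
  pct_neg <- percent_negative(supra)

  run_task <- function(designs, field_seed, task_seed) {
    maps <- make_field_maps(unique(designs[[1]]$label), grid,
                            seed = field_seed)
    series <- simulate_task_session(gt, designs, maps, grid, hrf,
                                    seed = task_seed)
    lapply(series, function(m) m[, keep, drop = FALSE])
  }
  recall_series <- run_task(recall_design, ss[["fields_recall"]],
                            ss[["recall"]] + 1000L)
  percept_series <- run_task(percept_design, ss[["fields_perception"]],
                             ss[["perception"]] + 1000L)

  map_series <- supra$y
  pos <- sgn > 0
  prf_rdm <- build_cross_rdm(map_series[, pos, drop = FALSE],
                             map_series[, !pos, drop = FALSE],
                             session = "mapping")
  rdm_for <- function(series_list, session) {
    per_run <- lapply(seq_along(series_list), function(r)
      build_cross_rdm(series_list[[r]][, pos, drop = FALSE],
                      series_list[[r]][, !pos, drop = FALSE],
                      session = session, run = r))
    list(per_run = per_run, average = average_rdms(per_run))
  }
  recall_rdms <- rdm_for(recall_series, "recall")
  percept_rdms <- rdm_for(percept_series, "perception")

  cor_recall <- correlate_rdms(prf_rdm, recall_rdms$average, config$rdm_method)
  cor_percept <- correlate_rdms(prf_rdm, percept_rdms$average, config$rdm_method)
  retest <- test_retest(prf_rdm, recall_rdms$per_run, config$rdm_method)

  pairs <- select_pairs(map_series, sgn)
  match_recall <- matching_analysis(pairs, do.call(rbind, recall_series),
                                    config$n_iter_match, ss[["matching"]])
  match_percept <- matching_analysis(pairs, do.call(rbind, percept_series),
                                     config$n_iter_match, ss[["matching"]] + 1L)

  boot_recall <- bootstrap_null(map_series, recall_series, sgn,
                                config$n_iter_boot, ss[["bootstrap"]],
                                config$rdm_method)

  manifest <- structure(list(
    config = config,
    truth = gt$truth,
    fit = fit,
    suprathreshold = supra$par,
    percent_negative = pct_neg,
    prf_rdm = prf_rdm,
    correlations = data.frame(
      session = c("recall", "perception",
                  paste0("recall_run", seq_along(retest))),
      run = c("average", "average", seq_along(retest)),
      r = c(cor_recall$r, cor_percept$r, vapply(retest, `[[`, 0, "r")),
      z = c(cor_recall$z, cor_percept$z, vapply(retest, `[[`, 0, "z")),
      n_entries = cor_recall$n_entries, stringsAsFactors = FALSE),
    matching = rbind(
      data.frame(session = "recall", scheme = names(match_recall$mean_r),
                 mean_r = unname(match_recall$mean_r)),
      data.frame(session = "perception", scheme = names(match_percept$mean_r),
                 mean_r = unname(match_percept$mean_r))),
    matching_detail = list(recall = match_recall, perception = match_percept),
    bootstrap = boot_recall,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    paths = NULL), class = "opponency_manifest")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    utils::write.csv(gt$truth, p("ground_truth.csv"), row.names = FALSE)
    utils::write.csv(fit$par, p("prf_fits.csv"), row.names = FALSE)
    utils::write.csv(manifest$correlations, p("rdm_correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(manifest$matching, p("matching.csv"), row.names = FALSE)
    utils::write.csv(data.frame(iter = seq_along(boot_recall$null_z),
                                null_z = boot_recall$null_z),
                     p("bootstrap_null.csv"), row.names = FALSE)
    write_design_csv(recall_design, p("design_recall.csv"))
    write_design_csv(percept_design, p("design_perception.csv"))
    manifest$paths <- vapply(c("ground_truth.csv", "prf_fits.csv",
                               "rdm_correlations.csv", "matching.csv",
                               "bootstrap_null.csv", "design_recall.csv",
                               "design_perception.csv"), p, character(1))
  }
  manifest
}

#' @export
print.opponency_manifest <- function(x, ...) {
  cat("Opponency pipeline run (seed", x$config$seed, ",",
      x$config$n_voxels, "voxels, kappa =", x$config$kappa, ")\n")
  cat(sprintf("  suprathreshold pRFs: %d (%.1f%% negative)\n",
              nrow(x$suprathreshold), x$percent_negative))
  avg <- x$correlations[x$correlations$run == "average", ]
  for (i in seq_len(nrow(avg)))
    cat(sprintf("  pRF-RDM vs %s-RDM: r = %.3f (z = %.3f)\n",
                avg$session[i], avg$r[i], avg$z[i]))
  cat(sprintf("  bootstrap: observed z at percentile %.1f of %d-shuffle null\n",
              x$bootstrap$percentile, x$bootstrap$n_iter))
  invisible(x)
}

#' Write a plain-text report of a pipeline run
#'
#' Summarises, per stage: the percentage of negative pRFs, the RDM
#' correlations (average and per recall run), the matched / unmatched /
#' random task correlations, the bootstrap outcome, and the per-stage seeds.
#' Every number in the report is taken from the manifest tables it
#' summarises.
#'
#' @param manifest an \code{opponency_manifest}.
#' @param path output file (default prints to the console).
#' @return The report lines, invisibly.
#' @export
write_report <- function(manifest, path = NULL) {
  stopifnot(inherits(manifest, "opponency_manifest"))
  cfg <- manifest$config
  fmt <- function(...) sprintf(...)
  lines <- c(
    "# Opponent visuospatial coding - pipeline report", "",
    fmt("Master seed: %d | voxels: %d | kappa: %.2f | noise sd: %.2f (%s)",
        cfg$seed, cfg$n_voxels, cfg$kappa, cfg$noise_sd, cfg$noise_model),
    fmt("Grid preset: %s | RDM correlation: %s", cfg$grid_preset,
        cfg$rdm_method), "",
    "## Stage seeds",
    paste0("- ", names(cfg$stage_seeds), ": ", cfg$stage_seeds), "",
    "## pRF population",
    fmt("- suprathreshold pRFs: %d of %d simulated voxels",
        nrow(manifest$suprathreshold), cfg$n_voxels),
    fmt("- negative pRFs: %.2f%%", manifest$percent_negative), "",
    "## RDM correlations (pRF vs task)")
  cr <- manifest$correlations
  lines <- c(lines,
             vapply(seq_len(nrow(cr)), function(i)
               fmt("- %s (run %s): r = %.4f, z = %.4f", cr$session[i],
                   cr$run[i], cr$r[i], cr$z[i]), character(1)), "")
  if (nrow(manifest$matching) > 0) {
    lines <- c(lines, "## Visuospatial matching (mean task-series r)",
               vapply(seq_len(nrow(manifest$matching)), function(i)
                 fmt("- %s / %s: %+.4f", manifest$matching$session[i],
                     manifest$matching$scheme[i],
                     manifest$matching$mean_r[i]), character(1)), "")
  } else {
    lines <- c(lines, "## Visuospatial matching",
               "- stage skipped: no matching results in manifest", "")
  }
  b <- manifest$bootstrap
  lines <- c(lines, "## Bootstrap (label shuffle, recall)",
             fmt("- observed z = %.4f at percentile %.1f of the %d-iteration null",
                 b$observed_z, b$percentile, b$n_iter),
             fmt("- null mean z = %.4f; t vs null mean: t = %.2f, p = %.3g",
                 mean(b$null_z), b$t_vs_null_mean["t"], b$t_vs_null_mean["p"]),
             "")
  if (!is.null(path)) writeLines(lines, path) else cat(lines, sep = "\n")
  invisible(lines)
}
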