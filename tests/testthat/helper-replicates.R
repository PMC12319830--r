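# Seeded replicate machinery shared by the structure-recovery and matching
# acceptance checks. Results are cached so several test blocks can reuse the
# same replicate set without recomputing.

.rep_cache <- new.env(parent = emptyenv())

# One synthetic "participant": sample a population, simulate mapping and the
# recall session, and return the RDM correlation (using true sign labels),
# optionally the bootstrap null quantiles and the matching-scheme means.
opponency_replicate <- function(seed, kappa, noise_sd = 0.3, n_vox = 32L,
                                n_null = 0L, do_match = FALSE,
                                apertures = default_apertures,
                                hrf = default_hrf) {
  grid <- apertures$grid
  gt <- sample_population(n_vox, kappa = kappa, noise_sd = noise_sd,
                          seed = seed)
  mapping <- simulate_mapping_run(gt, apertures, hrf, seed = seed + 1e6)
  des <- make_recall_design(seed = seed + 2e6)
  maps <- make_field_maps(unique(des[[1]]$label), grid, seed = seed + 3e6)
  series <- simulate_task_session(gt, des, maps, grid, hrf, seed = seed + 4e6)
  sgn <- gt$truth$sign
  pos <- sgn > 0
  prf_rdm <- build_cross_rdm(mapping[, pos], mapping[, !pos])
  avg <- average_rdms(lapply(series, function(m)
    build_cross_rdm(m[, pos], m[, !pos])))
  out <- c(z = correlate_rdms(prf_rdm, avg)$z)
  if (n_null > 0) {
    bn <- bootstrap_null(mapping, series, sgn, n_iter = n_null,
                         seed = seed + 5e6)
    out <- c(out,
             null_lo = unname(stats::quantile(bn$null_z, 0.025)),
             null_hi = unname(stats::quantile(bn$null_z, 0.975)),
             null_q95 = unname(stats::quantile(bn$null_z, 0.95)))
  }
  if (do_match) {
    pr <- select_pairs(mapping, sgn)
    ma <- matching_analysis(pr, do.call(rbind, series), n_iter = 200L,
                            seed = seed + 6e6)
    out <- c(out, ma$mean_r)
  }
  out
}

replicate_set <- function(key, seeds, ...) {
  if (is.null(.rep_cache[[key]]))
    .rep_cache[[key]] <- t(sapply(seeds, function(s)
      opponency_replicate(s, ...)))
  .rep_cache[[key]]
}

# 100 replicates at full opponency and at zero opponency, shared across
# acceptance blocks
kappa1_replicates <- function()
  replicate_set("kappa1", 301:400, kappa = 1, noise_sd = 0.3, do_match = TRUE)

kappa0_replicates <- function()
  replicate_set("kappa0", 1:100, kappa = 0, noise_sd = 0.3, n_null = 200L)
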