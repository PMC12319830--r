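#' @title Visuospatial matching analysis and label-shuffle bootstrap
#' @name matching_bootstrap
#' @description Controls for the RDM correlation: (i) pair every negative
#'   pRF with its best-matched, worst-matched, and randomly chosen partners
#'   (defined on the mapping timeseries) and compare their correlations on
#'   independent task timeseries; (ii) a permutation null that shuffles the
#'   positive/negative labels before rebuilding both RDMs.
NULL

# validate a +/-1 sign vector against a series matrix
.check_signs <- function(series, sign) {
  stopifnot(is.matrix(series), length(sign) == ncol(series),
            all(sign %in% c(-1, 1)))
}

#' Best- and worst-matched positive partner for every negative pRF
#'
#' Perfectly matched opponent pairs have perfectly anticorrelated mapping
#' timeseries, so for each negative voxel the best visuospatial match is the
#' positive voxel whose mapping series is most anticorrelated with it
#' (minimum Pearson r) and the worst match the most positively correlated
#' one (maximum r). Ties break to the lowest voxel index.
#'
#' @param mapping_series matrix (TRs x voxels) of mapping timeseries.
#' @param sign vector of +1/-1 amplitude signs, one per voxel.
#' @return Data frame with one row per negative voxel: \code{neg} (its
#'   column index), \code{matched} and \code{unmatched} (column indices of
#'   the selected positive voxels), and the corresponding mapping
#'   correlations \code{r_matched}, \code{r_unmatched}.
#' @export
select_pairs <- function(mapping_series, sign) {
  .check_signs(mapping_series, sign)
  pos <- which(sign > 0); neg <- which(sign < 0)
  if (length(pos) == 0) stop("no positive pRFs to match against")
  if (length(neg) == 0) stop("no negative pRFs to match")
  R <- stats::cor(mapping_series[, neg, drop = FALSE],
                  mapping_series[, pos, drop = FALSE])  # neg x pos
  i_min <- apply(R, 1, which.min)   # first index on ties
  i_max <- apply(R, 1, which.max)
  data.frame(neg = neg, matched = pos[i_min], unmatched = pos[i_max],
             r_matched = R[cbind(seq_along(neg), i_min)],
             r_unmatched = R[cbind(seq_along(neg), i_max)])
}

#' Matched / unmatched / random pairing correlations on task timeseries
#'
#' Evaluates the pairings chosen on the mapping data against an independent
#' task session. For each negative voxel the task-series Pearson r with its
#' matched and unmatched partner is averaged across voxels; the random
#' scheme draws, per iteration and per negative voxel, a uniformly random
#' other voxel of either sign (never the voxel itself), averages within the
#' iteration, then across \code{n_iter} iterations.
#'
#' @param pairs pairing table from [select_pairs()].
#' @param task_series matrix (TRs x voxels) of task timeseries, same voxel
#'   ordering as the mapping series the pairs were selected on.
#' @param n_iter random-scheme iterations (default 1000).
#' @param seed integer seed (required).
#' @return An object of class \code{matching_result}: list with
#'   \code{mean_r} (named vector: matched, unmatched, random),
#'   \code{per_voxel} (matched/unmatched task r per negative voxel),
#'   \code{random_iters} (per-iteration random means) and \code{pairs}.
#' @export
matching_analysis <- function(pairs, task_series, n_iter = 1000L, seed) {
  stopifnot(!missing(seed), n_iter >= 1, is.matrix(task_series))
  n_vox <- ncol(task_series)
  if (n_vox < 2) stop("need at least two voxels for the random scheme")
  sds <- apply(task_series, 2, stats::sd)
  degenerate <- which(sds == 0 | !is.finite(sds))
  keep <- !(pairs$neg %in% degenerate) & !(pairs$matched %in% degenerate) &
    !(pairs$unmatched %in% degenerate)
  if (any(!keep))
    warning("dropping ", sum(!keep), " negative voxel(s) with degenerate ",
            "task series (rows: ", paste(which(!keep), collapse = ", "), ")")
  pr <- pairs[keep, , drop = FALSE]
  if (nrow(pr) == 0) stop("no usable negative voxels left")

  C <- suppressWarnings(stats::cor(task_series))
  r_matched <- C[cbind(pr$matched, pr$neg)]
  r_unmatched <- C[cbind(pr$unmatched, pr$neg)]

  ok_partner <- setdiff(seq_len(n_vox), degenerate)
  set.seed(seed)
  random_iters <- vapply(seq_len(n_iter), function(i) {
    partners <- vapply(pr$neg, function(v) {
      cand <- ok_partner[ok_partner != v]
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    mean(C[cbind(partners, pr$neg)])
  }, numeric(1))

  structure(list(
    mean_r = c(matched = mean(r_matched), unmatched = mean(r_unmatched),
               random = mean(random_iters)),
    per_voxel = data.frame(neg = pr$neg, r_matched = r_matched,
                           r_unmatched = r_unmatched),
    random_iters = random_iters, n_iter = as.integer(n_iter),
    pairs = pr, seed = seed),
    class = "matching_result")
}

#' @export
print.matching_result <- function(x, ...) {
  cat("Visuospatial matching analysis (", nrow(x$per_voxel),
      "negative voxels,", x$n_iter, "random iterations )\n")
  cat(sprintf("  mean task r: matched = %+.3f, random = %+.3f, unmatched = %+.3f\n",
              x$mean_r["matched"], x$mean_r["random"], x$mean_r["unmatched"]))
  invisible(x)
}

#' Label-shuffle bootstrap null for the RDM correlation
#'
#' Permutes the positive/negative labels across all suprathreshold voxels
#' (class sizes preserved exactly), rebuilds the mapping and task cross-RDMs
#' under the shuffled labels, and recomputes the RDM correlation, yielding a
#' null distribution for the observed (unshuffled) value. Because RDM
#' entries are pairwise series correlations, the full voxel-by-voxel
#' correlation matrix is computed once per session and each shuffle merely
#' re-indexes it; this is exactly equivalent to rebuilding the RDMs from the
#' raw series.
#'
#' @param mapping_series matrix (TRs x voxels) of mapping timeseries.
#' @param task_series matrix of task timeseries (same voxel ordering), or a
#'   list of per-run matrices, in which case the task RDM entries are the
#'   across-run average of the per-run dissimilarities (matching the
#'   run-averaged RDM used in the observed correlation).
#' @param sign vector of +1/-1 signs (>= 2 voxels per class).
#' @param n_iter number of shuffles (default 1000).
#' @param seed integer seed (required).
#' @param method correlation between RDMs, as [correlate_rdms()].
#' @return An object of class \code{bootstrap_null}: list with
#'   \code{observed_z}, \code{observed_r}, \code{null_z} (length
#'   \code{n_iter}), the empirical \code{percentile} of the observed z in
#'   the null, and a one-sample \code{t} test of the observed value against
#'   the null mean.
#' @export
bootstrap_null <- function(mapping_series, task_series, sign, n_iter = 1000L,
                           seed, method = c("pearson", "spearman")) {
  stopifnot(!missing(seed), n_iter >= 1)
  method <- match.arg(method)
  .check_signs(mapping_series, sign)
  if (!is.list(task_series)) task_series <- list(task_series)
  for (ts in task_series) .check_signs(ts, sign)
  if (sum(sign > 0) < 2 || sum(sign < 0) < 2)
    stop("need at least 2 voxels per class to shuffle labels")

  Cm <- stats::cor(mapping_series)
  Ct <- Reduce(`+`, lapply(task_series, stats::cor)) / length(task_series)
  z_for <- function(lab) {
    p <- which(lab > 0); n <- which(lab < 0)
    a <- as.vector(1 - Cm[p, n]); b <- as.vector(1 - Ct[p, n])
    fisher_z(stats::cor(a, b, method = method))
  }
  observed_z <- z_for(sign)

  set.seed(seed)
  null_z <- vapply(seq_len(n_iter), function(i) z_for(sample(sign)), numeric(1))

  tt <- stats::t.test(null_z, mu = observed_z)
  structure(list(observed_z = observed_z, observed_r = tanh(observed_z),
                 null_z = null_z, n_iter = as.integer(n_iter), seed = seed,
                 percentile = mean(null_z < observed_z) * 100,
                 t_vs_null_mean = c(t = unname(tt$statistic),
                                    df = unname(tt$parameter),
                                    p = tt$p.value)),
            class = "bootstrap_null")
}

#' @export
print.bootstrap_null <- function(x, ...) {
  cat("Label-shuffle bootstrap (", x$n_iter, "iterations )\n")
  cat(sprintf("  observed z = %.4f (empirical percentile %.1f of null)\n",
              x$observed_z, x$percentile))
  cat(sprintf("  null z: mean %.4f, 95%% central interval [%.4f, %.4f]\n",
              mean(x$null_z), stats::quantile(x$null_z, 0.025),
              stats::quantile(x$null_z, 0.975)))
  invisible(x)
}
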