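#' @title Positive-by-negative cross representational dissimilarity analysis
#' @name opponent_rdm
#' @description The headline analysis: a rectangular RDM of timeseries
#'   dissimilarities (1 - Pearson r) between every positive and every
#'   negative pRF, built per session, then correlated between the mapping
#'   session and independent task sessions.
NULL

# drop constant-series columns with a warning naming them
.drop_constant <- function(M, what) {
  sds <- apply(M, 2, stats::sd)
  bad <- which(!is.finite(sds) | sds == 0)
  if (length(bad) > 0) {
    warning("dropping ", length(bad), " constant/non-finite ", what,
            " series (indices: ", paste(bad, collapse = ", "), ")")
    M <- M[, -bad, drop = FALSE]
  }
  M
}

#' Build a positive-by-negative cross-RDM from timeseries
#'
#' Entry (i, j) is \code{1 - Pearson r} between the i-th positive and j-th
#' negative voxel's timeseries, so entries lie in \code{[0, 2]}: 0 for
#' identical series, 2 for perfectly anticorrelated series. Overlapping
#' opponent pairs, whose series are anticorrelated, therefore sit at the
#' dissimilar end of the scale.
#'
#' @param pos_series matrix (TRs x voxels) of positive-voxel series.
#' @param neg_series matrix (TRs x voxels) of negative-voxel series, same
#'   number of rows.
#' @param session optional session tag (e.g. "mapping", "recall").
#' @param run optional run identifier (or "average").
#' @return An object of class \code{rect_rdm}: an \code{n_pos x n_neg}
#'   matrix with \code{session}/\code{run} attributes. Constant series are
#'   dropped with a warning before computing correlations.
#' @export
build_cross_rdm <- function(pos_series, neg_series, session = NA_character_,
                            run = NA) {
  pos_series <- as.matrix(pos_series); neg_series <- as.matrix(neg_series)
  if (nrow(pos_series) != nrow(neg_series))
    stop("positive and negative series differ in length")
  if (nrow(pos_series) < 3) stop("series must have length >= 3")
  if (ncol(pos_series) < 1 || ncol(neg_series) < 1)
    stop("both voxel classes must be non-empty")
  pos_series <- .drop_constant(pos_series, "positive")
  neg_series <- .drop_constant(neg_series, "negative")
  if (ncol(pos_series) < 1 || ncol(neg_series) < 1)
    stop("a voxel class became empty after dropping constant series")
  rdm <- 1 - stats::cor(pos_series, neg_series)
  structure(rdm, session = session, run = run, class = c("rect_rdm", "matrix"))
}

#' @export
print.rect_rdm <- function(x, ...) {
  cat(sprintf("Cross-RDM (1 - r): %d positive x %d negative = %d entries",
              nrow(x), ncol(x), length(x)))
  s <- attr(x, "session"); r <- attr(x, "run")
  if (!is.na(s)) cat("; session:", s)
  if (!all(is.na(r))) cat("; run:", r)
  cat("\n  entry range: [", round(min(x), 3), ",", round(max(x), 3), "]\n")
  invisible(x)
}

#' Entrywise average of cross-RDMs across runs
#'
#' @param rdms non-empty list of \code{rect_rdm} objects with identical
#'   dimensions and voxel ordering.
#' @return A \code{rect_rdm} tagged \code{run = "average"}.
#' @export
average_rdms <- function(rdms) {
  if (length(rdms) == 0) stop("cannot average an empty list of RDMs")
  d <- dim(rdms[[1]])
  if (!all(vapply(rdms, function(r) identical(dim(r), d), logical(1))))
    stop("all RDMs must share dimensions and voxel ordering")
  avg <- Reduce(`+`, lapply(rdms, unclass)) / length(rdms)
  structure(avg, session = attr(rdms[[1]], "session"), run = "average",
            class = c("rect_rdm", "matrix"))
}

#' Correlate two cross-RDMs
#'
#' Pearson (default) or Spearman correlation over the vectorised entries of
#' two RDMs with identical dimensions and voxel ordering, plus the Fisher
#' z-normalised value used for group-level tests (r is clipped to
#' \code{1 - 1e-7} in magnitude before atanh).
#'
#' @param a,b \code{rect_rdm} objects of identical shape.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return An object of class \code{rdm_correlation}: list with \code{r},
#'   \code{z}, \code{n_entries}, \code{method}.
#' @export
correlate_rdms <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(dim(a), dim(b)))
    stop("RDM dimensions differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  va <- as.vector(a); vb <- as.vector(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("RDM with zero variance: correlation undefined")
  r <- stats::cor(va, vb, method = method)
  structure(list(r = r, z = fisher_z(r), n_entries = length(va),
                 method = method),
            class = "rdm_correlation")
}

#' Fisher z-transform with clipping
#' @param r correlation(s) in \code{[-1, 1]}.
#' @param clip magnitude at which r is clipped before atanh (default
#'   \code{1 - 1e-7}).
#' @return \code{atanh} of the clipped value(s).
#' @export
fisher_z <- function(r, clip = 1 - 1e-7) atanh(pmin(pmax(r, -clip), clip))

#' @export
print.rdm_correlation <- function(x, ...) {
  cat(sprintf("RDM correlation (%s): r = %.4f, z = %.4f over %d entries\n",
              x$method, x$r, x$z, x$n_entries))
  invisible(x)
}

#' Per-run test-retest of the mapping-task RDM correlation
#'
#' Correlates the mapping-session RDM with the task RDM of each run
#' separately, assessing the reliability of the association across runs.
#'
#' @param prf_rdm mapping-session \code{rect_rdm}.
#' @param per_run_task_rdms list of per-run task \code{rect_rdm}s (>= 2).
#' @param method as [correlate_rdms()].
#' @return List of \code{rdm_correlation} objects in run order.
#' @export
test_retest <- function(prf_rdm, per_run_task_rdms,
                        method = c("pearson", "spearman")) {
  if (length(per_run_task_rdms) < 2)
    stop("test-retest requires at least 2 runs")
  method <- match.arg(method)
  lapply(per_run_task_rdms, function(rr) correlate_rdms(prf_rdm, rr, method))
}
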