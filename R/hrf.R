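#' Gamma-variate hemodynamic response function
#'
#' The impulse response linking neural events to the BOLD signal, in the
#' gamma-variate form \deqn{h(t) = (t/(pq))^p e^{p - t/q}} which peaks at
#' \eqn{t = pq} with analytic peak value 1. The defaults (p = 8.6,
#' q = 0.547) give a peak at about 4.7 s. The sampled kernel is rescaled so
#' its maximum sampled value is exactly 1.
#'
#' @param tr_s sampling interval in seconds (default 2).
#' @param duration_s kernel support in seconds (default 24; must be at least
#'   20 so the response has decayed far below 1\% of peak by kernel end).
#' @param p gamma shape parameter (default 8.6).
#' @param q gamma scale parameter in seconds (default 0.547).
#' @return An object of class \code{hrf_kernel}: list with \code{values}
#'   (kernel samples), \code{t_s}, \code{tr_s}, \code{p}, \code{q}.
#' @export
gam_hrf <- function(tr_s = 2, duration_s = 24, p = 8.6, q = 0.547) {
  stopifnot(tr_s > 0, duration_s >= 20)
  if (p <= 0 || q <= 0) stop("HRF shape (p) and scale (q) must be positive")
  t_s <- seq(0, duration_s, by = tr_s)
  h <- ifelse(t_s == 0, 0, (t_s / (p * q))^p * exp(p - t_s / q))
  h <- h / max(h)
  structure(list(values = h, t_s = t_s, tr_s = tr_s, p = p, q = q),
            class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat("Gamma-variate HRF: p =", x$p, ", q =", x$q,
      "s (peak at", round(x$p * x$q, 2), "s),",
      length(x$values), "samples at TR", x$tr_s, "s\n")
  invisible(x)
}
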