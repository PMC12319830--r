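#' Derive a stage seed from a master seed
#'
#' Stages of the pipeline each draw their own seed deterministically from a
#' master seed and the stage name, so individual stages can be re-run in
#' isolation while the whole run stays reproducible.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return A single integer seed in \code{[1, 2^31 - 2]}.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) %% 65536L) * 32749 + (h * 7919) %% 2147483L + 1)
}

# lower-triangular convolution operator: (Hx)_t = sum_k h_k x_{t-k+1}
conv_matrix <- function(h, n) {
  H <- matrix(0, n, n)
  for (j in seq_len(n)) {
    k <- j:min(n, j + length(h) - 1L)
    H[k, j] <- h[seq_along(k)]
  }
  H
}

# convolve a timeseries (or columns of a matrix) with a kernel, truncated to
# the input length
conv_truncate <- function(x, h) {
  if (is.matrix(x)) {
    H <- conv_matrix(h, nrow(x))
    return(H %*% x)
  }
  n <- length(x)
  drop(conv_matrix(h, n) %*% x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
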