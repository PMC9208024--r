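#' @keywords internal
new_fc_matrix <- function(values, band_name, rescaled) {
  structure(values, band = band_name, rescaled = rescaled, class = "fc_matrix")
}

#' Construct an FC matrix from precomputed values
#'
#' Wraps a symmetric node x node matrix of (corrected) amplitude envelope
#' correlations as an `fc_matrix`. Used when connectivity values come from
#' a file or a simulation rather than from [fc_matrix()].
#'
#' @param values Symmetric numeric matrix, zero diagonal. Off-diagonal in
#'   `[-1, 1]` (raw) or `[0, 1]` (rescaled).
#' @param band_name Frequency-band label.
#' @param rescaled Whether values are already on the `(r + 1) / 2` scale.
#' @return An `fc_matrix`.
#' @export
as_fc_matrix <- function(values, band_name = "unknown", rescaled = FALSE) {
  values <- check_square_symmetric(values, "values")
  diag(values) <- 0
  lo <- if (rescaled) 0 else -1
  hi <- 1
  off <- edge_vector(values)
  if (any(off < lo - 1e-9 | off > hi + 1e-9)) {
    stop(sprintf("FC values outside [%g, %g].", lo, hi), call. = FALSE)
  }
  new_fc_matrix(values, band_name, rescaled)
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d nodes, band %s, %s\n", nrow(x),
              attr(x, "band"), if (isTRUE(attr(x, "rescaled"))) "rescaled [0,1]" else "raw [-1,1]"))
  invisible(x)
}

# One directed AECc term: correlation between the envelope of the seed and
# the envelope of the target after removing the target's zero-lag
# projection on the seed. a_* are analytic signals of the band-filtered
# series. A (near-)zero residual, i.e. perfect collinearity, contributes 0.
directed_aec <- function(a_seed, a_target) {
  f_seed <- Re(a_seed)
  f_target <- Re(a_target)
  ss <- sum(f_seed^2)
  if (ss == 0) return(list(value = 0, degenerate = TRUE))
  beta <- sum(f_target * f_seed) / ss
  a_res <- a_target - beta * a_seed
  res_norm <- sqrt(sum(Re(a_res)^2))
  if (res_norm <= 1e-10 * sqrt(sum(f_target^2)) || res_norm == 0) {
    return(list(value = 0, degenerate = TRUE))
  }
  env_seed <- Mod(a_seed)
  env_res <- Mod(a_res)
  if (stats::sd(env_seed) == 0 || stats::sd(env_res) == 0) {
    return(list(value = 0, degenerate = TRUE))
  }
  list(value = stats::cor(env_seed, env_res), degenerate = FALSE)
}

#' Corrected amplitude envelope correlation between two series
#'
#' Band-pass filters both series, suppresses zero-lag leakage by pairwise
#' time-domain orthogonalization, and correlates Hilbert amplitude
#' envelopes. The two directed values (orthogonalizing y with respect to x,
#' and x with respect to y) are averaged, making the measure symmetric.
#'
#' @param x,y Equal-length numeric vectors.
#' @param band A [frequency_band()].
#' @param sampling_rate Sampling frequency in Hz.
#' @return Raw AECc in `[-1, 1]`. A perfectly collinear direction
#'   contributes 0 and raises a warning.
#' @export
aecc_pair <- function(x, y, band, sampling_rate) {
  stopifnot(length(x) == length(y))
  check_band(band, sampling_rate)
  a <- analytic_matrix(fft_bandpass_matrix(cbind(x, y), sampling_rate, band$low, band$high))
  d1 <- directed_aec(a[, 1], a[, 2])
  d2 <- directed_aec(a[, 2], a[, 1])
  if (d1$degenerate || d2$degenerate) {
    warning("Degenerate (collinear or constant-envelope) direction in AECc; term set to 0.",
            call. = FALSE)
  }
  (d1$value + d2$value) / 2
}

#' Rescale an FC matrix to the unit interval
#'
#' Maps raw AECc values elementwise through `(value + 1) / 2`, taking
#' `[-1, 1]` onto `[0, 1]` so FC matrices carry no negative weights.
#'
#' @param fc An `fc_matrix` with `rescaled = FALSE`.
#' @return The rescaled `fc_matrix`.
#' @export
rescale_fc <- function(fc) {
  stopifnot(inherits(fc, "fc_matrix"))
  if (isTRUE(attr(fc, "rescaled"))) stop("FC matrix is already rescaled.", call. = FALSE)
  values <- (unclass(fc) + 1) / 2
  diag(values) <- 0
  new_fc_matrix(values, attr(fc, "band"), rescaled = TRUE)
}

#' Full functional connectivity matrix
#'
#' Computes the corrected amplitude envelope correlation for every
#' unordered channel pair of a source-level recording and rescales to
#' `[0, 1]`. Internally the band-pass filter and analytic signal are
#' computed once per channel; orthogonalized residual envelopes reuse them
#' through the linearity of the Hilbert transform, so the result equals
#' (but is much faster than) a naive [aecc_pair()] double loop.
#'
#' @param ts A [source_ts()] with at least 2 channels.
#' @param band A [frequency_band()].
#' @param rescale If `TRUE` (default) return values on the `[0, 1]` scale.
#' @return An `fc_matrix` (symmetric, zero diagonal).
#' @export
fc_matrix <- function(ts, band, rescale = TRUE) {
  stopifnot(inherits(ts, "source_ts"))
  if (nrow(ts$data) < 2) stop("At least 2 channels are required.", call. = FALSE)
  check_band(band, ts$sampling_rate)
  a <- analytic_matrix(fft_bandpass_matrix(t(ts$data), ts$sampling_rate, band$low, band$high))
  k <- ncol(a)
  vals <- matrix(0, k, k, dimnames = list(ts$channel_labels, ts$channel_labels))
  n_degenerate <- 0L
  for (i in seq_len(k - 1L)) {
    ai <- a[, i]
    for (j in seq.int(i + 1L, k)) {
      d1 <- directed_aec(ai, a[, j])
      d2 <- directed_aec(a[, j], ai)
      if (d1$degenerate || d2$degenerate) n_degenerate <- n_degenerate + 1L
      vals[i, j] <- vals[j, i] <- (d1$value + d2$value) / 2
    }
  }
  if (n_degenerate > 0L) {
    warning(sprintf("%d channel pair(s) had a degenerate AECc direction (term set to 0).",
                    n_degenerate), call. = FALSE)
  }
  out <- new_fc_matrix(vals, band$name, rescaled = FALSE)
  if (rescale) rescale_fc(out) else out
}

#' Whole-brain functional connectivity
#'
#' Mean of the rescaled FC matrix over all unordered region pairs (the
#' upper triangle, diagonal excluded).
#'
#' @param fc A rescaled `fc_matrix`.
#' @return Scalar mean connectivity.
#' @export
whole_brain_fc <- function(fc) {
  stopifnot(inherits(fc, "fc_matrix"))
  if (!isTRUE(attr(fc, "rescaled"))) stop("whole_brain_fc() expects a rescaled FC matrix.", call. = FALSE)
  mean(edge_vector(unclass(fc)))
}
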