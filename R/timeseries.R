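#' Construct a source-level time-series object
#'
#' Container for beamformer-reconstructed (or simulated) regional time
#' series: a channels x samples numeric matrix at a fixed sampling rate,
#' one channel per cortical node.
#'
#' @param data Numeric matrix, channels x samples. All values finite.
#' @param sampling_rate Sampling frequency in Hz.
#' @param channel_labels Optional node names (defaults to rownames or
#'   `node_1 ... node_k`).
#' @return An object of class `source_ts`.
#' @export
source_ts <- function(data, sampling_rate, channel_labels = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) stop("`data` must be a numeric matrix (channels x samples).", call. = FALSE)
  if (any(!is.finite(data))) stop("`data` contains non-finite values.", call. = FALSE)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) stop("`sampling_rate` must be > 0.", call. = FALSE)
  labels <- channel_labels %||% rownames(data) %||% paste0("node_", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) stop("`channel_labels` length must match the number of channels.", call. = FALSE)
  rownames(data) <- labels
  structure(list(data = data, sampling_rate = as.numeric(sampling_rate),
                 channel_labels = labels),
            class = "source_ts")
}

#' @export
print.source_ts <- function(x, ...) {
  cat(sprintf("<source_ts> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' Select and concatenate the first epochs of a recording
#'
#' Keeps the first `n_epochs * epoch_samples` samples in original order,
#' i.e. the first consecutive artifact-free epochs concatenated into a
#' single series that is analyzed as a whole.
#'
#' @param ts A [source_ts()].
#' @param n_epochs Number of epochs (default 13).
#' @param epoch_samples Samples per epoch (default 16384, 13.10 s at
#'   1250 Hz).
#' @return A [source_ts()] truncated to the selected samples.
#' @export
select_epochs <- function(ts, n_epochs = 13, epoch_samples = 16384) {
  stopifnot(inherits(ts, "source_ts"))
  need <- as.integer(n_epochs) * as.integer(epoch_samples)
  have <- ncol(ts$data)
  if (have < need) {
    stop(sprintf("Insufficient samples: %d available, %d required (%d epochs x %d samples).",
                 have, need, n_epochs, epoch_samples), call. = FALSE)
  }
  source_ts(ts$data[, seq_len(need), drop = FALSE], ts$sampling_rate, ts$channel_labels)
}

# Physical frequency of each DFT bin of an n-point transform at rate fs.
bin_frequencies <- function(n, fs) {
  f <- (seq_len(n) - 1) * fs / n
  pmin(f, fs - f)
}

# Core FFT band-pass on a samples x channels matrix: zero every bin whose
# physical frequency falls outside [low, high), inverse transform. Exactly
# idempotent because the retained bin set depends only on (n, fs, band).
fft_bandpass_matrix <- function(x, fs, low, high) {
  n <- nrow(x)
  keep <- {
    f <- bin_frequencies(n, fs)
    f >= low & f < high
  }
  X <- stats::mvfft(x)
  X[!keep, ] <- 0
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

#' FFT band-pass filter
#'
#' Digital band-pass filtering by discrete Fourier transform: all frequency
#' bins outside the pass band (half-open, `low <= f < high`) are set to
#' zero, conjugate-symmetric counterparts included, and the inverse
#' transform is taken. Brick-wall in frequency; exactly idempotent.
#'
#' @param ts A [source_ts()] or a numeric vector (then `sampling_rate`
#'   must be supplied).
#' @param band A [frequency_band()].
#' @param sampling_rate Required when `ts` is a bare numeric vector.
#' @return Same type as `ts`, band-limited.
#' @export
fft_bandpass <- function(ts, band, sampling_rate = NULL) {
  if (inherits(ts, "source_ts")) {
    check_band(band, ts$sampling_rate)
    filt <- t(fft_bandpass_matrix(t(ts$data), ts$sampling_rate, band$low, band$high))
    return(source_ts(filt, ts$sampling_rate, ts$channel_labels))
  }
  stopifnot(is.numeric(ts))
  if (is.null(sampling_rate)) stop("`sampling_rate` is required for a bare numeric input.", call. = FALSE)
  check_band(band, sampling_rate)
  drop(fft_bandpass_matrix(cbind(ts), sampling_rate, band$low, band$high))
}

# Analytic signal (complex) of each column of a samples x channels real
# matrix, via the one-sided FFT construction: Re() is the input, Mod() the
# instantaneous amplitude envelope.
analytic_matrix <- function(x) {
  n <- nrow(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else if (n > 1) {
    h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(x) * h
  stats::mvfft(X, inverse = TRUE) / n
}

#' Hilbert amplitude envelope
#'
#' Magnitude of the analytic signal of a (narrowband) real series: the
#' instantaneous amplitude envelope used by the amplitude envelope
#' correlation.
#'
#' @param x Numeric vector, or samples x channels matrix (per column), or a
#'   [source_ts()] (per channel).
#' @return Non-negative envelope, same shape as the input.
#' @export
hilbert_envelope <- function(x) {
  if (inherits(x, "source_ts")) {
    env <- t(Mod(analytic_matrix(t(x$data))))
    return(source_ts(env, x$sampling_rate, x$channel_labels))
  }
  if (is.matrix(x)) return(Mod(analytic_matrix(x)))
  drop(Mod(analytic_matrix(cbind(x))))
}

#' Time-domain orthogonalization of one series with respect to another
#'
#' Removes from `y` its zero-lag projection onto `x`:
#' `y - (<y, x> / <x, x>) x`. Applied to band-filtered source signals this
#' suppresses the shared instantaneous component that signal leakage
#' (imperfect source unmixing) induces.
#'
#' @param y,x Equal-length numeric vectors; `x` must not be identically
#'   zero.
#' @return Residual series, orthogonal to `x` to machine precision.
#' @export
orthogonalize <- function(y, x) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  xx <- sum(x * x)
  if (xx == 0) stop("Cannot orthogonalize against an all-zero series: projection undefined.", call. = FALSE)
  y - (sum(y * x) / xx) * x
}

#' Relative spectral power in a band
#'
#' Periodogram power within `[low, high)` divided by total power over
#' `(0, Nyquist]`, averaged over channels. The DC bin is excluded from the
#' total.
#'
#' @param ts A [source_ts()].
#' @param band A [frequency_band()].
#' @return Fraction in `[0, 1]`.
#' @export
relative_power <- function(ts, band) {
  stopifnot(inherits(ts, "source_ts"))
  check_band(band, ts$sampling_rate)
  x <- t(ts$data)
  n <- nrow(x)
  f <- bin_frequencies(n, ts$sampling_rate)
  pos <- f > 0            # one-sided, DC excluded; conjugate bins pair up
  pow <- Mod(stats::mvfft(x))^2
  total <- colSums(pow[pos, , drop = FALSE])
  if (any(total == 0)) stop("Zero total power in at least one channel.", call. = FALSE)
  inband <- pos & f >= band$low & f < band$high
  mean(colSums(pow[inband, , drop = FALSE]) / total)
}
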