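#' Define a frequency band
#'
#' A half-open frequency interval `[low, high)` in Hz. The half-open
#' convention means adjacent bands such as theta (4-8 Hz) and alpha1
#' (8-10 Hz) partition the spectrum without double-counting the shared
#' printed endpoint.
#'
#' @param name Band label, e.g. `"theta"`.
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return An object of class `frequency_band`.
#' @examples
#' frequency_band("theta", 4, 8)
#' @export
frequency_band <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low) {
    stop("Invalid band: need 0 < low < high (Hz).", call. = FALSE)
  }
  structure(list(name = name, low = as.numeric(low), high = as.numeric(high)),
            class = "frequency_band")
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> %s: [%g, %g) Hz\n", x$name, x$low, x$high))
  invisible(x)
}

#' Canonical analysis bands
#'
#' Theta (4-8 Hz), alpha1 (8-10 Hz) and alpha2 (10-13 Hz), the oscillatory
#' ranges most consistently related to cognition in the MEG multiple
#' sclerosis literature.
#'
#' @return Named list of [frequency_band()] objects.
#' @export
default_bands <- function() {
  list(
    theta  = frequency_band("theta", 4, 8),
    alpha1 = frequency_band("alpha1", 8, 10),
    alpha2 = frequency_band("alpha2", 10, 13)
  )
}

check_band <- function(band, sampling_rate) {
  if (!inherits(band, "frequency_band")) stop("`band` must be a frequency_band.", call. = FALSE)
  nyq <- sampling_rate / 2
  if (band$high > nyq) {
    stop(sprintf("Band %s upper edge %g Hz exceeds Nyquist %g Hz.",
                 band$name, band$high, nyq), call. = FALSE)
  }
  invisible(band)
}
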