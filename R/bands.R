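#' Define a frequency band scheme
#'
#' A band scheme is an ordered set of contiguous, non-overlapping, half-open
#' frequency intervals `[low, high)` in Hz, one per named band. Band powers
#' everywhere in the package are integrals of the power spectral density over
#' these intervals.
#'
#' @param bands Named list; each element a numeric `c(low, high)` in Hz.
#' @return A tibble with columns `band` (factor, in the given order),
#'   `low_hz`, `high_hz`, of class `band_scheme`.
#' @examples
#' default_band_scheme()
#' band_scheme(list(slow = c(0.5, 8), fast = c(8, 25)))
#' @export
band_scheme <- function(bands) {
  if (length(bands) == 0 || is.null(names(bands)) || any(names(bands) == "")) {
    abort("bands must be a non-empty named list")
  }
  lows <- vapply(bands, `[`, numeric(1), 1)
  highs <- vapply(bands, `[`, numeric(1), 2)
  if (any(highs <= lows)) abort("every band needs high_hz > low_hz")
  if (is.unsorted(lows, strictly = TRUE) ||
      any(highs[-length(highs)] > lows[-1] + 1e-12)) {
    abort("bands must be ascending and non-overlapping")
  }
  out <- tibble(
    band = factor(names(bands), levels = names(bands)),
    low_hz = lows, high_hz = highs
  )
  class(out) <- c("band_scheme", class(out))
  out
}

#' Default EEG band scheme
#'
#' Delta \[0.5, 5), theta \[5, 8), alpha \[8, 12), sigma \[12, 16) and beta
#' \[16, 25) Hz. The delta and theta bands jointly cover the low-frequency
#' (0.5-7 Hz and up) range whose elevation defines EEG slowing; sigma spans
#' the sleep-spindle range.
#'
#' @return A `band_scheme` tibble.
#' @export
default_band_scheme <- function() {
  band_scheme(list(
    delta = c(0.5, 5), theta = c(5, 8), alpha = c(8, 12),
    sigma = c(12, 16), beta = c(16, 25)
  ))
}

band_names <- function(scheme) as.character(scheme$band)

assert_band_scheme <- function(scheme, fs = NULL) {
  if (!inherits(scheme, "band_scheme")) abort("not a band_scheme")
  if (!is.null(fs) && max(scheme$high_hz) >= fs / 2) {
    abort(sprintf("band scheme extends to %.1f Hz, at or above Nyquist (%.1f Hz)",
                  max(scheme$high_hz), fs / 2))
  }
  invisible(scheme)
}
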