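#' Frequency band specification
#'
#' A band is a named half-open passband `(low, high)` in Hz. The default
#' analysis set for neonatal sleep EEG covers low delta through alpha; see
#' [neonatal_bands()].
#'
#' @param name Band label.
#' @param low,high Passband edges in Hz, `0 < low < high`.
#' @return A one-row tibble with columns `name`, `low`, `high`.
#' @examples
#' band_spec("theta", 4, 8)
#' @export
band_spec <- function(name, low, high) {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
    length(high) != 1L || is.na(low) || is.na(high) || low <= 0 || high <= low) {
    abort("band edges must satisfy 0 < low < high", class = "neonet_invalid_band")
  }
  tibble(name = as.character(name), low = as.numeric(low), high = as.numeric(high))
}

#' Canonical neonatal EEG frequency bands
#'
#' The four bands used throughout the analysis: low delta 0.4–1.5 Hz, high
#' delta 1.5–4 Hz, theta 4–8 Hz and alpha 8–13 Hz. All are below the Nyquist
#' frequency of the 100 Hz working sampling rate.
#'
#' @return A tibble with columns `name`, `low`, `high` (Hz), one row per band.
#' @examples
#' neonatal_bands()
#' @export
neonatal_bands <- function() {
  dplyr::bind_rows(
    band_spec("low_delta", 0.4, 1.5),
    band_spec("high_delta", 1.5, 4),
    band_spec("theta", 4, 8),
    band_spec("alpha", 8, 13)
  )
}

# Coerce a band argument (1-row tibble, list or band_spec output) to a list
# with fields name/low/high, validating against a sampling rate if given.
as_band <- function(band, sampling_rate = NULL) {
  if (is.data.frame(band)) {
    if (nrow(band) != 1L) abort("`band` must be a single band (one row)")
    band <- as.list(band)
  }
  if (is.null(band$low) || is.null(band$high)) {
    abort("`band` needs `low` and `high` fields", class = "neonet_invalid_band")
  }
  if (band$low <= 0 || band$high <= band$low) {
    abort("band edges must satisfy 0 < low < high", class = "neonet_invalid_band")
  }
  if (!is.null(sampling_rate) && band$high >= sampling_rate / 2) {
    abort(
      sprintf(
        "band edge %.3g Hz is at or above Nyquist (%.3g Hz)",
        band$high, sampling_rate / 2
      ),
      class = "neonet_invalid_band"
    )
  }
  band$name <- band$name %||% sprintf("%g-%g", band$low, band$high)
  band
}
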