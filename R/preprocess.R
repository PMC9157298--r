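#' Sensor-space EEG recording
#'
#' Light container for a multichannel recording: a channels x samples matrix,
#' its sampling rate, channel names, and sleep-state annotations. Annotations
#' are given in seconds from recording onset and must not overlap within a
#' state.
#'
#' @param data Numeric matrix, channels x samples; finite throughout.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_names Optional character vector, one per channel.
#' @param annotations Data frame with columns `state` (e.g. `"AS"`, `"QS"`),
#'   `start`, `end` (seconds). May be empty.
#' @return An object of class `sensor_recording`.
#' @examples
#' rec <- sensor_recording(matrix(rnorm(200), 2), 100)
#' rec
#' @export
sensor_recording <- function(data, sampling_rate, channel_names = NULL,
                             annotations = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data))) {
    abort("recording data must be a finite numeric matrix",
      class = "neonet_invalid_recording"
    )
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be > 0", class = "neonet_invalid_recording")
  }
  channel_names <- channel_names %||% paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data)) {
    abort("`channel_names` length must match channel count")
  }
  if (is.null(annotations)) {
    annotations <- tibble(state = character(), start = numeric(), end = numeric())
  }
  annotations <- as_tibble(annotations)
  if (nrow(annotations)) {
    stopifnot(all(c("state", "start", "end") %in% names(annotations)))
    for (st in unique(annotations$state)) {
      a <- dplyr::arrange(annotations[annotations$state == st, ], .data$start)
      if (any(a$end <= a$start) ||
        (nrow(a) > 1L && any(a$start[-1L] < a$end[-nrow(a)]))) {
        abort("annotations must be positive-length and non-overlapping within a state",
          class = "neonet_invalid_recording"
        )
      }
    }
  }
  rownames(data) <- channel_names
  structure(
    list(
      data = data, sampling_rate = as.numeric(sampling_rate),
      channel_names = channel_names, annotations = annotations
    ),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf(
    "<sensor_recording> %d channels x %d samples @ %g Hz (%.1f s), %d annotation(s)\n",
    nrow(x$data), ncol(x$data), x$sampling_rate,
    ncol(x$data) / x$sampling_rate, nrow(x$annotations)
  ))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

# Butterworth filters are designed and applied as cascaded second-order
# sections (biquads): high-order transfer-function (b, a) realizations are
# numerically unstable at the extreme normalized cut-offs this analysis needs
# (e.g. 0.4 Hz at a 100 Hz rate), while biquad cascades stay well-conditioned
# at any order.

# Digital Butterworth as second-order sections via the bilinear transform.
# Returns list of sections, each list(b, a) in z^-1 convention with a[1] = 1.
butter_sos <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  w <- tan(pi * fc / fs) # prewarped analog cut-off
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # unit LP poles
  s_poles <- if (type == "low") w * proto else w / proto
  z_poles <- (1 + s_poles) / (1 - s_poles)
  z_zero <- if (type == "low") -1 else 1
  eval_at <- if (type == "low") 1 else -1 # gain-normalization point
  # group conjugate pairs (Im > 0 with its conjugate); odd order leaves one
  # real pole as a first-order section
  pos <- z_poles[Im(z_poles) > 1e-12]
  real_p <- Re(z_poles[abs(Im(z_poles)) <= 1e-12])
  sections <- lapply(pos, function(p) {
    list(b = c(1, -2 * z_zero, z_zero^2), a = c(1, -2 * Re(p), Mod(p)^2))
  })
  for (p in real_p) {
    sections[[length(sections) + 1L]] <- list(b = c(1, -z_zero), a = c(1, -p))
  }
  lapply(sections, function(sec) {
    zi <- eval_at^(-(seq_along(sec$a) - 1))
    g <- sum(sec$a * zi) / sum(sec$b * zi)
    sec$b <- sec$b * g
    sec
  })
}

sos_filter <- function(sos, x) {
  for (sec in sos) x <- as.numeric(signal::filter(sec$b, sec$a, x))
  x
}

# Zero-phase application: odd-reflection padding, forward pass through all
# sections, time reversal, second pass, reversal, trim.
sos_filtfilt <- function(sos, x) {
  n <- length(x)
  np <- min(n - 1L, 60L * (2L * length(sos) + 1L))
  padded <- if (np >= 1L) {
    c(2 * x[1L] - x[seq(np + 1L, 2L)], x, 2 * x[n] - x[seq(n - 1L, n - np)])
  } else {
    x
  }
  y <- sos_filter(sos, padded)
  y <- rev(sos_filter(sos, rev(y)))
  if (np >= 1L) y[(np + 1L):(np + n)] else y
}

# Minimum-order Butterworth pair meeting a stop-band attenuation target, with
# the transition band set to 25% of each cut-off. Returns list(hp, lp) of
# second-order-section cascades (either may be NULL).
design_band_filters <- function(low, high, sampling_rate,
                                atten_db = 20, ripple_db = 1) {
  nyq <- sampling_rate / 2
  hp <- NULL
  lp <- NULL
  if (!is.null(low) && low > 0) {
    ord <- signal::buttord(low / nyq, 0.75 * low / nyq, ripple_db, atten_db)
    hp <- butter_sos(ord$n, ord$Wc * nyq, sampling_rate, "high")
  }
  if (!is.null(high)) {
    ws <- min(1.25 * high / nyq, 0.999)
    ord <- signal::buttord(high / nyq, ws, ripple_db, atten_db)
    lp <- butter_sos(ord$n, ord$Wc * nyq, sampling_rate, "low")
  }
  list(hp = hp, lp = lp)
}

apply_filters_rows <- function(data, filters) {
  out <- data
  for (i in seq_len(nrow(data))) {
    y <- out[i, ]
    if (!is.null(filters$hp)) y <- sos_filtfilt(filters$hp, y)
    if (!is.null(filters$lp)) y <- sos_filtfilt(filters$lp, y)
    out[i, ] <- y
  }
  out
}

#' Zero-phase band-pass filtering
#'
#' Filters every channel into the requested band with a pair of minimum-order
#' Butterworth high-pass and low-pass filters (designed for at least
#' `atten_db` stop-band attenuation, transition bands at 25% of each cut-off)
#' applied forward and backward. The two-pass application cancels the phase
#' response exactly and doubles the attenuation in dB.
#'
#' @param rec A [sensor_recording()].
#' @param band A band (one row of [neonatal_bands()] or [band_spec()]).
#' @param atten_db Single-pass stop-band attenuation target in dB.
#' @return A filtered `sensor_recording` with unchanged shape and annotations.
#' @examples
#' rec <- sensor_recording(matrix(rnorm(400), 2), 100)
#' filt <- bandpass_zero_phase(rec, band_spec("theta", 4, 8))
#' @export
bandpass_zero_phase <- function(rec, band, atten_db = 20) {
  band <- as_band(band, rec$sampling_rate)
  filters <- design_band_filters(band$low, band$high, rec$sampling_rate,
    atten_db = atten_db
  )
  out <- rec
  out$data <- apply_filters_rows(rec$data, filters)
  out
}

#' Wide-band prefilter
#'
#' The 0.4–45 Hz prefilter applied before downsampling to the working rate.
#'
#' @inheritParams bandpass_zero_phase
#' @param low,high Prefilter edges in Hz.
#' @return A filtered `sensor_recording`.
#' @export
prefilter <- function(rec, low = 0.4, high = 45) {
  bandpass_zero_phase(rec, band_spec("prefilter", low, high))
}

#' Resample a recording to a lower rate
#'
#' Applies a zero-phase Butterworth anti-alias low-pass (cut-off at 0.45 of
#' the target rate) and then evaluates the filtered signal on the target
#' sample grid by cubic spline interpolation, which supports rational
#' (non-integer) rate ratios such as 250 to 100 Hz. Upsampling is refused.
#'
#' @param rec A [sensor_recording()].
#' @param target Target sampling rate in Hz, `target <= rec$sampling_rate`.
#' @return A `sensor_recording` at the target rate with
#'   `floor(n * target / fs)` samples; annotations are carried over unchanged
#'   (they are in seconds).
#' @examples
#' rec <- sensor_recording(matrix(rnorm(5000), 1), 500)
#' n_250 <- ncol(resample_to(rec, 100)$data) # 1000
#' @export
resample_to <- function(rec, target) {
  if (target > rec$sampling_rate) {
    abort("upsampling is not supported (target rate above original)",
      class = "neonet_invalid_config"
    )
  }
  if (target == rec$sampling_rate) {
    return(rec)
  }
  n_in <- n_samples(rec)
  n_out <- floor(n_in * target / rec$sampling_rate)
  nyq <- rec$sampling_rate / 2
  ord <- signal::buttord(
    0.45 * target / nyq, min(0.5 * target / nyq, 0.999), 1, 40
  )
  aa <- butter_sos(ord$n, ord$Wc * nyq, rec$sampling_rate, "low")
  t_in <- (seq_len(n_in) - 1L) / rec$sampling_rate
  t_out <- (seq_len(n_out) - 1L) / target
  out <- matrix(0, nrow(rec$data), n_out)
  for (i in seq_len(nrow(rec$data))) {
    y <- sos_filtfilt(aa, rec$data[i, ])
    out[i, ] <- stats::spline(t_in, y, xout = t_out, method = "natural")$y
  }
  sensor_recording(out, target, rec$channel_names, rec$annotations)
}

#' Average-reference (common average montage)
#'
#' Subtracts the instantaneous mean across channels from every channel, so the
#' channel mean is zero at every sample.
#'
#' @param rec A [sensor_recording()] with at least two channels.
#' @return A re-referenced `sensor_recording`.
#' @examples
#' rec <- sensor_recording(rbind(rep(1, 10), rep(3, 10)), 100)
#' average_reference(rec)$data[, 1] # -1, 1
#' @export
average_reference <- function(rec) {
  if (nrow(rec$data) < 2L) {
    abort("average reference needs at least 2 channels",
      class = "neonet_invalid_recording"
    )
  }
  out <- rec
  out$data <- sweep(rec$data, 2L, colMeans(rec$data))
  out
}

#' Select equidistant sleep-state analysis windows
#'
#' Accumulates the per-state analysis signal from `n_windows` equally spaced
#' windows of `window_length` seconds. Windows are placed in *annotated time*:
#' the annotated segments of the requested state are conceptually concatenated
#' and window onsets are spaced evenly from the first to the last possible
#' onset, so with exactly `n_windows * window_length` seconds available the
#' windows are back-to-back. Subjects without enough annotated signal raise an
#' exclusion condition (class `neonet_exclusion`).
#'
#' @param rec A [sensor_recording()] with annotations.
#' @param state State label to select (e.g. `"AS"`).
#' @param n_windows Number of windows (default 6).
#' @param window_length Window length in seconds (default 30).
#' @return An object of class `epoch_set`: a tibble with one row per window
#'   (`state`, `window`, `start`, `end` in annotated-time seconds) carrying
#'   the per-window recording sample indices as attribute `"index"` and the
#'   per-state total seconds as attribute `"total_per_state"`.
#' @export
select_epochs <- function(rec, state, n_windows = 6, window_length = 30) {
  assert_count(n_windows, "n_windows")
  fs <- rec$sampling_rate
  ann <- rec$annotations[rec$annotations$state == state, , drop = FALSE]
  ann <- dplyr::arrange(ann, .data$start)
  if (!nrow(ann)) {
    abort(sprintf("no annotated '%s' signal: subject excluded", state),
      class = c("neonet_exclusion", "neonet_error")
    )
  }
  # recording sample indices of all annotated samples for this state
  idx <- unlist(lapply(seq_len(nrow(ann)), function(k) {
    seq(floor(ann$start[k] * fs) + 1L, min(floor(ann$end[k] * fs), n_samples(rec)))
  }))
  need <- n_windows * window_length * fs
  if (length(idx) < need) {
    abort(
      sprintf(
        "only %.1f s of '%s' available, %.1f s required: subject excluded",
        length(idx) / fs, state, need / fs
      ),
      class = c("neonet_exclusion", "neonet_error")
    )
  }
  wlen <- as.integer(round(window_length * fs))
  last_onset <- length(idx) - wlen # 0-based, in annotated samples
  onsets <- if (n_windows == 1L) {
    0
  } else {
    floor(seq(0, last_onset, length.out = n_windows))
  }
  windows <- tibble(
    state = state,
    window = seq_len(n_windows),
    start = onsets / fs,
    end = (onsets + wlen) / fs
  )
  index <- lapply(onsets, function(o) idx[(o + 1L):(o + wlen)])
  structure(windows,
    index = index,
    total_per_state = n_windows * window_length,
    sampling_rate = fs,
    class = c("epoch_set", class(windows))
  )
}

#' Extract the per-window signal matrices of an epoch set
#'
#' @param rec The [sensor_recording()] the epochs were selected from.
#' @param epochs An `epoch_set` from [select_epochs()].
#' @return List of channels x samples matrices, one per window.
#' @export
epoch_signals <- function(rec, epochs) {
  lapply(attr(epochs, "index"), function(ix) rec$data[, ix, drop = FALSE])
}
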