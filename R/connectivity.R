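# Debiased squared weighted phase-lag index and per-cohort connectivity
# matrices. Cross-spectral terms come from the analytic (Hilbert) signal of
# band-filtered data, one term per sample, pooled across analysis windows.

# Accumulate the three pooled sums the debiased estimator needs for all
# parcel pairs of one window: sum Im, sum Im^2, sum |Im| of the per-sample
# cross terms Im(a_i conj(a_j)) = I_i R_j - R_i I_j.
dwpli_sums_matrix <- function(analytic) {
  R <- Re(analytic)
  I <- Im(analytic)
  p <- nrow(R)
  s_im <- I %*% t(R) - R %*% t(I)
  s_im2 <- (I^2) %*% t(R^2) - 2 * (I * R) %*% t(R * I) + (R^2) %*% t(I^2)
  s_abs <- matrix(0, p, p)
  for (i in seq_len(p - 1L)) {
    rest <- (i + 1L):p
    w <- abs(
      R[rest, , drop = FALSE] * matrix(I[i, ], length(rest), ncol(R), byrow = TRUE) -
        I[rest, , drop = FALSE] * matrix(R[i, ], length(rest), ncol(R), byrow = TRUE)
    )
    s_abs[i, rest] <- rowSums(w)
  }
  s_abs <- s_abs + t(s_abs)
  list(s_im = s_im, s_im2 = s_im2, s_abs = s_abs)
}

dwpli_from_sums <- function(s_im, s_im2, s_abs) {
  num <- s_im^2 - s_im2
  den <- s_abs^2 - s_im2
  out <- ifelse(den > 0, num / den, 0)
  diag(out) <- 0
  out
}

#' Debiased squared weighted phase-lag index of two signals
#'
#' Estimates squared phase synchrony from the imaginary part of the
#' cross-spectrum, with the sample bias of the squared estimator removed:
#' `((sum Im)^2 - sum Im^2) / ((sum |Im|)^2 - sum Im^2)` over per-sample
#' analytic cross terms. The estimate lies in `[-1, 1]`, has expectation 0
#' for independent signals (slightly negative values are possible and
#' retained), is insensitive to zero-lag (volume-conducted) coupling, and
#' reaches 1 for a constant non-zero (mod pi) phase lag.
#'
#' @param x,y Equal-length numeric vectors (at least 100 samples), already
#'   band-limited.
#' @return A single numeric estimate. If the imaginary cross-spectrum is
#'   identically zero (e.g. `y == x`), returns 0 by convention.
#' @examples
#' p <- generate_coupled_pair(2000, 100, c(4, 8), lag = pi / 2, coupling = 1, seed = 1)
#' debiased_wpli(p$x, p$y) # ~1
#' @export
debiased_wpli <- function(x, y) {
  if (length(x) != length(y)) {
    abort("signals must have equal length", class = "neonet_shape_error")
  }
  if (length(x) < 100L) {
    abort("need at least 100 samples", class = "neonet_invalid_config")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero-variance input: phase is undefined", class = "neonet_undefined_signal")
  }
  im <- Im(analytic_signal(x) * Conj(analytic_signal(y)))
  num <- sum(im)^2 - sum(im^2)
  den <- sum(abs(im))^2 - sum(im^2)
  if (den <= 0) {
    return(0)
  }
  num / den
}

#' Connectivity matrix over parcel signal windows
#'
#' Computes the debiased wPLI for every parcel pair by pooling the per-sample
#' analytic cross-spectral terms of all analysis windows into one estimate.
#' To avoid filter/Hilbert edge transients, `trim` seconds are dropped at
#' both ends of every window before pooling.
#'
#' @param windows List of parcels x samples matrices (band-filtered), e.g.
#'   from [epoch_signals()] after source collapse; or a single matrix.
#' @param sampling_rate Sampling rate in Hz (used for trimming).
#' @param trim Seconds discarded at each window edge (default 1).
#' @param state,subject,band_name Optional metadata attached as attributes.
#' @return A symmetric parcels x parcels matrix of class
#'   `connectivity_matrix` with zero diagonal.
#' @export
connectivity_matrix <- function(windows, sampling_rate, trim = 1,
                                state = NULL, subject = NULL, band_name = NULL) {
  if (is.matrix(windows)) windows <- list(windows)
  if (!length(windows)) {
    abort("no analysis windows supplied: subject excluded",
      class = c("neonet_exclusion", "neonet_error")
    )
  }
  p <- nrow(windows[[1L]])
  s_im <- matrix(0, p, p)
  s_im2 <- matrix(0, p, p)
  s_abs <- matrix(0, p, p)
  ntrim <- as.integer(round(trim * sampling_rate))
  for (w in windows) {
    if (nrow(w) != p) abort("window parcel counts differ", class = "neonet_shape_error")
    if (ncol(w) <= 2L * ntrim + 2L) {
      abort("window too short after edge trimming", class = "neonet_invalid_config")
    }
    a <- analytic_rows(w)
    if (ntrim > 0L) a <- a[, (ntrim + 1L):(ncol(a) - ntrim), drop = FALSE]
    sums <- dwpli_sums_matrix(a)
    s_im <- s_im + sums$s_im
    s_im2 <- s_im2 + sums$s_im2
    s_abs <- s_abs + sums$s_abs
  }
  out <- dwpli_from_sums(s_im, s_im2, s_abs)
  out <- (out + t(out)) / 2
  structure(out,
    state = state, subject = subject, band = band_name,
    class = c("connectivity_matrix", class(out))
  )
}

#' Apply an edge-validity mask to a connectivity matrix
#'
#' Masked (invalid) edges are set to `NA` so they are *absent* from all
#' downstream statistics, not treated as zero connectivity. Applying a mask
#' twice equals applying it once.
#'
#' @param cm A `connectivity_matrix` (or plain symmetric matrix).
#' @param mask An `edge_mask` from [fidelity_mask()] or a binary matrix of the
#'   same dimension.
#' @return The matrix with invalid off-diagonal entries set to `NA`.
#' @export
apply_mask <- function(cm, mask) {
  m <- if (inherits(mask, "edge_mask")) mask$mask else mask
  if (!all(dim(cm) == dim(m))) {
    abort("mask and connectivity matrix dimensions differ", class = "neonet_shape_error")
  }
  out <- cm
  out[m == 0] <- NA_real_
  diag(out) <- 0
  out
}

#' Long-format edge table of one or more connectivity matrices
#'
#' @param cm A `connectivity_matrix`.
#' @return Tibble with columns `i`, `j` (`i < j`), `value`, plus any
#'   `subject`/`state`/`band` metadata carried by the matrix.
#' @export
connectivity_edges <- function(cm) {
  p <- nrow(cm)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  out <- tibble(i = ut[, 1], j = ut[, 2], value = cm[ut])
  for (f in c("subject", "state", "band")) {
    v <- attr(cm, f)
    if (!is.null(v)) out[[f]] <- v
  }
  out
}
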