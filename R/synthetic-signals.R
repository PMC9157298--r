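# Band-limited signal construction in the frequency domain: independent
# complex Gaussian coefficients on the in-band positive frequencies, inverse
# FFT of the one-sided spectrum. The result is the *analytic* signal (real
# part = the observable trace), exactly band-limited and transient-free,
# normalized to unit variance of its real part.
band_limited_analytic <- function(n, sampling_rate, band) {
  freqs <- (seq_len(n) - 1L) / n * sampling_rate
  keep <- freqs >= band[1] & freqs <= band[2] & freqs <= sampling_rate / 2
  if (!any(keep)) {
    abort("band contains no FFT bins at this length/rate", class = "neonet_invalid_band")
  }
  coef <- complex(
    real = rnorm(sum(keep)),
    imaginary = rnorm(sum(keep))
  )
  spec <- complex(length.out = n)
  spec[keep] <- coef
  a <- fft(spec, inverse = TRUE) / sqrt(n)
  a / sd(Re(a))
}

#' Generate a phase-coupled pair of band-limited signals
#'
#' Construction used both to exercise the connectivity estimator and inside
#' the edge-fidelity simulation: a shared band-limited analytic driver `a(t)`
#' is mixed with independent band-limited noise,
#' `x = Re(sqrt(c) a + sqrt(1-c) e_x)` and
#' `y = Re(sqrt(c) a e^{-i lag} + sqrt(1-c) e_y)`, plus optional white
#' measurement noise. At `coupling = 1` and a quarter-cycle lag the imaginary
#' cross-spectrum has constant sign, so the debiased wPLI of the pair is 1 by
#' design; at `coupling = 0` the signals are independent.
#'
#' @param n_samples Number of samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param band Length-2 numeric, passband in Hz (within Nyquist).
#' @param lag Phase lag in radians applied to the shared driver in `y`.
#' @param coupling Mixing proportion in `[0, 1]`.
#' @param noise_sd Standard deviation of additive white measurement noise.
#' @param seed Integer seed; same seed, same sample paths.
#' @return List with numeric vectors `x` and `y`.
#' @examples
#' pair <- generate_coupled_pair(2000, 100, c(1.5, 4), lag = pi / 2, coupling = 1, seed = 7)
#' debiased_wpli(pair$x, pair$y)
#' @export
generate_coupled_pair <- function(n_samples, sampling_rate, band,
                                  lag = pi / 2, coupling = 1, noise_sd = 0,
                                  seed = 1) {
  assert_count(n_samples, "n_samples")
  assert_prob(coupling, "coupling")
  if (band[2] >= sampling_rate / 2 || band[1] <= 0) {
    abort("band must lie strictly within (0, Nyquist)", class = "neonet_invalid_band")
  }
  if (coupling == 1 && isTRUE(all.equal(sin(lag), 0, tolerance = 1e-8))) {
    warn(paste(
      "lag is 0 (mod pi) at full coupling: the imaginary cross-spectrum",
      "vanishes and the phase-lag index of the pair is 0 by construction"
    ))
  }
  with_seed(seed, {
    common <- band_limited_analytic(n_samples, sampling_rate, band)
    ex <- band_limited_analytic(n_samples, sampling_rate, band)
    ey <- band_limited_analytic(n_samples, sampling_rate, band)
    x <- Re(sqrt(coupling) * common + sqrt(1 - coupling) * ex)
    y <- Re(sqrt(coupling) * common * exp(-1i * lag) + sqrt(1 - coupling) * ey)
    if (noise_sd > 0) {
      x <- x + rnorm(n_samples, sd = noise_sd)
      y <- y + rnorm(n_samples, sd = noise_sd)
    }
    list(x = x, y = y)
  })
}
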