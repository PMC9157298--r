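# Internal numerical helpers shared across modules.

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal `x + i * H(x)` of a real vector, from
#' which instantaneous phase and the cross-spectral terms of the phase-lag
#' index are derived.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) abort("analytic signal needs at least 2 samples")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Row-wise analytic signal of a channels x samples matrix.
analytic_rows <- function(m) {
  t(apply(m, 1L, analytic_signal))
}

# Deterministic, approximately uniform points on the unit sphere
# (Fibonacci lattice); used for toy sensor/parcel geometry.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(
    x = sin(phi) * cos(theta),
    y = sin(phi) * sin(theta),
    z = cos(phi)
  )
}

# Run code under a local RNG state seeded with `seed`, restoring the caller's
# state afterwards; the basis of the bit-identical regeneration guarantee.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a master seed (kept < 2^31).
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 16807) %% 2147483647
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    abort(sprintf("`%s` must be a positive integer (got %s)", name, toString(x)),
      class = "neonet_invalid_config"
    )
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must lie in [0, 1]", name), class = "neonet_invalid_config")
  }
  invisible(as.numeric(x))
}
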