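#' Simulation-based edge fidelity mask
#'
#' Determines which parcel pairs the sensor array and forward/inverse model
#' can resolve at all. For every parcel pair, `n_iter` iterations drive that
#' pair with perfectly synchronous quarter-cycle-lagged band-limited signals
#' (true debiased wPLI of 1) while all remaining parcels receive independent
#' band-limited noise of the same variance; the simulated sensor data
#' (forward model, no added noise) are inverted and collapsed back to parcels
#' and the full parcel-pair wPLI matrix is computed. The mean reconstructed
#' wPLI of the driven pair over iterations is its *fidelity*; reconstructed
#' values of all non-driven pairs from all iterations form a single global
#' surrogate pool. An edge is kept when its fidelity exceeds the
#' `percentile` quantile (default 99th) of that pool.
#'
#' @param lf A `lead_field`.
#' @param inv An `inverse_operator` for it.
#' @param parc A `parcellation` (its fidelity weights are used in the
#'   collapse).
#' @param n_iter Iterations per edge (default 500; at least 2).
#' @param percentile Surrogate quantile in `(0, 1)`, default 0.99.
#' @param seed Integer seed.
#' @param n_samples,sampling_rate,band Simulation signal parameters.
#' @return Object of class `edge_mask`: list with `mask` (binary symmetric
#'   parcels x parcels, zero diagonal), `n_excluded` (zero off-diagonal pairs),
#'   `fidelity` (mean reconstructed wPLI per edge) and `threshold`.
#' @examples
#' cfg <- study_config(n_sensors = 6, n_sources = 6, n_parcels = 6, mixing = "identity")
#' hm <- generate_head_model(cfg)
#' inv <- make_inverse(hm$lead_field, lambda = 1e-6)
#' fidelity_mask(hm$lead_field, inv, hm$parcellation, n_iter = 5, seed = 1)$n_excluded
#' @export
fidelity_mask <- function(lf, inv, parc, n_iter = 500, percentile = 0.99,
                          seed = 1, n_samples = 400, sampling_rate = 100,
                          band = c(1.5, 4)) {
  if (!is.numeric(n_iter) || n_iter < 2) {
    abort("`n_iter` must be at least 2", class = "neonet_invalid_config")
  }
  p <- parc$n_parcels
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  fidelity <- matrix(0, p, p)
  surrogate_pool <- vector("list", nrow(pairs))
  off <- upper.tri(matrix(0, p, p))

  with_seed(seed, {
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]
      b <- pairs[k, 2]
      acc <- 0
      pool_k <- numeric(0)
      for (it in seq_len(n_iter)) {
        parcel_sig <- matrix(0, p, n_samples)
        driver <- band_limited_analytic(n_samples, sampling_rate, band)
        parcel_sig[a, ] <- Re(driver)
        parcel_sig[b, ] <- Re(driver * exp(-1i * pi / 2))
        for (q in seq_len(p)[-c(a, b)]) {
          parcel_sig[q, ] <- Re(band_limited_analytic(n_samples, sampling_rate, band))
        }
        s <- parcel_sig[parc$assignment, , drop = FALSE]
        rec <- apply_inverse(inv, lf$matrix %*% s)
        collapsed <- collapse_parcels(rec, parc)
        wp <- dwpli_from_sums_of(collapsed)
        acc <- acc + wp[a, b]
        pool_k <- c(pool_k, wp[off & !pair_indicator(p, a, b)])
      }
      fidelity[a, b] <- acc / n_iter
      surrogate_pool[[k]] <- pool_k
    }
  })
  fidelity <- fidelity + t(fidelity)
  threshold <- quantile(unlist(surrogate_pool), percentile, names = FALSE)
  mask <- (fidelity > threshold) * 1
  diag(mask) <- 0
  structure(
    list(
      mask = mask,
      n_excluded = sum(mask[off] == 0),
      fidelity = fidelity,
      threshold = threshold,
      n_iter = n_iter,
      percentile = percentile
    ),
    class = "edge_mask"
  )
}

# wPLI matrix of one multichannel segment (no trimming: simulation signals
# are constructed in the frequency domain and have no filter transients).
dwpli_from_sums_of <- function(m) {
  s <- dwpli_sums_matrix(analytic_rows(m))
  dwpli_from_sums(s$s_im, s$s_im2, s$s_abs)
}

pair_indicator <- function(p, a, b) {
  m <- matrix(FALSE, p, p)
  m[a, b] <- TRUE
  m[b, a] <- TRUE
  m
}

#' @export
print.edge_mask <- function(x, ...) {
  p <- nrow(x$mask)
  cat(sprintf(
    "<edge_mask> %d parcels, %d / %d edges excluded (surrogate threshold %.3g)\n",
    p, x$n_excluded, p * (p - 1) / 2, x$threshold
  ))
  invisible(x)
}
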