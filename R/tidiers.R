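# broom-style tidiers for the fitted result objects.

#' Tidy an NBS result
#'
#' @param x An `nbs_result` from [nbs_extent_test()].
#' @param type `"components"` (default, one row per component) or `"edges"`
#'   (one row per component edge with its t statistic).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nbs_result <- function(x, type = c("components", "edges"), ...) {
  type <- match.arg(type)
  base <- as_tibble(x)
  if (type == "components") {
    return(dplyr::select(base, -"edges"))
  }
  if (!nrow(base)) {
    return(tibble(
      component = integer(), i = integer(), j = integer(), t = numeric()
    ))
  }
  base |>
    dplyr::select("component", "contrast", "direction", "p_fwe", "edges") |>
    tidyr::unnest("edges")
}

#' One-row summary of an NBS result
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return Tibble with the number of components, the minimum family-wise
#'   p-value, the largest extent, and the test parameters.
#' @export
glance.nbs_result <- function(x, ...) {
  tibble(
    n_components = nrow(x),
    min_p_fwe = if (nrow(x)) min(x$p_fwe) else NA_real_,
    max_extent = if (nrow(x)) max(x$extent) else 0L,
    t_threshold = attr(x, "t_threshold"),
    n_perm = attr(x, "n_perm"),
    df = attr(x, "df"),
    exhaustive = attr(x, "exhaustive")
  )
}

#' @export
tidy.outcome_correlations <- function(x, ...) as_tibble(x)

#' @export
glance.outcome_correlations <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_significant = sum(x$p_fdr < 0.05, na.rm = TRUE),
    min_p_fdr = suppressWarnings(min(x$p_fdr, na.rm = TRUE))
  )
}

#' @export
tidy.cyto_test_result <- function(x, ...) as_tibble(x)

#' @export
glance.cyto_test_result <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_significant = sum(x$p_fdr < 0.05),
    max_D = max(x$D)
  )
}

#' @export
tidy.edge_mask <- function(x, ...) {
  p <- nrow(x$mask)
  ut <- which(upper.tri(x$mask), arr.ind = TRUE)
  tibble(
    i = ut[, 1], j = ut[, 2],
    fidelity = x$fidelity[ut], valid = x$mask[ut] == 1
  )
}

#' @export
glance.edge_mask <- function(x, ...) {
  p <- nrow(x$mask)
  tibble(
    n_parcels = p,
    n_edges = p * (p - 1) / 2,
    n_excluded = x$n_excluded,
    threshold = x$threshold,
    n_iter = x$n_iter
  )
}
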