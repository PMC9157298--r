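# Per-layer neuronal-density profiling of networks against the whole cortex.

#' Project a cytoarchitectonic atlas onto the source space
#'
#' Associates every source with the six per-layer neuronal densities of its
#' region. Atlas regions are matched first by parcel name, then by the
#' coarse lobar label (`frontal`/`central`/`temporal`/`occipital`); a source
#' whose parcel matches neither raises an error listing the offending
#' sources.
#'
#' @param atlas Tibble `region`, `layer` (1–6), `density` (> 0, all 6 layers
#'   per region).
#' @param parc A `parcellation`.
#' @return Tibble `source`, `parcel`, `layer`, `density` (6 rows per source).
#' @export
project_atlas <- function(atlas, parc) {
  atlas <- as_tibble(atlas)
  stopifnot(all(c("region", "layer", "density") %in% names(atlas)))
  if (any(atlas$density <= 0)) {
    abort("densities must be positive", class = "neonet_invalid_config")
  }
  cnt <- atlas |>
    dplyr::count(.data$region) |>
    dplyr::pull(n)
  if (any(cnt != 6L)) {
    abort("every atlas region needs exactly 6 layers", class = "neonet_invalid_config")
  }
  parcels <- parc$parcels
  region_of_parcel <- ifelse(
    parcels$name %in% atlas$region, parcels$name,
    ifelse(parcels$region %in% atlas$region, parcels$region, NA_character_)
  )
  bad <- which(is.na(region_of_parcel[parc$assignment]))
  if (length(bad)) {
    abort(
      sprintf(
        "no atlas region covers source(s): %s",
        toString(head(bad, 10L))
      ),
      class = "neonet_projection_error"
    )
  }
  src <- tibble(
    source = seq_along(parc$assignment),
    parcel = parc$assignment,
    region = region_of_parcel[parc$assignment]
  )
  dplyr::left_join(src, atlas, by = "region",
    relationship = "many-to-many"
  ) |>
    dplyr::select("source", "parcel", "layer", "density")
}

#' Per-layer density profile of a network
#'
#' The network's cytoarchitectonic profile: for each layer, the densities of
#' all sources belonging to parcels incident to at least one network edge.
#' Duplicate edges do not change the profile.
#'
#' @param network Edge set tibble (`i`, `j`), non-empty.
#' @param projected Source-level densities from [project_atlas()].
#' @return Tibble `layer`, `density` (one row per source x layer).
#' @export
network_density_profile <- function(network, projected) {
  if (is.null(network) || !nrow(network)) {
    abort("network is empty", class = "neonet_invalid_config")
  }
  parcels <- unique(c(network$i, network$j))
  projected |>
    dplyr::filter(.data$parcel %in% parcels) |>
    dplyr::select("layer", "density")
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The maximal distance between the empirical cumulative distribution
#' functions of two samples, `D = sup |ECDF_a - ECDF_b|`, computed directly
#' from the pooled sorted values. Invariant under any strictly monotone
#' transform of the measurement scale.
#'
#' @param a,b Non-empty numeric samples.
#' @return `D` in `[0, 1]`.
#' @examples
#' ks_two_sample(c(1, 2, 3, 4), c(3, 4, 5, 6)) # 0.5
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) {
    abort("both samples must be non-empty", class = "neonet_invalid_config")
  }
  ks_vs_sorted_ref(a, sort(b))
}

# D between a sample and a pre-sorted reference: both ECDFs evaluated at the
# pooled jump points via findInterval (counts of values <= t), which handles
# ties correctly.
ks_vs_sorted_ref <- function(x, ref_sorted) {
  x <- sort(x)
  pooled <- unique(c(x, ref_sorted))
  fx <- findInterval(pooled, x) / length(x)
  fr <- findInterval(pooled, ref_sorted) / length(ref_sorted)
  max(abs(fx - fr))
}

#' Surrogate-network test of a cytoarchitectonic profile
#'
#' Compares the per-layer density distribution of a network's sources with
#' the whole-cortex distribution by the two-sample KS statistic, and
#' calibrates each layer's D against `n_surrogates` networks of the same
#' size: parcel sets of equal cardinality sampled uniformly without
#' replacement (profiles depend only on incident parcels, so matching is at
#' the node level). `p_surrogate = (1 + #{D_surr >= D_obs}) /
#' (n_surrogates + 1)` (observed included in the null).
#'
#' @param network Edge set tibble (`i`, `j`).
#' @param parc A `parcellation`.
#' @param projected Source densities from [project_atlas()].
#' @param n_surrogates Number of surrogate networks (default 1000).
#' @param seed Integer seed.
#' @param network_name Label for the result rows.
#' @return Tibble `network`, `layer`, `n_network`, `D`, `direction`
#'   (`"higher"`/`"lower"` by median), `p_surrogate`. Apply
#'   [cyto_adjust_family()] across all tested networks for `p_fdr`.
#' @export
surrogate_network_test <- function(network, parc, projected,
                                   n_surrogates = 1000, seed = 1,
                                   network_name = "network") {
  assert_count(n_surrogates, "n_surrogates")
  net_parcels <- unique(c(network$i, network$j))
  m <- length(net_parcels)
  all_parcels <- seq_len(parc$n_parcels)
  if (m >= parc$n_parcels) {
    warn("network spans the whole cortex: surrogate null is degenerate")
  }
  by_layer <- split(projected, projected$layer)

  rows <- lapply(sort(unique(projected$layer)), function(layer) {
    lay <- by_layer[[as.character(layer)]]
    cortex <- sort(lay$density)
    obs_sample <- lay$density[lay$parcel %in% net_parcels]
    d_obs <- ks_vs_sorted_ref(obs_sample, cortex)
    d_surr <- with_seed(child_seed(seed, layer), {
      vapply(seq_len(n_surrogates), function(k) {
        sel <- sample(all_parcels, m)
        ks_vs_sorted_ref(lay$density[lay$parcel %in% sel], cortex)
      }, numeric(1))
    })
    tibble(
      network = network_name, layer = layer, n_network = m,
      D = d_obs,
      direction = if (median(obs_sample) >= median(lay$density)) "higher" else "lower",
      p_surrogate = (1 + sum(d_surr >= d_obs)) / (n_surrogates + 1)
    )
  })
  dplyr::bind_rows(rows)
}

#' Benjamini-Hochberg adjustment over a network-by-layer test family
#'
#' @param results Bound rows from [surrogate_network_test()] over all tested
#'   networks (e.g. 5 networks x 6 layers = 30 tests).
#' @return The same tibble with a `p_fdr` column (class `cyto_test_result`).
#' @export
cyto_adjust_family <- function(results) {
  out <- dplyr::mutate(results, p_fdr = p.adjust(.data$p_surrogate, method = "BH"))
  structure(out, class = c("cyto_test_result", class(out)))
}
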