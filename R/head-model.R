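#' Toy spherical head model and cortical parcellation
#'
#' Builds a deterministic lead field and parcellation for simulation and
#' testing. Parcels are placed on the unit sphere (Fibonacci lattice) and
#' labelled frontal/central/temporal/occipital by their position; sources are
#' assigned round-robin to parcels and scattered around their parcel centroid;
#' sensors sit on a concentric shell at radius 1.1. The gain of source j at
#' sensor i is the quasi-static dipole potential
#' `o_j . (r_i - p_j) / |r_i - p_j|^3` with radial (surface-orthogonal) fixed
#' orientations. With `mixing = "identity"` (requires
#' `n_sensors == n_sources == n_parcels`) the lead field is the identity and
#' parcel i contains exactly source i — the fully observable reference model.
#'
#' @param config A [study_config()]; uses `n_sensors`, `n_sources`,
#'   `n_parcels`, `mixing` and `seed`.
#' @return List with elements `lead_field` (class `lead_field`: `matrix`
#'   sensors x sources, `sensor_positions`, `source_positions`,
#'   `source_orientations`) and `parcellation` (class `parcellation`:
#'   `assignment` source -> parcel, `parcels` tibble with `parcel`, `name`,
#'   `region`, `x`, `y`, `z`, and unit `fidelity_weights`).
#' @examples
#' hm <- generate_head_model(study_config(n_sensors = 8, n_sources = 16, n_parcels = 8))
#' dim(hm$lead_field$matrix)
#' @export
generate_head_model <- function(config) {
  n_sensors <- assert_count(config$n_sensors, "n_sensors")
  n_sources <- assert_count(config$n_sources, "n_sources")
  n_parcels <- assert_count(config$n_parcels, "n_parcels")
  if (n_sensors < 4L) {
    abort("need at least 4 sensors", class = "neonet_invalid_config")
  }
  if (n_parcels > n_sources) {
    abort("`n_parcels` cannot exceed `n_sources`", class = "neonet_invalid_config")
  }
  mixing <- config$mixing %||% "geometric"

  centroids <- fibonacci_sphere(n_parcels)
  region <- parcel_region_labels(centroids)
  parcels <- tibble(
    parcel = seq_len(n_parcels),
    name = sprintf("P%02d", seq_len(n_parcels)),
    region = region,
    x = centroids[, 1], y = centroids[, 2], z = centroids[, 3]
  )
  assignment <- rep(seq_len(n_parcels), length.out = n_sources)

  if (identical(mixing, "identity")) {
    if (n_sensors != n_sources || n_sources != n_parcels) {
      abort("identity mixing requires n_sensors == n_sources == n_parcels",
        class = "neonet_invalid_config"
      )
    }
    src_pos <- centroids
    lf_mat <- diag(n_sources)
  } else {
    src_pos <- with_seed(child_seed(config$seed %||% 1, 11), {
      jitter <- matrix(rnorm(n_sources * 3, sd = 0.15), ncol = 3)
      p <- centroids[assignment, , drop = FALSE] + jitter
      p / sqrt(rowSums(p^2))
    })
    sens_pos <- fibonacci_sphere(n_sensors) * 1.1
    lf_mat <- dipole_gain(sens_pos, src_pos, src_pos) # radial orientations
  }
  if (any(!is.finite(lf_mat)) || any(colSums(lf_mat^2) == 0)) {
    abort("lead field has non-finite or all-zero columns", class = "neonet_error")
  }

  lead_field <- structure(
    list(
      matrix = lf_mat,
      sensor_positions = if (identical(mixing, "identity")) centroids * 1.1 else sens_pos,
      source_positions = src_pos,
      source_orientations = src_pos / sqrt(rowSums(src_pos^2))
    ),
    class = "lead_field"
  )
  parcellation <- structure(
    list(
      assignment = assignment,
      n_parcels = n_parcels,
      parcels = parcels,
      fidelity_weights = rep(1, n_sources)
    ),
    class = "parcellation"
  )
  list(lead_field = lead_field, parcellation = parcellation)
}

# Anterior parcels are frontal, posterior occipital, inferior lateral
# temporal, superior central — a coarse stand-in for lobar labels.
parcel_region_labels <- function(centroids) {
  ifelse(centroids[, 1] > 0.3, "frontal",
    ifelse(centroids[, 1] < -0.3, "occipital",
      ifelse(centroids[, 3] < 0, "temporal", "central")
    )
  )
}

# Quasi-static dipole gain: sensors x sources.
dipole_gain <- function(sensor_pos, source_pos, orientations) {
  ns <- nrow(sensor_pos)
  nq <- nrow(source_pos)
  g <- matrix(0, ns, nq)
  for (j in seq_len(nq)) {
    d <- sweep(sensor_pos, 2L, source_pos[j, ])
    r3 <- (rowSums(d^2))^1.5
    g[, j] <- (d %*% orientations[j, ]) / r3
  }
  g
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf(
    "<lead_field> %d sensors x %d sources\n",
    nrow(x$matrix), ncol(x$matrix)
  ))
  invisible(x)
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf(
    "<parcellation> %d sources -> %d parcels (%s)\n",
    length(x$assignment), x$n_parcels,
    paste(sprintf(
      "%s: %d", names(table(x$parcels$region)),
      as.integer(table(x$parcels$region))
    ), collapse = ", ")
  ))
  invisible(x)
}

# Sources belonging to each parcel, as a list of index vectors.
parcel_members <- function(parc) {
  split(seq_along(parc$assignment), parc$assignment)[as.character(seq_len(parc$n_parcels))]
}
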