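#' Configuration of a synthetic two-group, two-state EEG study
#'
#' Bundles every knob of the synthetic cohort: sample sizes (defaults mirror
#' the exposed/control design of 46 vs 61 subjects recorded in both active
#' and quiet sleep), the 19-sensor montage, the 58-parcel source model, the
#' 100 Hz working rate with 6 x 30 s analysis windows, the four neonatal
#' frequency bands, and the planted coupling structure: an edge set coupled
#' in AS for group A and in QS for group B, so the AS − QS difference has
#' opposite sign in the two groups (a pure sleep-by-group interaction).
#'
#' @param n_group_a,n_group_b Subjects per group.
#' @param n_sensors,n_sources,n_parcels Head-model dimensions.
#' @param sampling_rate Working sampling rate, Hz.
#' @param epoch_windows,window_length Analysis windows per state and their
#'   length in seconds.
#' @param bands Tibble of bands (default [neonatal_bands()]); must be
#'   ordered, non-overlapping and inside (0, Nyquist).
#' @param planted_edges `NULL` for the default interaction layout (disjoint
#'   edge pairs among the first parcels, coupled in AS for group A and QS for
#'   group B), an explicit list
#'   `list(A = list(AS = edges, QS = edges), B = ...)` with `i`/`j` tibbles,
#'   or `"none"`.
#' @param planted_band Name of the band carrying the planted coupling.
#' @param coupling_strength Planted coupling in `[0, 1]` (0 disables all
#'   planted structure).
#' @param coupling_sd Between-subject SD of the planted coupling.
#' @param phase_lag Planted phase lag in radians.
#' @param noise_sd Additive white sensor-noise scale is set by `snr_db`;
#'   `noise_sd` adds extra white noise at parcel level (default 0.3).
#' @param snr_db Sensor signal-to-noise ratio in dB (default 10).
#' @param outcome_effect Target Spearman correlation between the true planted
#'   AS − QS coupling difference and the linked outcome scores in group A.
#' @param atlas_layer3_shift Shift of layer-III neuronal density in network
#'   regions, in SD units of the between-region density spread (default 0).
#' @param subgroup_sizes Optional named integer vector partitioning (part of)
#'   group A into exposure subgroups.
#' @param mixing `"geometric"` toy dipole lead field or `"identity"`.
#' @param margin Fractional extra recording length beyond the windows
#'   (default 0.2).
#' @param seed Master seed; the whole study regenerates bit-identically.
#' @return Object of class `study_config` (a named list).
#' @examples
#' cfg <- study_config(n_group_a = 4, n_group_b = 4, n_parcels = 8, n_sources = 16)
#' @export
study_config <- function(n_group_a = 46, n_group_b = 61,
                         n_sensors = 19, n_sources = 232, n_parcels = 58,
                         sampling_rate = 100,
                         epoch_windows = 6, window_length = 30,
                         bands = neonatal_bands(),
                         planted_edges = NULL, planted_band = "high_delta",
                         coupling_strength = 0.5, coupling_sd = 0.15,
                         phase_lag = pi / 2, noise_sd = 0.3, snr_db = 10,
                         outcome_effect = 0.4, atlas_layer3_shift = 0,
                         subgroup_sizes = NULL,
                         mixing = "geometric", margin = 0.2, seed = 1) {
  for (nm in c(
    "n_group_a", "n_group_b", "n_sensors", "n_sources", "n_parcels",
    "epoch_windows"
  )) {
    assert_count(get(nm), nm)
  }
  if (n_parcels > n_sources) {
    abort("`n_parcels` cannot exceed `n_sources`", class = "neonet_invalid_config")
  }
  assert_prob(coupling_strength, "coupling_strength")
  if (sampling_rate <= 0 || window_length <= 0) {
    abort("rates and lengths must be positive", class = "neonet_invalid_config")
  }
  bands <- as_tibble(bands)
  if (any(bands$low >= bands$high) || any(bands$high >= sampling_rate / 2) ||
    any(bands$low <= 0) || is.unsorted(bands$low) ||
    (nrow(bands) > 1L && any(bands$low[-1L] < bands$high[-nrow(bands)]))) {
    abort("bands must be ordered, non-overlapping and within (0, Nyquist)",
      class = "neonet_invalid_config"
    )
  }
  if (!planted_band %in% bands$name) {
    abort("`planted_band` must name one of the bands", class = "neonet_invalid_config")
  }
  if (!is.null(subgroup_sizes) && sum(subgroup_sizes) > n_group_a) {
    abort("subgroup sizes exceed group A", class = "neonet_invalid_config")
  }
  cfg <- list(
    n_group_a = n_group_a, n_group_b = n_group_b,
    n_sensors = n_sensors, n_sources = n_sources, n_parcels = n_parcels,
    sampling_rate = sampling_rate,
    epoch_windows = epoch_windows, window_length = window_length,
    bands = bands, planted_edges = planted_edges, planted_band = planted_band,
    coupling_strength = coupling_strength, coupling_sd = coupling_sd,
    phase_lag = phase_lag, noise_sd = noise_sd, snr_db = snr_db,
    outcome_effect = outcome_effect, atlas_layer3_shift = atlas_layer3_shift,
    subgroup_sizes = subgroup_sizes,
    mixing = mixing, margin = margin, seed = seed
  )
  cfg$planted_edges <- resolve_planted_edges(cfg)
  structure(cfg, class = "study_config")
}

# Default interaction layout: up to 4 disjoint edges among the first parcels;
# group A couples them in AS, group B in QS. coupling_strength == 0 or
# planted_edges == "none" empties the truth sets.
resolve_planted_edges <- function(cfg) {
  pe <- cfg$planted_edges
  none <- list(
    A = list(AS = tibble(i = integer(), j = integer()), QS = tibble(i = integer(), j = integer())),
    B = list(AS = tibble(i = integer(), j = integer()), QS = tibble(i = integer(), j = integer()))
  )
  if (identical(pe, "none") || cfg$coupling_strength == 0) {
    return(none)
  }
  if (is.null(pe)) {
    k <- min(4L, floor(cfg$n_parcels / 2))
    if (k < 1L) {
      return(none)
    }
    e <- tibble(i = seq(1L, 2L * k, by = 2L), j = seq(2L, 2L * k, by = 2L))
    pe <- list(
      A = list(AS = e, QS = e[0, ]),
      B = list(AS = e[0, ], QS = e)
    )
  }
  for (g in names(pe)) {
    for (st in names(pe[[g]])) {
      e <- as_tibble(pe[[g]][[st]])
      if (nrow(e) && (any(e$i == e$j) | any(e$i < 1) | any(e$j > cfg$n_parcels))) {
        abort("planted edges must be valid distinct parcel pairs",
          class = "neonet_invalid_config"
        )
      }
      pe[[g]][[st]] <- e
    }
  }
  pe
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "<study_config> %d + %d subjects, %d sensors, %d sources -> %d parcels, %g Hz, %d x %g s windows, %d bands, seed %s\n",
    x$n_group_a, x$n_group_b, x$n_sensors, x$n_sources, x$n_parcels,
    x$sampling_rate, x$epoch_windows, x$window_length, nrow(x$bands),
    format(x$seed)
  ))
  invisible(x)
}

#' Generate a complete synthetic study
#'
#' Builds the toy head model, simulates per-subject sensor recordings for
#' both sleep states (band-limited parcel background in every analysis band
#' with 1/f-like amplitudes, planted phase coupling on the configured edges,
#' projection through the lead field, white sensor noise at the configured
#' SNR), and generates outcome scores and a per-region cytoarchitectonic
#' atlas linked to the planted structure. Regeneration with the same config
#' (same seed) is bit-identical.
#'
#' @param config A [study_config()].
#' @return Object of class `synthetic_study`: list with `config`,
#'   `lead_field`, `parcellation`, `recordings` (per subject: list with
#'   elements `AS` and `QS`, each a [sensor_recording()]), `subjects`
#'   (tibble with `subject`, `group`, `subgroup`), `truth` (planted couplings
#'   per subject/state/edge and per-subject `delta_true`), `outcomes`,
#'   `hnne_items`, `atlas`.
#' @examples
#' cfg <- study_config(
#'   n_group_a = 2, n_group_b = 2, n_sensors = 8, n_sources = 16,
#'   n_parcels = 8, epoch_windows = 2, window_length = 5
#' )
#' study <- generate_cohort(cfg)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dur <- config$epoch_windows * config$window_length
  n_samp <- ceiling(dur * (1 + config$margin) * config$sampling_rate)
  if (n_samp < config$epoch_windows * config$window_length * config$sampling_rate) {
    abort("recording shorter than the requested windows", class = "neonet_invalid_config")
  }
  hm <- generate_head_model(config)
  g <- hm$lead_field$matrix
  n <- config$n_group_a + config$n_group_b
  group <- rep(c("A", "B"), c(config$n_group_a, config$n_group_b))
  subjects <- sprintf("S%03d", seq_len(n))
  subgroup <- rep(NA_character_, n)
  if (!is.null(config$subgroup_sizes)) {
    subgroup[seq_len(sum(config$subgroup_sizes))] <-
      rep(names(config$subgroup_sizes), config$subgroup_sizes)
  }
  band_amp <- 1 / sqrt((config$bands$low + config$bands$high) / 2)
  planted_band_idx <- match(config$planted_band, config$bands$name)

  recordings <- vector("list", n)
  names(recordings) <- subjects
  truth_rows <- list()

  for (s in seq_len(n)) {
    recs <- list()
    for (st in c("AS", "QS")) {
      seed_s <- child_seed(config$seed, 100 + s * 7 + (st == "QS") * 3)
      planted <- config$planted_edges[[group[s]]][[st]]
      sim <- with_seed(seed_s, simulate_state_recording(
        config, hm, g, n_samp, planted, band_amp, planted_band_idx, st
      ))
      recs[[st]] <- sim$rec
      if (nrow(sim$couplings)) {
        truth_rows[[length(truth_rows) + 1L]] <- dplyr::mutate(
          sim$couplings,
          subject = subjects[s], group = group[s], state = st
        )
      }
    }
    recordings[[s]] <- recs
  }
  truth_edges <- if (length(truth_rows)) {
    dplyr::bind_rows(truth_rows)
  } else {
    tibble(
      i = integer(), j = integer(), coupling = numeric(),
      subject = character(), group = character(), state = character()
    )
  }
  delta_true <- subject_delta_truth(truth_edges, subjects, group)

  outcomes <- with_seed(
    child_seed(config$seed, 5),
    generate_outcomes(subjects, group, delta_true$delta_true, config$outcome_effect)
  )
  network_parcels <- unique(unlist(lapply(config$planted_edges, function(gl) {
    unlist(lapply(gl, function(e) c(e$i, e$j)))
  })))
  atlas <- with_seed(
    child_seed(config$seed, 6),
    generate_cyto_atlas(hm$parcellation,
      layer3_shift = config$atlas_layer3_shift,
      shifted_parcels = network_parcels
    )
  )

  structure(
    list(
      config = config,
      lead_field = hm$lead_field,
      parcellation = hm$parcellation,
      recordings = recordings,
      subjects = tibble(subject = subjects, group = group, subgroup = subgroup),
      truth = list(
        planted = config$planted_edges, couplings = truth_edges,
        delta_true = delta_true
      ),
      outcomes = outcomes$scores,
      hnne_items = outcomes$items,
      atlas = atlas
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d subjects (%d A / %d B), %d parcels, %d bands, seed %s\n",
    nrow(x$subjects), sum(x$subjects$group == "A"), sum(x$subjects$group == "B"),
    x$parcellation$n_parcels, nrow(x$config$bands), format(x$config$seed)
  ))
  invisible(x)
}

# One subject-state recording: per-band parcel background, planted coupled
# pairs in the planted band, lead-field projection, sensor noise at snr_db.
simulate_state_recording <- function(config, hm, g, n_samp, planted,
                                     band_amp, planted_band_idx, state = "AS") {
  p <- config$n_parcels
  fs <- config$sampling_rate
  parcel_sig <- matrix(0, p, n_samp)
  couplings <- tibble(i = integer(), j = integer(), coupling = numeric())
  for (b in seq_len(nrow(config$bands))) {
    band <- c(config$bands$low[b], config$bands$high[b])
    comp <- matrix(0, p, n_samp)
    for (q in seq_len(p)) {
      comp[q, ] <- Re(band_limited_analytic(n_samp, fs, band))
    }
    if (b == planted_band_idx && nrow(planted)) {
      for (k in seq_len(nrow(planted))) {
        cc <- pmin(1, pmax(0, config$coupling_strength +
          rnorm(1, 0, config$coupling_sd)))
        driver <- band_limited_analytic(n_samp, fs, band)
        ei <- planted$i[k]
        ej <- planted$j[k]
        comp[ei, ] <- Re(sqrt(cc) * driver +
          sqrt(1 - cc) * band_limited_analytic(n_samp, fs, band))
        comp[ej, ] <- Re(sqrt(cc) * driver * exp(-1i * config$phase_lag) +
          sqrt(1 - cc) * band_limited_analytic(n_samp, fs, band))
        couplings <- dplyr::bind_rows(
          couplings,
          tibble(i = ei, j = ej, coupling = cc)
        )
      }
    }
    parcel_sig <- parcel_sig + band_amp[b] * comp
  }
  if (config$noise_sd > 0) {
    parcel_sig <- parcel_sig + matrix(
      rnorm(p * n_samp, sd = config$noise_sd), p, n_samp
    )
  }
  src <- parcel_sig[hm$parcellation$assignment, , drop = FALSE]
  sensors <- g %*% src
  sig_pow <- mean(sensors^2)
  noise_pow <- sig_pow / 10^(config$snr_db / 10)
  sensors <- sensors + matrix(
    rnorm(length(sensors), sd = sqrt(noise_pow)),
    nrow(sensors), ncol(sensors)
  )
  rec <- sensor_recording(
    sensors, fs,
    channel_names = paste0("E", seq_len(nrow(sensors))),
    annotations = tibble(state = state, start = 0, end = n_samp / fs)
  )
  list(rec = rec, couplings = couplings)
}

# True per-subject network-level AS - QS coupling difference, averaged over
# the union of planted edges (states where an edge is uncoupled count as 0).
subject_delta_truth <- function(truth_edges, subjects, group) {
  base <- tibble(subject = subjects, group = group)
  if (!nrow(truth_edges)) {
    return(dplyr::mutate(base, delta_true = 0))
  }
  per <- truth_edges |>
    tidyr::pivot_wider(
      names_from = "state", values_from = "coupling", values_fill = 0
    )
  if (!"AS" %in% names(per)) per$AS <- 0
  if (!"QS" %in% names(per)) per$QS <- 0
  per <- per |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(delta_true = mean(.data$AS - .data$QS), .groups = "drop")
  dplyr::left_join(base, per, by = "subject") |>
    dplyr::mutate(delta_true = dplyr::coalesce(.data$delta_true, 0))
}

# Outcome tables: HNNE-like item scores with a two-factor structure, their
# composites C1/C2 (C2 negatively copula-linked to the true difference), and
# BSID-like compound scores with fine_motor positively linked. Two group-A
# subjects lose their 2-year scores to mirror per-assessment availability.
generate_outcomes <- function(subjects, group, delta_true, outcome_effect) {
  n <- length(subjects)
  a <- group == "A"
  f1 <- rnorm(n)
  f2 <- (copula_linked_score(delta_true, -outcome_effect, a) - 100) / 15
  loadings1 <- c(0.9, 0.8, 0.7, 0.75, 0.1, 0.15, 0.05, 0.1)
  loadings2 <- c(0.1, 0.05, 0.15, 0.1, 0.85, 0.8, 0.9, 0.7)
  items <- sapply(seq_along(loadings1), function(k) {
    loadings1[k] * f1 + loadings2[k] * f2 + rnorm(n, sd = 0.3)
  })
  colnames(items) <- paste0("item", seq_len(ncol(items)))
  items_tbl <- dplyr::bind_cols(tibble(subject = subjects), as_tibble(items))
  scores <- tibble(
    subject = subjects,
    group = group,
    C1 = f1 + rnorm(n, sd = 0.2),
    C2 = f2 + rnorm(n, sd = 0.2),
    cognitive = 100 + 15 * rnorm(n),
    receptive_language = 100 + 15 * rnorm(n),
    expressive_language = 100 + 15 * rnorm(n),
    fine_motor = copula_linked_score(delta_true, outcome_effect, a)
  )
  if (sum(a) > 5L) {
    drop <- sample(which(a), 2L)
    scores[drop, c(
      "cognitive", "receptive_language",
      "expressive_language", "fine_motor"
    )] <- NA_real_
  }
  list(scores = scores, items = items_tbl)
}

#' Synthetic cytoarchitectonic atlas
#'
#' One region per parcel with six per-layer neuronal densities
#' (neurons/mm^3): layer-specific baselines with log-normal between-region
#' variation, optionally shifting layer III upward in a chosen parcel set by
#' `layer3_shift` between-region standard deviations.
#'
#' @param parc A `parcellation`.
#' @param layer3_shift Shift in SD units (default 0).
#' @param shifted_parcels Parcel ids receiving the shift.
#' @return Tibble with columns `region`, `layer`, `density`.
#' @export
generate_cyto_atlas <- function(parc, layer3_shift = 0, shifted_parcels = integer(0)) {
  baselines <- c(30, 90, 70, 110, 60, 50) * 1000
  p <- parc$n_parcels
  rows <- lapply(1:6, function(layer) {
    dens <- baselines[layer] * exp(rnorm(p, sd = 0.15))
    if (layer == 3L && layer3_shift != 0 && length(shifted_parcels)) {
      dens[shifted_parcels] <- dens[shifted_parcels] +
        layer3_shift * sd(dens)
    }
    tibble(region = parc$parcels$name, layer = layer, density = dens)
  })
  dplyr::bind_rows(rows)
}
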