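# Directory serialization of a synthetic study: delimited text plus JSON
# sidecars, so a study can be regenerated, archived and re-read without any
# binary formats.

#' Write a synthetic study to a directory
#'
#' Layout: `config.json`; `lead_field.csv` (sensors x sources);
#' `parcellation.csv` (per source: parcel, fidelity weight) and
#' `parcels.csv` (per parcel: name, region, centroid); `outcomes.csv`,
#' `hnne_items.csv`, `atlas.csv`, `truth_couplings.csv`, `subjects.csv`; and
#' under `recordings/`, per subject and state a samples x channels CSV with a
#' JSON sidecar holding the sampling rate, channel names and annotations.
#'
#' @param study A `synthetic_study`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "recordings"), recursive = TRUE, showWarnings = FALSE)
  cfg <- study$config
  cfg_json <- unclass(cfg)
  cfg_json$bands <- as.data.frame(cfg$bands)
  cfg_json$planted_edges <- lapply(cfg$planted_edges, function(gl) {
    lapply(gl, as.data.frame)
  })
  jsonlite::write_json(cfg_json, file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(
    as.data.frame(study$lead_field$matrix),
    file.path(dir, "lead_field.csv")
  )
  readr::write_csv(
    tibble(
      source = seq_along(study$parcellation$assignment),
      parcel = study$parcellation$assignment,
      weight = study$parcellation$fidelity_weights
    ),
    file.path(dir, "parcellation.csv")
  )
  readr::write_csv(study$parcellation$parcels, file.path(dir, "parcels.csv"))
  readr::write_csv(study$subjects, file.path(dir, "subjects.csv"))
  readr::write_csv(study$outcomes, file.path(dir, "outcomes.csv"))
  readr::write_csv(study$hnne_items, file.path(dir, "hnne_items.csv"))
  readr::write_csv(study$atlas, file.path(dir, "atlas.csv"))
  readr::write_csv(study$truth$couplings, file.path(dir, "truth_couplings.csv"))
  for (subj in names(study$recordings)) {
    for (st in names(study$recordings[[subj]])) {
      rec <- study$recordings[[subj]][[st]]
      stem <- file.path(dir, "recordings", paste0(subj, "_", st))
      readr::write_csv(
        as.data.frame(t(rec$data)),
        paste0(stem, ".csv"),
        col_names = FALSE
      )
      jsonlite::write_json(
        list(
          sampling_rate = rec$sampling_rate,
          channel_names = rec$channel_names,
          annotations = as.data.frame(rec$annotations)
        ),
        paste0(stem, ".json"),
        auto_unbox = TRUE, digits = NA
      )
    }
  }
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Directory path.
#' @return A `synthetic_study` (truth restricted to what was serialized).
#' @export
read_study <- function(dir) {
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  pe <- lapply(cfg_raw$planted_edges, function(gl) lapply(gl, as_tibble))
  cfg <- study_config(
    n_group_a = cfg_raw$n_group_a, n_group_b = cfg_raw$n_group_b,
    n_sensors = cfg_raw$n_sensors, n_sources = cfg_raw$n_sources,
    n_parcels = cfg_raw$n_parcels, sampling_rate = cfg_raw$sampling_rate,
    epoch_windows = cfg_raw$epoch_windows, window_length = cfg_raw$window_length,
    bands = as_tibble(cfg_raw$bands), planted_edges = pe,
    planted_band = cfg_raw$planted_band,
    coupling_strength = cfg_raw$coupling_strength,
    coupling_sd = cfg_raw$coupling_sd, phase_lag = cfg_raw$phase_lag,
    noise_sd = cfg_raw$noise_sd, snr_db = cfg_raw$snr_db,
    outcome_effect = cfg_raw$outcome_effect,
    atlas_layer3_shift = cfg_raw$atlas_layer3_shift,
    mixing = cfg_raw$mixing, margin = cfg_raw$margin, seed = cfg_raw$seed
  )
  lf_mat <- as.matrix(readr::read_csv(file.path(dir, "lead_field.csv"),
    show_col_types = FALSE
  ))
  dimnames(lf_mat) <- NULL
  parc_src <- readr::read_csv(file.path(dir, "parcellation.csv"),
    show_col_types = FALSE
  )
  parcels <- readr::read_csv(file.path(dir, "parcels.csv"), show_col_types = FALSE)
  subjects <- readr::read_csv(file.path(dir, "subjects.csv"),
    show_col_types = FALSE,
    col_types = readr::cols(subgroup = readr::col_character())
  )
  parcellation <- structure(
    list(
      assignment = parc_src$parcel, n_parcels = nrow(parcels),
      parcels = parcels, fidelity_weights = parc_src$weight
    ),
    class = "parcellation"
  )
  lead_field <- structure(
    list(
      matrix = lf_mat, sensor_positions = NULL,
      source_positions = NULL, source_orientations = NULL
    ),
    class = "lead_field"
  )
  recordings <- list()
  for (subj in subjects$subject) {
    recs <- list()
    for (st in c("AS", "QS")) {
      stem <- file.path(dir, "recordings", paste0(subj, "_", st))
      side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
      dat <- t(as.matrix(readr::read_csv(paste0(stem, ".csv"),
        col_names = FALSE, show_col_types = FALSE
      )))
      dimnames(dat) <- NULL
      recs[[st]] <- sensor_recording(
        dat, side$sampling_rate, side$channel_names,
        as_tibble(side$annotations)
      )
    }
    recordings[[subj]] <- recs
  }
  structure(
    list(
      config = cfg, lead_field = lead_field, parcellation = parcellation,
      recordings = recordings, subjects = subjects,
      truth = list(
        planted = cfg$planted_edges,
        couplings = readr::read_csv(file.path(dir, "truth_couplings.csv"),
          show_col_types = FALSE
        ),
        delta_true = NULL
      ),
      outcomes = readr::read_csv(file.path(dir, "outcomes.csv"),
        show_col_types = FALSE
      ),
      hnne_items = readr::read_csv(file.path(dir, "hnne_items.csv"),
        show_col_types = FALSE
      ),
      atlas = readr::read_csv(file.path(dir, "atlas.csv"), show_col_types = FALSE)
    ),
    class = "synthetic_study"
  )
}
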