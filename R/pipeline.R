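# End-to-end orchestration: config -> preprocessed epochs -> parcel signals
# -> masked connectivity -> network statistics -> outcome correlation ->
# cytoarchitectonic profiling, with a reproducibility manifest.

#' Run the full study pipeline
#'
#' Executes, in order: cohort generation (or loading), dSPM inverse modelling
#' with fidelity-weighted parcel collapse, per-band edge-fidelity masking,
#' zero-phase band filtering with average montage and equidistant epoch
#' selection, debiased wPLI connectivity per subject/state/band, NBS for the
#' sleep, group and sleep-by-group contrasts in every band, Spearman
#' correlation of the significant interaction networks' AS − QS dynamics
#' (within the exposed group) with the outcome scores, optional per-subgroup
#' interaction contrasts, and cytoarchitectonic surrogate tests of every
#' significant interaction network.
#'
#' @param x A [study_config()], a `synthetic_study`, or a directory written
#'   by [write_study()].
#' @param t_threshold NBS edge-forming t threshold (default 2.5).
#' @param n_perm NBS permutations (default 5000).
#' @param fidelity_iter Iterations per edge in the fidelity mask (default
#'   500).
#' @param fidelity_percentile Surrogate percentile of the mask (default
#'   0.99).
#' @param weight_iter Iterations for the per-source fidelity weights.
#' @param n_surrogates Surrogate networks in the cytoarchitectonic test.
#' @param alpha Family-wise significance level for carrying networks forward.
#' @param min_subgroup Minimum subgroup size analysed; smaller subgroups are
#'   skipped with a notice.
#' @param verbose Emit per-stage messages.
#' @return Object of class `study_report`: list with `study`, `masks` (per
#'   band), `connectivity` (edge table incl. `band`), `nbs` (bound
#'   `nbs_result` rows + `band`), `outcome_correlations`, `subgroup_nbs`,
#'   `cyto`, `manifest`.
#' @export
run_study <- function(x, t_threshold = 2.5, n_perm = 5000,
                      fidelity_iter = 500, fidelity_percentile = 0.99,
                      weight_iter = 100, n_surrogates = 1000,
                      alpha = 0.05, min_subgroup = 5, verbose = TRUE) {
  say <- function(...) if (verbose) inform(sprintf(...))
  t0 <- Sys.time()

  study <- if (inherits(x, "synthetic_study")) {
    x
  } else if (inherits(x, "study_config")) {
    say("generating synthetic cohort (%d subjects)", x$n_group_a + x$n_group_b)
    generate_cohort(x)
  } else if (is.character(x) && dir.exists(x)) {
    say("reading study from %s", x)
    read_study(x)
  } else {
    abort("`x` must be a config, a study, or a study directory",
      class = "neonet_invalid_config"
    )
  }
  cfg <- study$config
  stage_err <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", stage, conditionMessage(e)),
        class = "neonet_stage_error", parent = e
      )
    })
  }

  say("building inverse operator and fidelity weights")
  inv <- stage_err("source_model", make_inverse(study$lead_field))
  parc <- study$parcellation
  parc$fidelity_weights <- stage_err("source_model", compute_fidelity_weights(
    study$lead_field, inv, parc,
    n_iter = weight_iter,
    seed = child_seed(cfg$seed, 21), sampling_rate = cfg$sampling_rate
  ))

  say("computing per-band edge fidelity masks (%d iterations/edge)", fidelity_iter)
  masks <- stage_err("connectivity", {
    out <- list()
    for (b in seq_len(nrow(cfg$bands))) {
      out[[cfg$bands$name[b]]] <- fidelity_mask(
        study$lead_field, inv, parc,
        n_iter = fidelity_iter, percentile = fidelity_percentile,
        seed = child_seed(cfg$seed, 30 + b),
        sampling_rate = cfg$sampling_rate,
        band = c(cfg$bands$low[b], cfg$bands$high[b])
      )
    }
    out
  })

  say("preprocessing and connectivity for %d recordings", 2L * nrow(study$subjects))
  conn <- stage_err("connectivity", pipeline_connectivity(study, inv, parc, masks))

  say("network-based statistics (%d permutations)", n_perm)
  nbs_all <- stage_err("network_stats", {
    rows <- list()
    for (b in cfg$bands$name) {
      conn_b <- conn[conn$band == b, ]
      for (ctr in c("sleep_main", "group_main", "interaction")) {
        res <- nbs_extent_test(conn_b, ctr,
          t_threshold = t_threshold,
          n_perm = n_perm, seed = child_seed(cfg$seed, 50)
        )
        if (nrow(res)) {
          res$band <- b
          rows[[length(rows) + 1L]] <- as_tibble(res)
        }
      }
    }
    if (length(rows)) dplyr::bind_rows(rows) else NULL
  })

  sig_inter <- if (!is.null(nbs_all)) {
    nbs_all[nbs_all$contrast == "interaction" & nbs_all$p_fwe < alpha, ]
  } else {
    NULL
  }

  say("network-to-outcome correlation")
  outcome_corr <- NULL
  if (!is.null(sig_inter) && nrow(sig_inter)) {
    deltas <- dplyr::bind_rows(lapply(seq_len(nrow(sig_inter)), function(k) {
      cohort_deltas(
        conn[conn$band == sig_inter$band[k] & conn$group == "A", ],
        sig_inter$edges[[k]],
        network_name = sprintf("%s_interaction_%d", sig_inter$band[k], k)
      )
    }))
    outcome_corr <- stage_err(
      "outcomes",
      correlate_outcomes(deltas, study$outcomes)
    )
  }

  subgroup_nbs <- stage_err(
    "network_stats",
    subgroup_interactions(study, conn, t_threshold, n_perm, min_subgroup, say)
  )

  say("cytoarchitectonic profiling")
  cyto <- NULL
  cyto_source_nbs <- if (!is.null(subgroup_nbs) && nrow(subgroup_nbs)) {
    subgroup_nbs[subgroup_nbs$p_fwe < alpha, ]
  } else {
    sig_inter
  }
  if (!is.null(cyto_source_nbs) && nrow(cyto_source_nbs)) {
    projected <- stage_err("cytoarchitecture", project_atlas(study$atlas, parc))
    cyto <- stage_err("cytoarchitecture", {
      rows <- lapply(seq_len(nrow(cyto_source_nbs)), function(k) {
        surrogate_network_test(
          cyto_source_nbs$edges[[k]], parc, projected,
          n_surrogates = n_surrogates,
          seed = child_seed(cfg$seed, 70 + k),
          network_name = sprintf(
            "%s_%s_%d", cyto_source_nbs$band[k],
            cyto_source_nbs$contrast[k], k
          )
        )
      })
      cyto_adjust_family(dplyr::bind_rows(rows))
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("neonet")),
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    parameters = list(
      t_threshold = t_threshold, n_perm = n_perm,
      fidelity_iter = fidelity_iter,
      fidelity_percentile = fidelity_percentile,
      weight_iter = weight_iter, n_surrogates = n_surrogates,
      alpha = alpha, min_subgroup = min_subgroup
    ),
    stages = c(
      "generate", "source_model", "fidelity_mask", "preprocess",
      "connectivity", "network_stats", "outcomes", "cytoarchitecture"
    ),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(
    list(
      study = study, masks = masks, connectivity = conn, nbs = nbs_all,
      outcome_correlations = outcome_corr, subgroup_nbs = subgroup_nbs,
      cyto = cyto, manifest = manifest
    ),
    class = "study_report"
  )
}

# Sensor recordings -> masked long edge table across subjects/states/bands.
pipeline_connectivity <- function(study, inv, parc, masks) {
  cfg <- study$config
  rows <- list()
  for (s in seq_len(nrow(study$subjects))) {
    subj <- study$subjects$subject[s]
    grp <- study$subjects$group[s]
    for (st in c("AS", "QS")) {
      rec <- study$recordings[[subj]][[st]]
      if (rec$sampling_rate > cfg$sampling_rate) {
        rec <- resample_to(prefilter(rec), cfg$sampling_rate)
      }
      rec <- average_reference(rec)
      epochs <- select_epochs(rec, st, cfg$epoch_windows, cfg$window_length)
      for (b in seq_len(nrow(cfg$bands))) {
        bname <- cfg$bands$name[b]
        filtered <- bandpass_zero_phase(rec, cfg$bands[b, ])
        windows <- lapply(
          epoch_signals(filtered, epochs),
          function(w) collapse_parcels(apply_inverse(inv, w), parc)
        )
        cm <- connectivity_matrix(windows, cfg$sampling_rate,
          state = st, subject = subj, band_name = bname
        )
        cm <- apply_mask(cm, masks[[bname]])
        ed <- connectivity_edges(cm)
        ed$group <- grp
        ed$band <- bname
        rows[[length(rows) + 1L]] <- ed
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Per-exposure-subgroup interaction contrasts against the full control group.
subgroup_interactions <- function(study, conn, t_threshold, n_perm,
                                  min_subgroup, say) {
  sg <- study$subjects
  if (all(is.na(sg$subgroup))) {
    return(NULL)
  }
  rows <- list()
  for (lab in unique(stats::na.omit(sg$subgroup))) {
    members <- sg$subject[!is.na(sg$subgroup) & sg$subgroup == lab]
    if (length(members) < min_subgroup) {
      say("subgroup %s has %d subjects (< %d): skipped", lab, length(members), min_subgroup)
      next
    }
    keep <- conn$subject %in% c(members, sg$subject[sg$group == "B"])
    for (b in unique(conn$band)) {
      res <- nbs_extent_test(conn[keep & conn$band == b, ], "interaction",
        t_threshold = t_threshold, n_perm = n_perm,
        seed = child_seed(study$config$seed, 60)
      )
      if (nrow(res)) {
        res$band <- b
        res$subgroup <- lab
        rows[[length(rows) + 1L]] <- as_tibble(res)
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else NULL
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf(
    "  subjects: %d, parcels: %d, bands: %d\n",
    nrow(x$study$subjects), x$study$parcellation$n_parcels,
    nrow(x$study$config$bands)
  ))
  n_sig <- if (!is.null(x$nbs)) sum(x$nbs$p_fwe < 0.05) else 0L
  cat(sprintf("  NBS components with p_fwe < 0.05: %d\n", n_sig))
  if (!is.null(x$outcome_correlations)) {
    cat(sprintf(
      "  outcome correlations: %d tests, %d with p_fdr < 0.05\n",
      nrow(x$outcome_correlations),
      sum(x$outcome_correlations$p_fdr < 0.05, na.rm = TRUE)
    ))
  }
  if (!is.null(x$cyto)) {
    cat(sprintf(
      "  cyto tests: %d, %d with p_fdr < 0.05\n",
      nrow(x$cyto), sum(x$cyto$p_fdr < 0.05)
    ))
  }
  invisible(x)
}

#' Empirical family-wise error rate of the network test on null cohorts
#'
#' Simulates `n_cohorts` cohorts with no group effect (independent Gaussian
#' edge values), runs the unpaired network-based test on each, and returns
#' the fraction of cohorts in which any component reaches `p_fwe < alpha` —
#' the quantity that must stay at or below the nominal level for the
#' permutation correction to be valid.
#'
#' @param n_cohorts Number of simulated null cohorts.
#' @param n_parcels,n_a,n_b Cohort dimensions.
#' @param t_threshold,n_perm,alpha Test parameters.
#' @param seed Integer seed.
#' @return List with `fwe` (empirical rate), `n_reject`, `n_cohorts`, and
#'   `rejected` (logical per cohort).
#' @export
nbs_null_fwe <- function(n_cohorts = 200, n_parcels = 20, n_a = 15, n_b = 15,
                         t_threshold = 2.5, n_perm = 500, alpha = 0.05,
                         seed = 1) {
  rejected <- logical(n_cohorts)
  for (k in seq_len(n_cohorts)) {
    coh <- generate_edge_cohort(
      n_parcels = n_parcels, n_a = n_a, n_b = n_b,
      planted = NULL, effect = 0, seed = child_seed(seed, k)
    )
    res <- nbs_extent_test(coh$edges, "group_main",
      t_threshold = t_threshold, n_perm = n_perm,
      seed = child_seed(seed, 100000 + k)
    )
    rejected[k] <- nrow(res) > 0 && any(res$p_fwe < alpha)
  }
  list(
    fwe = mean(rejected), n_reject = sum(rejected),
    n_cohorts = n_cohorts, rejected = rejected
  )
}
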