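#' Simulate a cohort of connectivity matrices directly at the edge level
#'
#' Fast generator for calibration and power studies of the network statistics
#' and outcome stages: per subject, state and edge it draws an independent
#' Gaussian connectivity value around a common baseline, then adds a
#' sleep-by-group interaction on a planted edge set — group A gains
#' `+effect/2` and group B `-effect/2` on the AS − QS difference, i.e. the
#' two groups change in opposite directions between sleep states. A
#' per-subject random network effect (`subject_sd`) makes the true
#' within-subject difference heterogeneous, and an outcome score is linked to
#' that true difference through a Gaussian copula targeting Spearman
#' correlation `outcome_effect` within group A.
#'
#' With `planted = NULL` and `effect = 0` the edge values are i.i.d. — the
#' null cohort used for family-wise error calibration.
#'
#' @param n_parcels Number of parcels (nodes).
#' @param n_a,n_b Group sizes (group `"A"` mirrors the exposed group,
#'   `"B"` the controls).
#' @param planted Tibble with columns `i`, `j`: the interaction edge set
#'   (default `NULL`, no planted structure). See [planted_star()].
#' @param effect Interaction effect on the planted AS − QS difference, in
#'   standard deviations of that difference (Cohen's d of the unpaired
#'   contrast on the difference).
#' @param baseline Baseline edge value (debiased wPLI scale).
#' @param edge_sd Independent edge noise standard deviation.
#' @param subject_sd Between-subject standard deviation of the network-level
#'   true difference.
#' @param outcome_effect Target Spearman correlation between the true
#'   difference and the `fine_motor` outcome within group A.
#' @param seed Integer seed.
#' @return List with `edges` (edge table: `subject`, `group`, `state`, `i`,
#'   `j`, `value`), `outcomes` (per-subject tibble with `fine_motor` score),
#'   `truth` (planted edges and per-subject true differences `delta_true`).
#' @examples
#' coh <- generate_edge_cohort(n_parcels = 10, n_a = 8, n_b = 8, seed = 1)
#' head(coh$edges)
#' @export
generate_edge_cohort <- function(n_parcels = 20, n_a = 15, n_b = 15,
                                 planted = NULL, effect = 0,
                                 baseline = 0.05, edge_sd = 0.1,
                                 subject_sd = 0.15, outcome_effect = 0,
                                 seed = 1) {
  assert_count(n_parcels, "n_parcels")
  n <- n_a + n_b
  ut <- which(upper.tri(matrix(0, n_parcels, n_parcels)), arr.ind = TRUE)
  edges <- tibble(i = ut[, 1], j = ut[, 2])
  ne <- nrow(edges)
  planted_idx <- integer(0)
  if (!is.null(planted) && nrow(planted)) {
    key <- paste(pmin(planted$i, planted$j), pmax(planted$i, planted$j))
    planted_idx <- match(key, paste(edges$i, edges$j))
    if (anyNA(planted_idx)) {
      abort("planted edges must be valid parcel pairs", class = "neonet_invalid_config")
    }
  }
  group <- rep(c("A", "B"), c(n_a, n_b))
  subjects <- sprintf("S%03d", seq_len(n))

  with_seed(seed, {
    as_m <- matrix(rnorm(ne * n, baseline, edge_sd), ne, n)
    qs_m <- matrix(rnorm(ne * n, baseline, edge_sd), ne, n)
    # per-edge AS-QS difference sd, for calibrating `effect` as Cohen's d
    diff_sd <- sqrt(2 * edge_sd^2 + (length(planted_idx) > 0) * subject_sd^2)
    delta_true <- numeric(n)
    if (length(planted_idx)) {
      shift <- ifelse(group == "A", 0.5, -0.5) * effect * diff_sd
      subj_eff <- rnorm(n, 0, subject_sd)
      delta_true <- shift + subj_eff
      # split the network-level difference evenly between the two states
      as_m[planted_idx, ] <- as_m[planted_idx, ] +
        matrix(delta_true / 2, length(planted_idx), n, byrow = TRUE)
      qs_m[planted_idx, ] <- qs_m[planted_idx, ] -
        matrix(delta_true / 2, length(planted_idx), n, byrow = TRUE)
    }
    outcomes <- tibble(
      subject = subjects, group = group,
      fine_motor = copula_linked_score(delta_true, outcome_effect, group == "A")
    )
    edge_tbl <- dplyr::bind_rows(
      edge_long(as_m, "AS", edges, subjects, group),
      edge_long(qs_m, "QS", edges, subjects, group)
    )
    list(
      edges = edge_tbl,
      outcomes = outcomes,
      truth = list(
        planted = edges[planted_idx, , drop = FALSE],
        delta_true = tibble(subject = subjects, group = group, delta_true = delta_true)
      )
    )
  })
}

edge_long <- function(m, state, edges, subjects, group) {
  tibble(
    subject = rep(subjects, each = nrow(edges)),
    group = rep(group, each = nrow(edges)),
    state = state,
    i = rep(edges$i, length(subjects)),
    j = rep(edges$j, length(subjects)),
    value = as.vector(m)
  )
}

# Gaussian-copula score: rank-correlated with `x` at Spearman rho within the
# `active` subset (scaled to a BSID-like mean 100, sd 15 scale), independent
# noise elsewhere. rho_pearson = 2 sin(pi * rho_spearman / 6).
copula_linked_score <- function(x, rho_s, active = rep(TRUE, length(x))) {
  n <- length(x)
  z <- rnorm(n)
  if (rho_s != 0 && any(active)) {
    rho_p <- 2 * sin(pi * rho_s / 6)
    xa <- x[active]
    zx <- qnorm((rank(xa) - 0.5) / length(xa))
    z[active] <- rho_p * zx + sqrt(1 - rho_p^2) * rnorm(length(xa))
  }
  100 + 15 * z
}

#' Star-shaped planted network
#'
#' A connected `n_edges`-edge component: a hub parcel joined to `n_edges`
#' leaves. Convenient planted truth because every suprathreshold planted edge
#' touches the hub and therefore stays in one component.
#'
#' @param hub Hub parcel id.
#' @param leaves Leaf parcel ids (length = number of edges).
#' @return Tibble with columns `i`, `j`.
#' @export
planted_star <- function(hub = 1, leaves = 2:11) {
  tibble(i = pmin(hub, leaves), j = pmax(hub, leaves))
}
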