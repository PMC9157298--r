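# Composite clinical scores, network-level connectivity change, and
# network-to-outcome correlation with Benjamini-Hochberg FDR control.

#' Composite scores from item-level data by PCA
#'
#' Standardizes the items, runs principal component analysis, and returns the
#' projections of every subject on the first two principal axes (C1, C2).
#' The sign of each axis is fixed so its largest-magnitude loading is
#' positive. Constant items are dropped with a warning.
#'
#' @param raw_scores Tibble with a `subject` column and at least 3 numeric
#'   item columns, at least 3 subjects.
#' @return Tibble `subject`, `C1`, `C2`; loadings in attribute `"rotation"`,
#'   explained variance share in `"variance_explained"`.
#' @examples
#' items <- tibble::tibble(subject = letters[1:5], a = rnorm(5), b = rnorm(5), c = rnorm(5))
#' pca_composites(items)
#' @export
pca_composites <- function(raw_scores) {
  stopifnot("subject" %in% names(raw_scores))
  items <- dplyr::select(raw_scores, -"subject")
  items <- items[vapply(items, is.numeric, logical(1))]
  keep <- vapply(items, function(x) sd(x) > 0, logical(1))
  if (any(!keep)) {
    warn(sprintf("dropping constant item(s): %s", toString(names(items)[!keep])))
    items <- items[keep]
  }
  if (ncol(items) < 3L || nrow(items) < 3L) {
    abort("need at least 3 non-constant items and 3 subjects",
      class = "neonet_invalid_config"
    )
  }
  pc <- prcomp(as.matrix(items), center = TRUE, scale. = TRUE)
  rot <- pc$rotation[, 1:2, drop = FALSE]
  flip <- vapply(1:2, function(k) sign(rot[which.max(abs(rot[, k])), k]), numeric(1))
  scores <- sweep(pc$x[, 1:2, drop = FALSE], 2L, flip, "*")
  out <- tibble(
    subject = raw_scores$subject,
    C1 = scores[, 1], C2 = scores[, 2]
  )
  attr(out, "rotation") <- sweep(rot, 2L, flip, "*")
  attr(out, "variance_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  out
}

#' Sleep-related connectivity change of a network
#'
#' The per-subject network dynamics summary: mean over the network's edges of
#' the AS − QS connectivity difference.
#'
#' @param cm_as,cm_qs Masked connectivity matrices of one subject (AS and
#'   QS).
#' @param network Edge set: tibble with columns `i`, `j`; must be a subset of
#'   valid (unmasked) edges.
#' @return Single numeric delta.
#' @export
delta_connectivity <- function(cm_as, cm_qs, network) {
  if (is.null(network) || !nrow(network)) {
    abort("empty network: delta undefined", class = "neonet_invalid_config")
  }
  idx <- cbind(network$i, network$j)
  vals_as <- cm_as[idx]
  vals_qs <- cm_qs[idx]
  if (anyNA(vals_as) || anyNA(vals_qs)) {
    abort("network contains masked (invalid) edges", class = "neonet_invalid_config")
  }
  mean(vals_as - vals_qs)
}

#' Network-level deltas for a whole cohort from an edge table
#'
#' @param conn Edge table (`subject`, `group`, `state`, `i`, `j`, `value`).
#' @param network Edge set tibble (`i`, `j`).
#' @param network_name Label attached to the result.
#' @return Tibble `subject`, `group`, `network`, `delta`.
#' @export
cohort_deltas <- function(conn, network, network_name = "network") {
  net_keys <- paste(pmin(network$i, network$j), pmax(network$i, network$j))
  sub <- conn |>
    dplyr::mutate(key = paste(pmin(.data$i, .data$j), pmax(.data$i, .data$j))) |>
    dplyr::filter(.data$key %in% .env$net_keys)
  sub |>
    tidyr::pivot_wider(
      id_cols = c("subject", "group", "key"),
      names_from = "state", values_from = "value"
    ) |>
    dplyr::group_by(.data$subject, .data$group) |>
    dplyr::summarise(delta = mean(.data$AS - .data$QS), .groups = "drop") |>
    dplyr::mutate(network = network_name)
}

#' Correlate network dynamics with clinical outcomes
#'
#' Two-tailed Spearman correlations between per-subject network deltas and
#' each outcome score, with Benjamini-Hochberg FDR adjustment within declared
#' score families (by default, per network: the two neurological composites
#' form one family and the four 2-year neurocognitive scores another).
#' Subjects with a missing score are dropped pairwise. Exact p-values are
#' used for n <= 10 (no ties), the t approximation otherwise; ties get
#' average ranks.
#'
#' @param deltas Tibble `subject`, `network`, `delta` (e.g. from
#'   [cohort_deltas()], possibly several networks bound together).
#' @param outcomes Outcome table: `subject` plus numeric score columns.
#' @param families Named list mapping family label -> character vector of
#'   score columns. Default: `neurological = c("C1", "C2")`,
#'   `neurocognitive = c("cognitive", "receptive_language",
#'   "expressive_language", "fine_motor")` (columns absent from `outcomes`
#'   are ignored).
#' @param min_pairs Minimum complete pairs per test (default 5).
#' @return Tibble `network`, `family`, `score`, `n`, `rho`, `p`, `p_fdr`
#'   (class `outcome_correlations`). All-tied score vectors yield `NA` rho,
#'   reported as such and excluded from the adjustment.
#' @export
correlate_outcomes <- function(deltas, outcomes,
                               families = list(
                                 neurological = c("C1", "C2"),
                                 neurocognitive = c(
                                   "cognitive", "receptive_language",
                                   "expressive_language", "fine_motor"
                                 )
                               ),
                               min_pairs = 5) {
  families <- lapply(families, intersect, names(outcomes))
  families <- families[lengths(families) > 0L]
  rows <- list()
  for (net in unique(deltas$network)) {
    d <- deltas[deltas$network == net, ]
    merged <- dplyr::left_join(d, outcomes, by = "subject")
    for (fam in names(families)) {
      for (sc in families[[fam]]) {
        ok <- stats::complete.cases(merged$delta, merged[[sc]])
        x <- merged$delta[ok]
        y <- merged[[sc]][ok]
        if (sum(ok) < min_pairs) {
          abort(sprintf(
            "fewer than %d complete pairs for %s / %s", min_pairs, net, sc
          ), class = "neonet_invalid_config")
        }
        if (length(unique(y)) < 2L || length(unique(x)) < 2L) {
          rows[[length(rows) + 1L]] <- tibble(
            network = net, family = fam, score = sc, n = sum(ok),
            rho = NA_real_, p = NA_real_
          )
          next
        }
        exact <- length(x) <= 10 && !anyDuplicated(x) && !anyDuplicated(y)
        ct <- suppressWarnings(
          cor.test(x, y, method = "spearman", exact = exact)
        )
        rows[[length(rows) + 1L]] <- tibble(
          network = net, family = fam, score = sc, n = sum(ok),
          rho = unname(ct$estimate), p = ct$p.value
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$network, .data$family) |>
    dplyr::mutate(p_fdr = p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup()
  structure(out, class = c("outcome_correlations", class(out)))
}
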