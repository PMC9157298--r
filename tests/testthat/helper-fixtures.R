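# Shared fixtures: all built in code, deterministic under fixed seeds.

# Fully observable reference model: identity lead field, parcel i = source i.
identity_model <- function(p = 6) {
  cfg <- study_config(
    n_sensors = p, n_sources = p, n_parcels = p,
    mixing = "identity", seed = 1
  )
  hm <- generate_head_model(cfg)
  inv <- make_inverse(hm$lead_field, lambda = 1e-9)
  list(cfg = cfg, lf = hm$lead_field, parc = hm$parcellation, inv = inv)
}

# Small geometric toy model.
toy_model <- function(n_sensors = 8, n_sources = 16, n_parcels = 8, seed = 2) {
  cfg <- study_config(
    n_sensors = n_sensors, n_sources = n_sources,
    n_parcels = n_parcels, seed = seed
  )
  hm <- generate_head_model(cfg)
  inv <- make_inverse(hm$lead_field)
  list(cfg = cfg, lf = hm$lead_field, parc = hm$parcellation, inv = inv)
}

# Single-state edge table for unpaired contrasts: values[e, s] per edge/subject.
edge_table_from_matrix <- function(values, group, edges = NULL) {
  ne <- nrow(values)
  n <- ncol(values)
  if (is.null(edges)) edges <- tibble::tibble(i = rep(1, ne), j = seq_len(ne) + 1)
  dplyr::bind_rows(lapply(seq_len(n), function(s) {
    tibble::tibble(
      subject = sprintf("S%02d", s), group = group[s], state = "AS",
      i = edges$i, j = edges$j, value = values[, s]
    )
  }))
}

# Paired two-state edge table from AS and QS matrices.
edge_table_paired <- function(as_m, qs_m, group, edges = NULL) {
  dplyr::bind_rows(
    dplyr::mutate(edge_table_from_matrix(as_m, group, edges), state = "AS"),
    dplyr::mutate(edge_table_from_matrix(qs_m, group, edges), state = "QS")
  )
}

# Hand step-up Benjamini-Hochberg (independent oracle for FDR adjustment).
bh_step_up <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force connected-component extents via igraph (oracle for NBS).
component_extents_igraph <- function(i, j) {
  if (!length(i)) {
    return(integer(0))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(i), to = as.character(j)),
    directed = FALSE
  )
  comp <- igraph::components(g)
  vapply(seq_len(comp$no), function(cid) {
    nodes <- names(comp$membership)[comp$membership == cid]
    sum(as.character(i) %in% nodes & as.character(j) %in% nodes)
  }, numeric(1))
}
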