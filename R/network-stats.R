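# Edge-wise contrasts and network-based permutation statistics (NBS).
#
# Connectivity data flow through a long "edge table": one row per
# subject x state x edge with columns `subject`, `group`, `state`, `i`, `j`,
# `value` (and optionally `band`, handled by the caller via grouping).

# Reshape an edge table into per-state edges x subjects matrices plus design
# metadata. Edges carrying NA (masked) for any subject are dropped entirely.
prepare_edge_data <- function(conn) {
  needed <- c("subject", "group", "state", "i", "j", "value")
  if (!all(needed %in% names(conn))) {
    abort(paste("edge table needs columns", toString(needed)),
      class = "neonet_invalid_design"
    )
  }
  conn <- dplyr::mutate(conn,
    i2 = pmin(.data$i, .data$j), j2 = pmax(.data$i, .data$j)
  )
  edges <- dplyr::distinct(conn, i = .data$i2, j = .data$j2)
  edges <- dplyr::arrange(edges, .data$i, .data$j)
  edge_key <- paste(edges$i, edges$j)
  subj <- dplyr::distinct(conn, .data$subject, .data$group)
  if (anyDuplicated(subj$subject)) {
    abort("a subject appears in more than one group", class = "neonet_invalid_design")
  }
  states <- sort(unique(conn$state))
  mats <- lapply(states, function(st) {
    d <- conn[conn$state == st, ]
    m <- matrix(NA_real_, length(edge_key), nrow(subj))
    m[cbind(
      match(paste(d$i2, d$j2), edge_key),
      match(d$subject, subj$subject)
    )] <- d$value
    m
  })
  names(mats) <- states
  # drop masked/incomplete edges
  keep <- Reduce(`&`, lapply(mats, function(m) rowSums(is.na(m)) == 0))
  mats <- lapply(mats, function(m) m[keep, , drop = FALSE])
  list(
    edges = edges[keep, , drop = FALSE],
    mats = mats,
    states = states,
    subjects = subj$subject,
    group = as.character(subj$group)
  )
}

# Per-subject response matrix for a contrast, plus the permutation scheme.
contrast_response <- function(prep, contrast) {
  st <- prep$states
  two_states <- length(st) == 2L
  if (contrast %in% c("sleep_main", "interaction") && !two_states) {
    abort("sleep and interaction contrasts need both sleep states",
      class = "neonet_invalid_design"
    )
  }
  X <- switch(contrast,
    sleep_main = ,
    interaction = prep$mats[["AS"]] - prep$mats[["QS"]],
    group_main = if (two_states) {
      (prep$mats[[1L]] + prep$mats[[2L]]) / 2
    } else {
      prep$mats[[1L]]
    },
    abort("unknown contrast", class = "neonet_invalid_design")
  )
  paired <- contrast == "sleep_main"
  groups <- prep$group
  if (!paired) {
    lev <- unique(groups)
    if (length(lev) != 2L || min(table(groups)) < 2L) {
      abort("group contrasts need two groups with >= 2 subjects each",
        class = "neonet_invalid_design"
      )
    }
  }
  df <- if (paired) ncol(X) - 1L else ncol(X) - 2L
  list(X = X, paired = paired, groups = groups, df = df)
}

# Vectorized unpaired pooled-variance t for many group-A indicator columns.
t_unpaired_cols <- function(X, ind) {
  n <- ncol(X)
  n1 <- colSums(ind)
  n2 <- n - n1
  S <- rowSums(X)
  Q <- rowSums(X^2)
  S1 <- X %*% ind
  Q1 <- (X^2) %*% ind
  m1 <- sweep(S1, 2L, n1, "/")
  m2 <- sweep(-S1 + S, 2L, n2, "/")
  ss1 <- Q1 - sweep(m1^2, 2L, n1, "*")
  ss2 <- (Q - Q1) - sweep(m2^2, 2L, n2, "*")
  vp <- sweep(ss1 + ss2, 2L, n - 2, "/")
  se <- sqrt(sweep(vp, 2L, 1 / n1 + 1 / n2, "*"))
  tt <- (m1 - m2) / se
  tt[!is.finite(tt)] <- 0
  tt
}

# Vectorized one-sample t of sign-flipped columns (paired contrast null).
t_paired_cols <- function(X, signs) {
  n <- ncol(X)
  Q <- rowSums(X^2)
  m <- (X %*% signs) / n
  v <- (Q - n * m^2) / (n - 1)
  tt <- m / sqrt(v / n)
  tt[!is.finite(tt)] <- 0
  tt
}

#' Edge-wise t statistics for a cohort contrast
#'
#' Computes, per edge: `sleep_main` — a paired two-tailed t on the
#' within-subject difference AS − QS across all subjects; `group_main` — an
#' unpaired pooled-variance t between groups on the per-subject mean over
#' both sleep states; `interaction` — an unpaired t between groups on the
#' per-subject difference AS − QS (the 2 x 2 mixed-design sleep-by-group
#' interaction). Edges masked as invalid (NA) are absent from the output.
#'
#' @param conn Edge table: tibble with columns `subject`, `group`, `state`,
#'   `i`, `j`, `value`.
#' @param contrast One of `"sleep_main"`, `"group_main"`, `"interaction"`.
#' @return Tibble with columns `i`, `j`, `t`; degrees of freedom in attribute
#'   `"df"` and the contrast name in `"contrast"`. Edges with degenerate
#'   (zero) variance get `t = 0` with a warning.
#' @export
edge_statistics <- function(conn, contrast = c("interaction", "sleep_main", "group_main")) {
  contrast <- match.arg(contrast)
  prep <- prepare_edge_data(conn)
  cr <- contrast_response(prep, contrast)
  tt <- observed_t(cr)
  out <- tibble(i = prep$edges$i, j = prep$edges$j, t = as.numeric(tt))
  attr(out, "df") <- cr$df
  attr(out, "contrast") <- contrast
  out
}

observed_t <- function(cr) {
  if (cr$paired) {
    tt <- t_paired_cols(cr$X, matrix(1, ncol(cr$X), 1))
  } else {
    ind <- matrix(as.numeric(cr$groups == unique(cr$groups)[1L]), ncol = 1)
    tt <- t_unpaired_cols(cr$X, ind)
  }
  if (any(tt == 0 & apply(cr$X, 1L, function(r) sd(r) == 0))) {
    warn("degenerate variance at one or more edges; t set to 0 there")
  }
  tt
}

# Union-find maximum component statistic over a suprathreshold edge set.
# `w` is the per-edge component weight (1 for extent, |t| for intensity).
max_component_stat <- function(ei, ej, w) {
  ne <- length(ei)
  if (ne == 0L) {
    return(0)
  }
  if (ne == 1L) {
    return(w[1L])
  }
  nodes <- unique(c(ei, ej))
  a <- match(ei, nodes)
  b <- match(ej, nodes)
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(ne)) {
    ra <- find(a[k])
    rb <- find(b[k])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(a, find, integer(1))
  max(rowsum(w, roots))
}

# Observed connected components of a suprathreshold edge set via igraph.
observed_components <- function(edges, tvals) {
  if (!nrow(edges)) {
    return(list())
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$i), to = as.character(edges$j)),
    directed = FALSE
  )
  comp <- igraph::components(g)
  membership <- comp$membership
  lapply(seq_len(comp$no), function(cid) {
    nodes <- as.integer(names(membership)[membership == cid])
    sel <- edges$i %in% nodes & edges$j %in% nodes
    tibble(i = edges$i[sel], j = edges$j[sel], t = tvals[sel])
  })
}

#' Network-based statistics: permutation test on component extent
#'
#' Thresholds the edge-wise t map at `t_threshold` (positive and negative
#' directions are tested as separate one-sided families, mirroring the
#' separate reporting of AS > QS and AS < QS networks), forms connected
#' components in the parcel graph, and compares each component's statistic
#' (extent = edge count by default, or intensity = sum of |t|) against the
#' permutation null distribution of the maximum component statistic. Group
#' labels are permuted for `group_main`/`interaction`; sleep-state labels are
#' flipped within subject for `sleep_main`. When the total number of distinct
#' permutations is at most `n_perm` the null is enumerated exhaustively;
#' otherwise `n_perm` random permutations are drawn and the observed
#' labelling is included in the null, so `p_fwe >= 1 / (n_perm + 1)`.
#'
#' @inheritParams edge_statistics
#' @param t_threshold Edge-forming threshold on t (default 2.5, > 0).
#' @param n_perm Number of permutations (default 5000; a warning is issued
#'   below 100).
#' @param seed Integer seed for the permutation stream (recorded in the
#'   result).
#' @param component_stat `"extent"` (default) or `"intensity"`.
#' @param direction_family `"joint"` (default) compares every component
#'   against the permutation null of the maximum component statistic over
#'   *both* directions, so the family-wise error rate over all reported
#'   components is controlled at the nominal level; `"separate"` calibrates
#'   each direction against its own one-sided null (each direction then
#'   controls its own family, but the union of the two families can exceed
#'   the nominal rate).
#' @return A tibble of class `nbs_result`, one row per observed component:
#'   `contrast`, `direction`, `component`, `extent`, `stat`, `p_fwe`,
#'   `cohens_d`, and `edges` (list column of per-component edge tibbles).
#'   Attributes: `t_threshold`, `n_perm`, `seed`, `df`, `exhaustive`,
#'   `null_max` (per-direction null maxima).
#' @examples
#' cohort <- generate_edge_cohort(n_parcels = 8, n_a = 6, n_b = 6, seed = 2)
#' nbs_extent_test(cohort$edges, "interaction", n_perm = 199, seed = 1)
#' @export
nbs_extent_test <- function(conn, contrast = c("interaction", "sleep_main", "group_main"),
                            t_threshold = 2.5, n_perm = 5000, seed = 1,
                            component_stat = c("extent", "intensity"),
                            direction_family = c("joint", "separate")) {
  contrast <- match.arg(contrast)
  component_stat <- match.arg(component_stat)
  direction_family <- match.arg(direction_family)
  if (!is.numeric(t_threshold) || t_threshold <= 0) {
    abort("`t_threshold` must be > 0", class = "neonet_invalid_config")
  }
  if (n_perm < 100) warn("fewer than 100 permutations: p-values are coarse")
  prep <- prepare_edge_data(conn)
  cr <- contrast_response(prep, contrast)
  tt <- as.numeric(suppressWarnings(observed_t(cr)))
  ei <- prep$edges$i
  ej <- prep$edges$j

  perms <- build_permutations(cr, n_perm, seed)
  null_t <- if (cr$paired) {
    t_paired_cols(cr$X, perms$cols)
  } else {
    t_unpaired_cols(cr$X, perms$cols)
  }
  null_max <- list(positive = numeric(perms$k), negative = numeric(perms$k))
  for (k in seq_len(perms$k)) {
    tk <- null_t[, k]
    for (dir in c("positive", "negative")) {
      sel <- if (dir == "positive") tk > t_threshold else tk < -t_threshold
      if (!any(sel)) next
      w <- if (component_stat == "extent") rep(1, sum(sel)) else abs(tk[sel])
      null_max[[dir]][k] <- max_component_stat(ei[sel], ej[sel], w)
    }
  }

  joint_max <- pmax(null_max$positive, null_max$negative)
  rows <- list()
  for (dir in c("positive", "negative")) {
    sel <- if (dir == "positive") tt > t_threshold else tt < -t_threshold
    comps <- observed_components(prep$edges[sel, , drop = FALSE], tt[sel])
    null_ref <- if (direction_family == "joint") joint_max else null_max[[dir]]
    for (cc in comps) {
      stat <- if (component_stat == "extent") nrow(cc) else sum(abs(cc$t))
      p <- if (perms$exhaustive) {
        mean(null_ref >= stat)
      } else {
        (1 + sum(null_ref >= stat)) / (perms$k + 1)
      }
      rows[[length(rows) + 1L]] <- tibble(
        contrast = contrast, direction = dir,
        extent = nrow(cc), stat = stat, p_fwe = p,
        cohens_d = mean(abs(cc$t)) / sqrt(cr$df),
        edges = list(cc)
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(
      contrast = character(), direction = character(), extent = integer(),
      stat = numeric(), p_fwe = numeric(), cohens_d = numeric(), edges = list()
    )
  }
  out <- dplyr::arrange(out, .data$p_fwe, dplyr::desc(.data$stat))
  if (nrow(out)) out$component <- seq_len(nrow(out))
  structure(out,
    t_threshold = t_threshold, n_perm = perms$k, seed = seed, df = cr$df,
    exhaustive = perms$exhaustive, null_max = null_max,
    class = c("nbs_result", class(out))
  )
}

# Permutation columns: group-A indicators (unpaired) or sign vectors (paired).
# Exhaustive enumeration when the total permutation count fits in n_perm.
build_permutations <- function(cr, n_perm, seed) {
  n <- ncol(cr$X)
  if (cr$paired) {
    total <- 2^n
    if (total <= n_perm) {
      cols <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      return(list(cols = t(unname(as.matrix(cols))), k = total, exhaustive = TRUE))
    }
    cols <- with_seed(seed, {
      matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    })
    list(cols = cols, k = n_perm, exhaustive = FALSE)
  } else {
    lev1 <- unique(cr$groups)[1L]
    n1 <- sum(cr$groups == lev1)
    total <- choose(n, n1)
    if (total <= n_perm) {
      sets <- combn(n, n1)
      cols <- matrix(0, n, ncol(sets))
      cols[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = n1))] <- 1
      return(list(cols = cols, k = ncol(sets), exhaustive = TRUE))
    }
    cols <- with_seed(seed, {
      m <- matrix(0, n, n_perm)
      for (k in seq_len(n_perm)) m[sample.int(n, n1), k] <- 1
      m
    })
    list(cols = cols, k = n_perm, exhaustive = FALSE)
  }
}

#' Cohen's d of a network component
#'
#' Effect size of a suprathreshold component: the average absolute edge t
#' statistic divided by the square root of the degrees of freedom.
#'
#' @param t_map Edge t map from [edge_statistics()] (tibble with `i`, `j`,
#'   `t`), or any tibble with a `t` column.
#' @param component Edge subset: tibble with columns `i`, `j` (e.g. one
#'   element of an `nbs_result` `edges` column). If `NULL`, all edges of
#'   `t_map` are used.
#' @param df Degrees of freedom; defaults to `attr(t_map, "df")`.
#' @return Single numeric effect size.
#' @examples
#' cohens_d(tibble::tibble(i = 1, j = 2, t = 2.5), df = 100) # 0.25
#' @export
cohens_d <- function(t_map, component = NULL, df = NULL) {
  df <- df %||% attr(t_map, "df")
  if (is.null(df)) abort("`df` is required", class = "neonet_invalid_config")
  tt <- if (is.null(component)) {
    t_map$t
  } else {
    sel <- paste(t_map$i, t_map$j) %in% paste(
      pmin(component$i, component$j),
      pmax(component$i, component$j)
    )
    t_map$t[sel]
  }
  if (!length(tt)) abort("empty component", class = "neonet_invalid_config")
  mean(abs(tt)) / sqrt(df)
}
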