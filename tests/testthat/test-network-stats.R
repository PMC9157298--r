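test_that("unpaired edge t matches the hand-computed pooled-variance value", {
  vals <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1)
  conn <- edge_table_from_matrix(vals, rep(c("A", "B"), each = 3))
  tm <- edge_statistics(conn, "group_main")
  expect_equal(tm$t, -3.674, tolerance = 1e-3)
  expect_equal(attr(tm, "df"), 4)
})

test_that("edge t statistics agree with t.test across random edges", {
  set.seed(41)
  vals <- matrix(rnorm(5 * 12), 5)
  group <- rep(c("A", "B"), each = 6)
  conn <- edge_table_from_matrix(vals, group)
  tm <- edge_statistics(conn, "group_main")
  for (e in 1:5) {
    ref <- t.test(vals[e, 1:6], vals[e, 7:12], var.equal = TRUE)
    expect_equal(tm$t[e], unname(ref$statistic), tolerance = 1e-10)
  }
  # paired contrast against t.test on the AS-QS differences
  as_m <- matrix(rnorm(5 * 12), 5)
  qs_m <- matrix(rnorm(5 * 12), 5)
  conn2 <- edge_table_paired(as_m, qs_m, group)
  tm2 <- edge_statistics(conn2, "sleep_main")
  for (e in 1:5) {
    ref <- t.test(as_m[e, ] - qs_m[e, ])
    expect_equal(tm2$t[e], unname(ref$statistic), tolerance = 1e-10)
  }
  expect_equal(attr(tm2, "df"), 11)
})

test_that("copied groups give all-zero t and degenerate edges warn", {
  vals <- cbind(matrix(rnorm(3 * 4), 3), matrix(0, 3, 4))
  vals[, 5:8] <- vals[, 1:4] # group B = copy of group A
  conn <- edge_table_from_matrix(vals, rep(c("A", "B"), each = 4))
  tm <- edge_statistics(conn, "group_main")
  expect_equal(tm$t, rep(0, 3))
  flat <- edge_table_from_matrix(matrix(1, 1, 8), rep(c("A", "B"), each = 4))
  expect_warning(edge_statistics(flat, "group_main"), "degenerate")
})

test_that("interaction t is invariant to per-subject state-constant offsets", {
  set.seed(42)
  as_m <- matrix(rnorm(4 * 10), 4)
  qs_m <- matrix(rnorm(4 * 10), 4)
  group <- rep(c("A", "B"), each = 5)
  base <- edge_statistics(edge_table_paired(as_m, qs_m, group), "interaction")
  offs <- rnorm(10)
  shifted <- edge_statistics(
    edge_table_paired(
      sweep(as_m, 2, offs, "+"), sweep(qs_m, 2, offs, "+"), group
    ),
    "interaction"
  )
  expect_equal(base$t, shifted$t, tolerance = 1e-10)
})

test_that("masked (NA) edges are absent from the t map", {
  set.seed(43)
  vals <- matrix(rnorm(3 * 8), 3)
  conn <- edge_table_from_matrix(vals, rep(c("A", "B"), each = 4))
  conn$value[conn$i == 1 & conn$j == 2] <- NA
  tm <- edge_statistics(conn, "group_main")
  expect_equal(nrow(tm), 2)
  expect_false(any(tm$i == 1 & tm$j == 2))
})

test_that("component extents match the igraph brute-force oracle", {
  # the fixed 5-node example: edges {(1,2),(2,3),(4,5)} -> extents {2, 1}
  expect_equal(
    sort(component_extents_igraph(c(1, 2, 4), c(2, 3, 5))),
    c(1, 2)
  )
  expect_equal(
    neonet:::max_component_stat(c(1, 2, 4), c(2, 3, 5), rep(1, 3)),
    2
  )
  # random graphs on <= 6 nodes
  set.seed(44)
  for (rep in 1:25) {
    n_edges <- sample(1:8, 1)
    i <- sample(1:6, n_edges, replace = TRUE)
    j <- sample(1:6, n_edges, replace = TRUE)
    keep <- i != j
    if (!any(keep)) next
    i <- i[keep]
    j <- j[keep]
    expect_equal(
      neonet:::max_component_stat(i, j, rep(1, length(i))),
      max(component_extents_igraph(i, j))
    )
  }
})

test_that("NBS finds a planted component and reports calibrated p-values", {
  coh <- generate_edge_cohort(
    n_parcels = 10, n_a = 12, n_b = 12,
    planted = planted_star(1, 2:6), effect = 2.5, seed = 3
  )
  res <- nbs_extent_test(coh$edges, "interaction", n_perm = 199, seed = 1)
  expect_s3_class(res, "nbs_result")
  expect_gte(nrow(res), 1)
  top <- res[1, ]
  expect_lt(top$p_fwe, 0.05)
  expect_gte(top$p_fwe, 1 / 200) # observed labelling included in the null
  planted_keys <- paste(coh$truth$planted$i, coh$truth$planted$j)
  found_keys <- paste(top$edges[[1]]$i, top$edges[[1]]$j)
  expect_gte(length(intersect(planted_keys, found_keys)), 4)
  g <- glance(res)
  expect_equal(g$n_perm, 199)
  expect_false(g$exhaustive)
})

test_that("p-values are monotone in extent and capped below by 1/(K+1)", {
  res <- attr(
    nbs_extent_test(
      generate_edge_cohort(n_parcels = 8, n_a = 10, n_b = 10, seed = 5)$edges,
      "group_main",
      t_threshold = 1.5, n_perm = 199, seed = 2
    ),
    "null_max"
  )
  # direct check on the null mechanism: larger observed extent, smaller p
  joint <- pmax(res$positive, res$negative)
  p_of <- function(k) (1 + sum(joint >= k)) / (length(joint) + 1)
  expect_true(all(diff(vapply(1:5, p_of, numeric(1))) <= 0))
  expect_gte(p_of(100), 1 / 200)
})

test_that("small designs enumerate the permutation group exhaustively", {
  set.seed(45)
  vals <- matrix(rnorm(4 * 8), 4)
  conn <- edge_table_from_matrix(vals, rep(c("A", "B"), each = 4))
  res <- nbs_extent_test(conn, "group_main",
    t_threshold = 1.2,
    n_perm = 500, seed = 1
  )
  expect_true(attr(res, "exhaustive"))
  expect_equal(attr(res, "n_perm"), choose(8, 4))
})

test_that("relabeling parcels leaves extent, p and d unchanged", {
  coh <- generate_edge_cohort(
    n_parcels = 8, n_a = 10, n_b = 10,
    planted = planted_star(1, 2:5), effect = 2, seed = 7
  )
  res <- nbs_extent_test(coh$edges, "interaction", n_perm = 99, seed = 1)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  relabeled <- dplyr::mutate(coh$edges,
    i2 = perm[.data$i], j2 = perm[.data$j],
    i = pmin(.data$i2, .data$j2), j = pmax(.data$i2, .data$j2)
  )
  res2 <- nbs_extent_test(
    dplyr::select(relabeled, -"i2", -"j2"), "interaction",
    n_perm = 99, seed = 1
  )
  expect_equal(res$extent, res2$extent)
  expect_equal(res$p_fwe, res2$p_fwe)
  expect_equal(res$cohens_d, res2$cohens_d)
})

test_that("a planted connected component is detected in most replicates", {
  hits <- vapply(1:20, function(s) {
    coh <- generate_edge_cohort(
      n_parcels = 12, n_a = 20, n_b = 20,
      planted = planted_star(1, 2:11), effect = 1, seed = s
    )
    res <- nbs_extent_test(coh$edges, "interaction", n_perm = 299, seed = s)
    nrow(res) > 0 && min(res$p_fwe) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Cohen's d follows mean |t| / sqrt(df) and scales linearly", {
  one <- tibble::tibble(i = 1, j = 2, t = 2.5)
  expect_equal(cohens_d(one, df = 100), 0.25)
  expect_equal(cohens_d(tibble::tibble(i = 1, j = 2, t = 2.97), df = 105),
    0.2899,
    tolerance = 1e-3
  )
  set.seed(46)
  tm <- tibble::tibble(i = 1:5, j = 2:6, t = rnorm(5))
  expect_equal(cohens_d(dplyr::mutate(tm, t = 3 * t), df = 50),
    3 * cohens_d(tm, df = 50),
    tolerance = 1e-12
  )
  comp <- tibble::tibble(i = c(1, 2), j = c(2, 3))
  expect_equal(
    cohens_d(tm, comp, df = 50),
    mean(abs(tm$t[1:2])) / sqrt(50)
  )
  expect_error(cohens_d(tm[0, ], df = 10), class = "neonet_invalid_config")
})

test_that("warnings and contract errors fire for bad designs", {
  coh <- generate_edge_cohort(n_parcels = 6, n_a = 5, n_b = 5, seed = 9)
  expect_warning(
    nbs_extent_test(coh$edges, "group_main", n_perm = 50, seed = 1),
    "fewer than 100"
  )
  expect_error(
    nbs_extent_test(coh$edges, "group_main", t_threshold = 0),
    class = "neonet_invalid_config"
  )
  solo <- coh$edges[coh$edges$state == "AS", ]
  expect_error(edge_statistics(solo, "interaction"), class = "neonet_invalid_design")
})
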