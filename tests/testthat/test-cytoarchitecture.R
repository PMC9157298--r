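test_that("atlas projection assigns each source its region's six densities", {
  tm <- toy_model(n_sensors = 8, n_sources = 16, n_parcels = 8)
  atlas <- with(new.env(), {
    set.seed(61)
    generate_cyto_atlas(tm$parc)
  })
  proj <- project_atlas(atlas, tm$parc)
  expect_equal(nrow(proj), 16 * 6)
  # identity mapping: source densities equal their parcel's region values
  for (src in c(1, 7, 16)) {
    p <- tm$parc$assignment[src]
    expected <- atlas$density[atlas$region == tm$parc$parcels$name[p]]
    got <- proj$density[proj$source == src][order(proj$layer[proj$source == src])]
    expect_equal(got, expected[order(atlas$layer[atlas$region == tm$parc$parcels$name[p]])])
  }
})

test_that("coarse-region atlases and uncovered sources behave as specified", {
  tm <- toy_model(n_sensors = 8, n_sources = 16, n_parcels = 8)
  regions <- unique(tm$parc$parcels$region)
  coarse <- tidyr::expand_grid(region = regions, layer = 1:6)
  coarse$density <- 1000 * coarse$layer + as.integer(factor(coarse$region))
  proj <- project_atlas(coarse, tm$parc)
  expect_equal(nrow(proj), 16 * 6)
  # two-value toy atlas -> bimodal source histogram per layer
  two <- coarse
  two$density <- ifelse(two$region == regions[1], 100, 200)
  proj2 <- project_atlas(two, tm$parc)
  expect_setequal(unique(proj2$density), c(100, 200))
  missing <- coarse[coarse$region != regions[1], ]
  expect_error(project_atlas(missing, tm$parc), class = "neonet_projection_error")
})

test_that("constant atlases produce identical source values and zero D", {
  tm <- toy_model(n_sensors = 8, n_sources = 16, n_parcels = 8)
  const <- tidyr::expand_grid(region = tm$parc$parcels$name, layer = 1:6)
  const$density <- 42
  proj <- project_atlas(const, tm$parc)
  expect_equal(unique(proj$density), 42)
  res <- surrogate_network_test(
    tibble::tibble(i = 1, j = 2), tm$parc, proj,
    n_surrogates = 20, seed = 1
  )
  expect_equal(res$D, rep(0, 6))
  expect_equal(res$p_surrogate, rep(1, 6))
})

test_that("network profiles cover exactly the incident parcels' sources", {
  tm <- toy_model(n_sensors = 8, n_sources = 16, n_parcels = 8)
  set.seed(62)
  atlas <- generate_cyto_atlas(tm$parc)
  proj <- project_atlas(atlas, tm$parc)
  single <- tibble::tibble(i = 2, j = 5)
  prof <- network_density_profile(single, proj)
  n_src <- sum(tm$parc$assignment %in% c(2, 5))
  expect_equal(nrow(prof), n_src * 6)
  # duplicate edges change nothing
  dup <- dplyr::bind_rows(single, single)
  expect_equal(network_density_profile(dup, proj), prof)
  # a network touching all parcels reproduces the whole cortex
  all_net <- tibble::tibble(i = 1:7, j = 2:8)
  expect_equal(
    sort(network_density_profile(all_net, proj)$density),
    sort(proj$density)
  )
  expect_error(network_density_profile(single[0, ], proj),
    class = "neonet_invalid_config"
  )
})

test_that("KS statistic matches hand ECDF computations and ks.test", {
  expect_equal(ks_two_sample(1:5, 1:5), 0)
  expect_equal(ks_two_sample(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(ks_two_sample(c(1, 2, 3, 4), c(3, 4, 5, 6)), 0.5)
  set.seed(63)
  for (k in 1:10) {
    a <- rnorm(30 + k)
    b <- rnorm(40, mean = k / 10)
    expect_equal(
      ks_two_sample(a, b),
      unname(suppressWarnings(ks.test(a, b)$statistic))
    )
    # internal fast variant agrees too
    expect_equal(neonet:::ks_vs_sorted_ref(a, sort(b)), ks_two_sample(a, b))
  }
  expect_error(ks_two_sample(numeric(0), 1:3), class = "neonet_invalid_config")
})

test_that("KS D is invariant under strictly monotone transforms", {
  set.seed(64)
  a <- rexp(25)
  b <- rexp(35, rate = 2)
  d0 <- ks_two_sample(a, b)
  expect_equal(ks_two_sample(log(a), log(b)), d0)
  expect_equal(ks_two_sample(a^3, b^3), d0)
})

test_that("surrogate p-values are calibrated for sampler-drawn networks", {
  tm <- toy_model(n_sensors = 10, n_sources = 40, n_parcels = 10)
  set.seed(65)
  atlas <- generate_cyto_atlas(tm$parc)
  proj <- project_atlas(atlas, tm$parc)
  # draw the observed network with the same sampler the null uses
  pvals <- vapply(1:150, function(s) {
    parcels <- sample(1:10, 3)
    net <- tibble::tibble(i = parcels[c(1, 1)], j = parcels[c(2, 3)])
    surrogate_network_test(net, tm$parc, proj,
      n_surrogates = 49, seed = s, network_name = "cal"
    )$p_surrogate[3]
  }, numeric(1))
  expect_gte(min(pvals), 1 / 50)
  # approximately uniform: mean near 0.5, no excess of small p
  expect_lt(abs(mean(pvals) - 0.5), 0.08)
  expect_lt(mean(pvals <= 0.05), 0.11)
})

test_that("a planted layer-III density shift is detected at FDR < 0.05", {
  tm <- toy_model(n_sensors = 12, n_sources = 100, n_parcels = 20)
  net <- tibble::tibble(i = c(1, 1, 2, 3), j = c(2, 3, 4, 5))
  net_parcels <- 1:5
  set.seed(66)
  atlas <- generate_cyto_atlas(tm$parc,
    layer3_shift = 3,
    shifted_parcels = net_parcels
  )
  proj <- project_atlas(atlas, tm$parc)
  res <- cyto_adjust_family(
    surrogate_network_test(net, tm$parc, proj, n_surrogates = 499, seed = 2)
  )
  l3 <- res[res$layer == 3, ]
  expect_lt(l3$p_fdr, 0.05)
  expect_equal(l3$direction, "higher")
})

test_that("the null atlas keeps the surrogate test calibrated after BH", {
  tm <- toy_model(n_sensors = 8, n_sources = 32, n_parcels = 8)
  hits <- vapply(1:100, function(s) {
    atlas <- neonet:::with_seed(1000 + s, generate_cyto_atlas(tm$parc))
    proj <- project_atlas(atlas, tm$parc)
    net <- neonet:::with_seed(2000 + s, {
      parcels <- sample(1:8, 3)
      tibble::tibble(i = parcels[c(1, 1)], j = parcels[c(2, 3)])
    })
    res <- cyto_adjust_family(
      surrogate_network_test(net, tm$parc, proj, n_surrogates = 99, seed = s)
    )
    any(res$p_fdr < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 100))
})

test_that("whole-cortex networks trigger the degenerate-null warning", {
  tm <- toy_model(n_sensors = 8, n_sources = 16, n_parcels = 8)
  set.seed(67)
  atlas <- generate_cyto_atlas(tm$parc)
  proj <- project_atlas(atlas, tm$parc)
  expect_warning(
    surrogate_network_test(
      tibble::tibble(i = 1:7, j = 2:8), tm$parc, proj,
      n_surrogates = 19, seed = 1
    ),
    "degenerate"
  )
})
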