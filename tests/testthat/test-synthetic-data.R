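test_that("identity mixing gives the identity lead field and 1:1 parcels", {
  hm <- identity_model(4)
  expect_equal(hm$lf$matrix, diag(4))
  expect_equal(hm$parc$assignment, 1:4)
  expect_true(all(hm$parc$parcels$region %in%
    c("frontal", "central", "temporal", "occipital")))
})

test_that("head-model generation is deterministic under a fixed seed", {
  cfg <- study_config(n_sensors = 10, n_sources = 40, n_parcels = 10, seed = 7)
  a <- generate_head_model(cfg)
  b <- generate_head_model(cfg)
  expect_identical(a$lead_field$matrix, b$lead_field$matrix)
  expect_identical(a$parcellation, b$parcellation)
})

test_that("source-to-parcel assignment covers every parcel and sums up", {
  cfg <- study_config(n_sensors = 10, n_sources = 100, n_parcels = 20, seed = 3)
  hm <- generate_head_model(cfg)
  counts <- table(hm$parcellation$assignment)
  expect_length(counts, 20)
  expect_true(all(counts >= 1))
  expect_equal(sum(counts), 100)
  expect_true(all(colSums(hm$lead_field$matrix^2) > 0))
})

test_that("more parcels than sources is an invalid configuration", {
  expect_error(
    study_config(n_sensors = 8, n_sources = 5, n_parcels = 10),
    class = "neonet_invalid_config"
  )
})

test_that("coupled pairs reach the designed phase-synchrony endpoints", {
  p1 <- generate_coupled_pair(18000, 100, c(1.5, 4),
    lag = pi / 2,
    coupling = 1, seed = 5
  )
  expect_gte(debiased_wpli(p1$x, p1$y), 0.95)
  # coupling 0: unbiased around 0 (Monte-Carlo over seeds)
  m <- mean(vapply(1:100, function(s) {
    p <- generate_coupled_pair(2000, 100, c(4, 8), coupling = 0, seed = s)
    debiased_wpli(p$x, p$y)
  }, numeric(1)))
  expect_lt(abs(m), 0.05)
})

test_that("coupled-pair generation is deterministic and warns on zero lag", {
  a <- generate_coupled_pair(500, 100, c(4, 8), coupling = 0.5, seed = 9)
  b <- generate_coupled_pair(500, 100, c(4, 8), coupling = 0.5, seed = 9)
  expect_identical(a, b)
  expect_warning(
    generate_coupled_pair(500, 100, c(4, 8), lag = 0, coupling = 1, seed = 1),
    "imaginary cross-spectrum"
  )
  expect_error(
    generate_coupled_pair(500, 100, c(4, 60), coupling = 1, seed = 1),
    class = "neonet_invalid_band"
  )
})

test_that("generated signals keep at least 90% of power inside the band", {
  for (s in 1:5) {
    p <- generate_coupled_pair(4000, 100, c(1.5, 4), coupling = 0.5, seed = s)
    spec <- Mod(fft(p$x))^2
    freqs <- (seq_along(spec) - 1) / length(spec) * 100
    sym <- freqs > 50
    freqs[sym] <- 100 - freqs[sym]
    inband <- freqs >= 1.4 & freqs <= 4.1
    expect_gte(sum(spec[inband]) / sum(spec), 0.9)
  }
})

test_that("empirical phase synchrony increases with planted coupling", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(grid, function(cc) {
    mean(vapply(1:50, function(s) {
      p <- generate_coupled_pair(1500, 100, c(4, 8), coupling = cc, seed = s)
      debiased_wpli(p$x, p$y)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("cohort regeneration is bit-identical and sized like the study", {
  cfg <- study_config(
    n_group_a = 3, n_group_b = 4, n_sensors = 8, n_sources = 16,
    n_parcels = 8, epoch_windows = 1, window_length = 3,
    bands = band_spec("high_delta", 1.5, 4), planted_band = "high_delta",
    seed = 11
  )
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$recordings, b$recordings)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$atlas, b$atlas)
  expect_equal(nrow(a$outcomes), 7)
  expect_named(a$recordings[[1]], c("AS", "QS"))
})

test_that("full-size design yields one outcome row per subject", {
  cfg <- study_config(
    n_group_a = 46, n_group_b = 61, n_sensors = 6, n_sources = 6,
    n_parcels = 6, epoch_windows = 1, window_length = 2,
    bands = band_spec("high_delta", 1.5, 4), planted_band = "high_delta",
    coupling_strength = 0, seed = 2
  )
  st <- generate_cohort(cfg)
  expect_equal(nrow(st$outcomes), 107)
  expect_equal(sum(st$subjects$group == "A"), 46)
})

test_that("zero coupling empties the planted truth", {
  cfg <- study_config(
    n_group_a = 2, n_group_b = 2, n_sensors = 6, n_sources = 6, n_parcels = 6,
    epoch_windows = 1, window_length = 2,
    bands = band_spec("high_delta", 1.5, 4), planted_band = "high_delta",
    coupling_strength = 0, seed = 3
  )
  st <- generate_cohort(cfg)
  expect_equal(nrow(st$truth$couplings), 0)
  expect_true(all(st$truth$delta_true$delta_true == 0))
})

test_that("planted interaction couplings have opposite sign across groups", {
  cfg <- study_config(
    n_group_a = 4, n_group_b = 4, n_sensors = 8, n_sources = 16, n_parcels = 8,
    epoch_windows = 1, window_length = 3,
    bands = band_spec("high_delta", 1.5, 4), planted_band = "high_delta",
    coupling_strength = 0.8, coupling_sd = 0.05, seed = 13
  )
  st <- generate_cohort(cfg)
  dt <- st$truth$delta_true
  expect_true(all(dt$delta_true[dt$group == "A"] > 0))
  expect_true(all(dt$delta_true[dt$group == "B"] < 0))
})

test_that("with no planted effect the outcome is unlinked to the truth delta", {
  # null-correlation check across seeds at outcome_effect = 0; at n = 50 the
  # null Spearman rho has sd ~ 1/7, so |rho| < 0.3 holds for ~96% of draws
  rhos <- vapply(1:20, function(s) {
    coh <- generate_edge_cohort(
      n_parcels = 10, n_a = 50, n_b = 25,
      planted = planted_star(1, 2:6), effect = 0.5, outcome_effect = 0, seed = s
    )
    a <- coh$truth$delta_true$group == "A"
    cor(coh$truth$delta_true$delta_true[a],
      coh$outcomes$fine_motor[a],
      method = "spearman"
    )
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
  expect_gte(mean(abs(rhos) < 0.3), 0.9)
})

test_that("a study directory round-trips through write_study/read_study", {
  cfg <- study_config(
    n_group_a = 2, n_group_b = 2, n_sensors = 6, n_sources = 12, n_parcels = 6,
    epoch_windows = 1, window_length = 2,
    bands = band_spec("theta", 4, 8), planted_band = "theta", seed = 21
  )
  st <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_study(dir)
  expect_equal(back$lead_field$matrix, st$lead_field$matrix, tolerance = 1e-12)
  expect_equal(
    back$recordings[["S001"]][["AS"]]$data,
    st$recordings[["S001"]][["AS"]]$data,
    tolerance = 1e-12, ignore_attr = TRUE
  )
  expect_equal(back$outcomes$fine_motor, st$outcomes$fine_motor)
  expect_equal(back$atlas, st$atlas, tolerance = 1e-12, ignore_attr = TRUE)
})
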