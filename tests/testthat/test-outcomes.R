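test_that("PCA composites capture a dominant shared factor", {
  set.seed(51)
  base <- rnorm(20)
  items <- tibble::tibble(
    subject = sprintf("S%02d", 1:20),
    a = base, b = base, c = base + rnorm(20, sd = 1e-6)
  )
  comp <- pca_composites(items)
  ve <- attr(comp, "variance_explained")
  expect_gt(ve[1], 0.999)
  expect_lt(ve[2], 1e-3)
})

test_that("planted orthogonal factors are recovered up to sign", {
  set.seed(52)
  n <- 200
  # unequal block sizes keep the two principal axes identifiable after the
  # per-item standardization inside the PCA
  f1 <- rnorm(n)
  f2 <- rnorm(n)
  l1 <- c(1, 1, 1, 1, 0, 0)
  l2 <- c(0, 0, 0, 0, 1, 1)
  items <- sapply(1:6, function(k) l1[k] * f1 + l2[k] * f2 + rnorm(n, sd = 0.1))
  colnames(items) <- paste0("it", 1:6)
  tbl <- dplyr::bind_cols(
    tibble::tibble(subject = sprintf("S%03d", 1:n)),
    tibble::as_tibble(items)
  )
  comp <- pca_composites(tbl)
  # each composite aligns with one planted factor
  cors <- abs(cor(cbind(comp$C1, comp$C2), cbind(f1, f2)))
  expect_gt(max(cors[1, ]), 0.95)
  expect_gt(max(cors[2, ]), 0.95)
  # sign convention: largest loading positive
  rot <- attr(comp, "rotation")
  expect_gt(rot[which.max(abs(rot[, 1])), 1], 0)
  expect_gt(rot[which.max(abs(rot[, 2])), 2], 0)
})

test_that("duplicated subjects get identical composites; constant items drop", {
  set.seed(53)
  items <- tibble::tibble(
    subject = c(sprintf("S%02d", 1:8), "S01"),
    a = c(rnorm(8), 0), b = c(rnorm(8), 0), c = c(rnorm(8), 0)
  )
  items[9, -1] <- items[1, -1]
  comp <- pca_composites(items)
  expect_equal(comp$C1[9], comp$C1[1])
  expect_equal(comp$C2[9], comp$C2[1])
  with_const <- dplyr::mutate(items, flat = 1)
  expect_warning(pca_composites(with_const), "constant")
})

test_that("delta connectivity is the network-mean state difference", {
  m_as <- matrix(0.3, 4, 4)
  m_qs <- matrix(0.2, 4, 4)
  diag(m_as) <- diag(m_qs) <- 0
  net <- tibble::tibble(i = c(1, 2), j = c(2, 3))
  expect_equal(delta_connectivity(m_as, m_qs, net), 0.1)
  expect_equal(delta_connectivity(m_as, m_as, net), 0)
  # antisymmetric under swapping the state matrices
  expect_equal(
    delta_connectivity(m_qs, m_as, net),
    -delta_connectivity(m_as, m_qs, net)
  )
  masked <- m_as
  masked[1, 2] <- masked[2, 1] <- NA
  expect_error(delta_connectivity(masked, m_qs, net), class = "neonet_invalid_config")
  expect_error(delta_connectivity(m_as, m_qs, net[0, ]), class = "neonet_invalid_config")
})

test_that("cohort deltas equal per-subject hand computation", {
  coh <- generate_edge_cohort(n_parcels = 6, n_a = 3, n_b = 3, seed = 11)
  net <- tibble::tibble(i = c(1, 1), j = c(2, 3))
  dl <- cohort_deltas(coh$edges, net, "net")
  one <- coh$edges[coh$edges$subject == "S001" &
    paste(coh$edges$i, coh$edges$j) %in% c("1 2", "1 3"), ]
  hand <- mean(one$value[one$state == "AS"] - one$value[one$state == "QS"])
  expect_equal(dl$delta[dl$subject == "S001"], hand)
  expect_equal(nrow(dl), 6)
})

test_that("Spearman correlations match hand-ranked values", {
  deltas <- tibble::tibble(
    subject = c("a", "b", "c"), network = "n1", delta = c(1, 2, 3)
  )
  outcomes <- tibble::tibble(subject = c("a", "b", "c"), C1 = c(3, 1, 2))
  res <- correlate_outcomes(deltas, outcomes,
    families = list(neurological = "C1"), min_pairs = 3
  )
  expect_equal(res$rho, -0.5)
  # perfectly monotone pair
  out2 <- tibble::tibble(subject = c("a", "b", "c"), C1 = c(10, 20, 40))
  res2 <- correlate_outcomes(deltas, out2,
    families = list(neurological = "C1"), min_pairs = 3
  )
  expect_equal(res2$rho, 1)
})

test_that("rank correlation is invariant to monotone transforms", {
  set.seed(54)
  deltas <- tibble::tibble(
    subject = sprintf("S%02d", 1:15), network = "n1", delta = rnorm(15)
  )
  y <- rnorm(15)
  out_raw <- tibble::tibble(subject = deltas$subject, C1 = y)
  out_tr <- tibble::tibble(subject = deltas$subject, C1 = exp(3 * y))
  fam <- list(neurological = "C1")
  r1 <- correlate_outcomes(deltas, out_raw, fam)
  r2 <- correlate_outcomes(deltas, out_tr, fam)
  r3 <- correlate_outcomes(dplyr::mutate(deltas, delta = .data$delta^3),
    out_raw, fam
  )
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$rho, r3$rho)
})

test_that("BH adjustment matches the step-up formula on a printed example", {
  p <- c(0.01, 0.04, 0.03, 0.002)
  res <- cyto_adjust_family(tibble::tibble(
    network = "n", layer = 1:4, n_network = 4, D = 0.5,
    direction = "higher", p_surrogate = p
  ))
  expect_equal(res$p_fdr, c(0.02, 0.04, 0.04, 0.008))
  expect_equal(res$p_fdr, bh_step_up(p))
})

test_that("BH within families: adjusted >= raw, order-invariant, monotone", {
  set.seed(55)
  deltas <- tibble::tibble(
    subject = sprintf("S%02d", 1:20), network = "n1", delta = rnorm(20)
  )
  outcomes <- tibble::tibble(
    subject = deltas$subject,
    C1 = rnorm(20), C2 = rnorm(20),
    cognitive = rnorm(20), fine_motor = rnorm(20)
  )
  res <- correlate_outcomes(deltas, outcomes)
  expect_true(all(res$p_fdr >= res$p))
  # families adjusted separately
  for (fam in unique(res$family)) {
    sub <- res[res$family == fam, ]
    expect_equal(sub$p_fdr, bh_step_up(sub$p))
    o <- order(sub$p)
    expect_true(all(diff(sub$p_fdr[o]) >= -1e-12))
  }
})

test_that("missing scores are dropped pairwise; ties in y are handled", {
  set.seed(56)
  deltas <- tibble::tibble(
    subject = sprintf("S%02d", 1:12), network = "n1", delta = rnorm(12)
  )
  outcomes <- tibble::tibble(
    subject = deltas$subject,
    C1 = c(rnorm(10), NA, NA),
    C2 = rep(1, 12) # all tied: rho undefined
  )
  res <- correlate_outcomes(deltas, outcomes,
    families = list(neurological = c("C1", "C2"))
  )
  expect_equal(res$n[res$score == "C1"], 10)
  expect_true(is.na(res$rho[res$score == "C2"]))
  expect_error(
    correlate_outcomes(deltas[1:4, ], outcomes,
      families = list(neurological = "C1")
    ),
    class = "neonet_invalid_config"
  )
})

test_that("the planted outcome correlation is recovered on average", {
  rhos <- vapply(1:100, function(s) {
    coh <- generate_edge_cohort(
      n_parcels = 12, n_a = 44, n_b = 10,
      planted = planted_star(1, 2:11), effect = 0.5,
      outcome_effect = 0.4, seed = s
    )
    deltas <- cohort_deltas(
      coh$edges[coh$edges$group == "A", ], coh$truth$planted, "net"
    )
    merged <- dplyr::left_join(deltas, coh$outcomes, by = c("subject", "group"))
    cor(merged$delta, merged$fine_motor, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.4), 0.15)
})
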