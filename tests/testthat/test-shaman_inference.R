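test_that("residual differences vanish for identical or FD-linear halves", {
  set.seed(1)
  E <- 6; n <- 8
  z <- matrix(rnorm(n * E), n, E)
  fdl <- runif(n, 0.05, 0.15); fdh <- runif(n, 0.3, 0.6)
  # halves identical in both edges and mean FD cancel exactly
  ident <- lapply(seq_len(n), function(i) {
    fake_half(z[i, ], z[i, ], fdl[i], fdl[i], 4)
  })
  expect_equal(residual_difference(ident), matrix(0, n, E),
               tolerance = 1e-12)

  # edges exactly linear in the half's mean FD: residuals are zero
  lin <- lapply(seq_len(n), function(i) {
    fake_half(0.2 + 1.5 * fdl[i] + numeric(E), 0.2 + 1.5 * fdh[i] + numeric(E),
              fdl[i], fdh[i], 4)
  })
  expect_equal(residual_difference(lin), matrix(0, n, E), tolerance = 1e-12)

  # constant FD across participants is rank-deficient
  const <- lapply(seq_len(n), function(i) {
    fake_half(z[i, ], z[i, ], 0.1, 0.4, 4)
  })
  expect_error(residual_difference(const), "rank-deficient")
})

test_that("residual differences match the hat-matrix OLS oracle", {
  set.seed(2)
  n <- 5; E <- 4
  zl <- matrix(rnorm(n * E), n, E); zh <- matrix(rnorm(n * E), n, E)
  fdl <- runif(n, 0, 0.2); fdh <- runif(n, 0.3, 0.8)
  halves <- lapply(seq_len(n), function(i) {
    fake_half(zl[i, ], zh[i, ], fdl[i], fdh[i], 4)
  })
  got <- residual_difference(halves)
  for (e in seq_len(E)) {
    rl <- ols_oracle(cbind(1, fdl), zl[, e])$residuals
    rh <- ols_oracle(cbind(1, fdh), zh[, e])$residuals
    expect_equal(got[, e], rh - rl, tolerance = 1e-10)
  }
})

test_that("the trait regression on residual differences matches a brute-force oracle", {
  expect_equal(impact_glm(matrix(0, 6, 3), rnorm(6))$beta, rep(0, 3))
  expect_equal(impact_glm(matrix(0, 6, 3), rnorm(6))$t, rep(0, 3))

  # planted slope recovered within 1%
  set.seed(3)
  trait <- rnorm(60, 5, 2)
  slope <- 0.8
  diff <- outer(trait * slope, rep(1, 4)) + matrix(rnorm(240, 0, 1e-3), 60, 4)
  im <- impact_glm(diff, trait)
  expect_true(all(abs(im$beta - slope) / slope < 0.01))

  # 6-participant toy with one covariate vs explicit normal equations
  set.seed(4)
  tr6 <- rnorm(6); cv6 <- rnorm(6)
  d6 <- matrix(rnorm(6 * 5), 6, 5)
  im6 <- impact_glm(d6, tr6, cbind(age = cv6))
  X <- cbind(1, tr6, cv6)
  for (e in 1:5) {
    o <- ols_oracle(X, d6[, e])
    expect_equal(im6$beta[e], o$beta[2], tolerance = 1e-10)
    expect_equal(im6$t[e], o$t[2], tolerance = 1e-10)
  }
  expect_equal(im6$df, 3L)

  # negating the trait negates the edgewise coefficients, leaves |t| alone
  im_neg <- impact_glm(d6, -tr6, cbind(age = cv6))
  expect_equal(im_neg$beta, -im6$beta, tolerance = 1e-12)
  expect_equal(im_neg$t, -im6$t, tolerance = 1e-12)

  expect_error(impact_glm(d6, tr6, cbind(tr6)), "rank-deficient")
  expect_error(impact_glm(matrix(0, 2, 3), c(1, 2)), "n <= p")
})

test_that("Stouffer combining reduces to the closed form", {
  expect_equal(stouffer_z(c(0.5, 1.5, -1.0)), 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(stouffer_z(c(0.5, 1.5, -1.0)), 0.5773503, tolerance = 1e-6)
  set.seed(6)
  for (E in c(1, 2, 17, 100)) {
    z <- rnorm(E)
    expect_equal(stouffer_z(z), sum(z) / sqrt(E), tolerance = 1e-12)
  }
})

test_that("non-parametric combining counts with add-one smoothing", {
  set.seed(7)
  E <- 5; P <- 99
  null <- matrix(rnorm(P * E), P, E)
  obs <- rep(10, E)                       # above every null value
  res <- npc_stouffer(obs, null, direction = "two_sided")
  expect_equal(res$edge_p, rep(1 / 100, E))
  expect_equal(res$p, 1 / 100)
  expect_gt(res$Z, max(res$perm_Z))

  # E = 1: the combined Z is the single edge z
  r1 <- npc_stouffer(3, matrix(rnorm(50), 50, 1))
  expect_equal(r1$Z, r1$edge_z)

  # omnibus p respects its floor and ceiling
  expect_gte(res$p, 1 / (P + 1))
  r_low <- npc_stouffer(rep(0, E), abs(null))
  expect_lte(r_low$p, 1)
  expect_true(is.finite(r_low$Z))        # worst case stays finite

  expect_warning(r_empty <- npc_stouffer(obs, null,
                                         include = rep(FALSE, E)),
                 "empty")
  expect_equal(r_empty$Z, 0)
  expect_equal(r_empty$p, 1)
})

test_that("directional scores gate, split by sign, and are trait-sign invariant", {
  set.seed(8)
  E <- 40; P <- 60
  t_imp <- rnorm(E)
  null <- matrix(rnorm(P * E), P, E)

  # everything gated
  suppressWarnings(d0 <- directional_scores(t_imp, rep(0.5, E), null))
  expect_equal(d0$over_z, 0); expect_equal(d0$over_p, 1)
  expect_equal(d0$under_z, 0); expect_equal(d0$under_p, 1)

  # impact identical to a strong trait-FC map: all edges overestimation
  strong <- 3 * sign(rnorm(E)) * runif(E, 1, 2)
  suppressWarnings(d1 <- directional_scores(strong, strong, null))
  expect_true(all(d1$over_set))
  expect_false(any(d1$under_set))
  expect_false(any(d1$over_set & d1$under_set))

  # sign-flip invariance: negating the trait negates impact, trait-FC,
  # and every permutation statistic, leaving both scores unchanged
  tfc <- rnorm(E, 0, 3)
  d2 <- suppressWarnings(directional_scores(t_imp, tfc, null))
  d3 <- suppressWarnings(directional_scores(-t_imp, -tfc, -null))
  expect_equal(d2$over_z, d3$over_z, tolerance = 1e-12)
  expect_equal(d2$over_p, d3$over_p)
  expect_equal(d2$under_z, d3$under_z, tolerance = 1e-12)
  expect_equal(d2$under_p, d3$under_p)
})

test_that("the full pipeline is deterministic and internally consistent", {
  co <- tiny_cohort(12, 16, 64, seed = 33)
  r1 <- run_shaman(co, trait = "trait", n_perm = 30, seed = 5)
  r2 <- run_shaman(co, trait = "trait", n_perm = 30, seed = 5)
  expect_identical(r1$omnibus_z, r2$omnibus_z)
  expect_identical(r1$null_t, r2$null_t)
  expect_identical(r1$edge_z, r2$edge_z)

  expect_gte(r1$omnibus_p, 1 / 31)
  expect_lte(r1$omnibus_p, 1)
  expect_length(r1$edge_z, n_edges(16))
  expect_false(any(r1$over_set & r1$under_set))
  gated <- abs(r1$trait_fc$t) <= r1$gate
  expect_false(any(gated & (r1$over_set | r1$under_set)))

  # the observed edgewise t matches the exported double-precision path
  hs <- lapply(co$participants, function(ts) {
    summarize_half(ts, assign_halves(ts$fd, ts$run_starts))
  })
  imR <- impact_glm(residual_difference(hs), co$traits$trait)
  expect_equal(r1$impact$t, imR$t, tolerance = 1e-4)

  expect_error(run_shaman(co, trait = "trait", n_perm = 0), "n_perm")
  expect_error(run_shaman(co, trait = "nope"), "not found")
})

test_that("omnibus p-values are uniform under an independent trait", {
  # small-cohort calibration: an analysis trait independent of the data
  ps <- vapply(1:60, function(r) {
    co <- tiny_cohort(20, 12, 64, seed = 400 + r)
    suppressWarnings(run_shaman(co, trait = "null_trait", n_perm = 49,
                                seed = 800 + r)$omnibus_p)
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(mean(ps < 0.05), 0.2)
})

test_that("power_analysis reports one detection flag per replicate", {
  gen <- function(n, seed) tiny_cohort(n, 12, 64, seed = seed)
  pw <- power_analysis(gen, sizes = c(8, 10), reps = 1, n_perm = 19,
                       seed = 2)
  expect_equal(pw$n, c(8, 10))
  expect_true(all(pw$rate %in% c(0, 1)))
  expect_equal(pw$detections, pw$rate * pw$reps)
})
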