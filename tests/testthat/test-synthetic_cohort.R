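test_that("basis construction scales, symmetrizes, and enforces positive definiteness", {
  # zero pattern: identity correlation
  b0 <- build_basis(matrix(0, 5, 5), peak = 0.4)
  expect_equal(b0$values, diag(5))
  expect_equal(b0$shrinkage, 1)

  # single off-diagonal pair: closed-form eigenvalues 1 +/- peak
  pat <- matrix(0, 3, 3); pat[2, 3] <- 1
  b1 <- build_basis(pat, peak = 0.5)
  expect_equal(b1$values[2, 3], 0.5)
  expect_equal(b1$values[3, 2], 0.5)
  expect_equal(sort(eigen(b1$values)$values), c(0.5, 1.0, 1.5))

  # all-ones off-diagonal at peak 0.9 on 4 nodes is not PD until shrunk
  pat2 <- matrix(1, 4, 4); diag(pat2) <- 0
  # eigenvalue oracle: 1 + 3p and 1 - p; PD needs p < 1 (ok) but start
  # from a deliberately broken asymmetric variant to exercise shrinkage
  b2 <- build_basis(pat2, peak = 0.9)
  expect_gt(min(eigen(b2$values)$values), 0)
  expect_true(is.matrix(b2$chol))

  # a genuinely non-PD start: 3 nodes fully connected at peak ~ 1
  pat3 <- matrix(1, 3, 3); diag(pat3) <- 0
  b3 <- build_basis(pat3, peak = 0.99)
  # atanh-free check via brute-force eigendecomposition
  expect_gt(min(eigen(b3$values)$values), 0)

  expect_error(build_basis(matrix(0, 2, 3)), "square")
  expect_error(build_basis(matrix(0, 3, 3), peak = 1.2), "peak")
  expect_error(build_basis(matrix(0, 3, 3), peak = 0), "peak")
})

test_that("correlated draws have unit variance and converge to the basis", {
  bI <- build_basis(matrix(0, 4, 4), peak = 0.3)
  x <- draw_correlated_series(bI, 1e5, seed = 1)
  r <- cor(t(x))
  expect_lt(max(abs(r[lower.tri(r)])), 0.02)      # ~3/sqrt(n)

  x1 <- draw_correlated_series(bI, 50, seed = 9)
  x2 <- draw_correlated_series(bI, 50, seed = 9)
  expect_identical(x1, x2)

  pat <- matrix(c(0, 1, 1, 0), 2, 2)
  b8 <- build_basis(pat, peak = 0.8)
  y <- draw_correlated_series(b8, 1e5, seed = 2)
  expect_gt(cor(y[1, ], y[2, ]), 0.78)
  expect_lt(cor(y[1, ], y[2, ]), 0.82)

  expect_error(draw_correlated_series(bI, 1), "n_frames")
})

test_that("convergence to the basis improves with series length", {
  pat <- basis_pattern(8, "brain", n_groups = 2)
  b <- build_basis(pat, peak = 0.3)
  frob <- vapply(c(256, 4096, 65536), function(nf) {
    x <- draw_correlated_series(b, nf, seed = 31)
    norm(cor(t(x)) - b$values, "F")
  }, 0)
  expect_true(all(diff(frob) < 0))
})

test_that("FD is the per-frame cross-node population variance", {
  expect_equal(fd_from_series(matrix(c(2, 2, 2), 3, 1)), 0)
  expect_equal(fd_from_series(matrix(c(1, 3), 2, 1)), 1.0)  # divide by n
  m <- matrix(rep(c(1, 5, 9), 4), 3, 4)                     # constant rows
  expect_equal(fd_from_series(m), rep(var(c(1, 5, 9)) * 2 / 3, 4))
  set.seed(3)
  fd <- fd_from_series(matrix(rnorm(40), 4, 10))
  expect_true(all(fd >= 0))
  expect_error(fd_from_series(matrix(1, 1, 5)), "2 nodes")
})

test_that("mixing applies sqrt-variance weights and the unit-variance correction", {
  set.seed(8)
  brain <- matrix(rnorm(3 * 100), 3, 100)
  motion <- matrix(rnorm(3 * 100), 3, 100)

  mix <- mix_series(brain, motion, 1.6329, 0.2216, correct_variance = FALSE)
  expect_equal(mix, sqrt(1.6329) * brain + sqrt(0.2216) * motion,
               tolerance = 1e-15)
  expect_equal(sqrt(1.6329), 1.277850, tolerance = 1e-6)
  expect_equal(sqrt(0.2216), 0.470744, tolerance = 1e-6)

  expect_equal(mix_series(brain, motion, 1, 0, correct_variance = FALSE),
               brain)

  # variance-addition: independent unit inputs at (0.5, 0.5) stay near 1
  b2 <- matrix(rnorm(2 * 2e4), 2, 2e4)
  m2 <- matrix(rnorm(2 * 2e4), 2, 2e4)
  v <- apply(mix_series(b2, m2, 0.5, 0.5, correct_variance = FALSE), 1, var)
  expect_true(all(abs(v - 1) < 0.05))

  # corrected output has exactly unit sample variance per node
  vc <- apply(mix_series(brain, motion, 2, 0.3), 1, var)
  expect_equal(vc, rep(1, 3), tolerance = 1e-12)

  expect_error(mix_series(brain, motion[, 1:10], 1, 1), "shape")
  expect_error(mix_series(brain, motion, -1, 1), "non-negative")
})

test_that("cohorts are reproducible and honor the zero-motion override", {
  co1 <- tiny_cohort(6, 12, 48, seed = 21)
  co2 <- tiny_cohort(6, 12, 48, seed = 21)
  expect_identical(co1$participants, co2$participants)
  expect_identical(co1$traits, co2$traits)

  co0 <- tiny_cohort(5, 12, 48, seed = 3, fd_scale = 0)
  for (ts in co0$participants) expect_true(all(ts$fd == 0))
  expect_true(all(co0$design$w_motion == 0))
  expect_true(all(co0$traits$trait > 0))

  # FD positivity and the all-identical-iff-zero property
  co <- tiny_cohort(4, 12, 48, seed = 5)
  for (ts in co$participants) expect_true(all(ts$fd >= 0))
  expect_error(generate_cohort(n_participants = 1), "2 participants")
})

test_that("default basis patterns are disjoint, symmetric binary masks", {
  br <- basis_pattern(32, "brain")
  mo <- basis_pattern(32, "motion")
  for (m in list(br, mo)) {
    expect_equal(m, t(m))
    expect_true(all(m %in% c(0, 1)))
    expect_true(all(diag(m) == 0))
  }
  expect_equal(sum(br * mo), 0)
  expect_gt(sum(mo), 0)
})
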