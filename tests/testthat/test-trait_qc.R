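test_that("edgewise trait regressions match the normal-equations oracle", {
  set.seed(1)
  n <- 6
  trait <- rnorm(n); fd <- runif(n, 0.05, 0.6)
  edges <- matrix(rnorm(n * 3), n, 3)
  em <- trait_fc(edges, trait, cbind(FD = fd))
  X <- cbind(1, trait, fd)
  for (e in 1:3) {
    o <- ols_oracle(X, edges[, e])
    expect_equal(em$beta[e], o$beta[2], tolerance = 1e-10)
    expect_equal(em$t[e], o$t[2], tolerance = 1e-10)
  }
  expect_equal(em$df, n - 3L)
  expect_match(em$model, "FC ~ trait \\+ FD")
  expect_error(trait_fc(edges, c(trait[-n], NA)), "missing")
})

test_that("a trait orthogonal to the edges yields centered null t-values", {
  set.seed(2)
  n <- 300; E <- 80
  em <- trait_fc(matrix(rnorm(n * E), n, E), rnorm(n))
  expect_lt(abs(mean(em$t)), 0.25)
  expect_lt(mean(abs(em$t) > 2), 0.15)

  # planted slope recovered within its confidence band
  trait <- rnorm(n)
  planted <- 0.4
  edges <- outer(trait, rep(planted, 5)) + matrix(rnorm(n * 5, 0, 0.5), n, 5)
  emp <- trait_fc(edges, trait)
  expect_true(all(abs(emp$beta - planted) < 4 * 0.5 / sqrt(n)))
})

test_that("motion-FC regression is exact on linear data and rejects constant FD", {
  n <- 20
  fd <- seq(0.1, 1, length.out = n)
  edges <- outer(rep(1, n), c(0.3, -0.1)) + fd %*% t(c(-0.5, 0.25))
  em <- motion_fc(edges, fd)
  expect_equal(em$beta, c(-0.5, 0.25), tolerance = 1e-12)
  expect_equal(em$predictor, "FD")
  expect_error(motion_fc(edges, rep(0.2, n)), "constant")

  set.seed(3)
  em0 <- motion_fc(matrix(rnorm(500 * 10, 0, 0.1), 500, 10),
                   runif(500, 0.05, 0.8))
  expect_lt(max(abs(em0$beta)), 0.1)     # null calibration at edge-noise scale
})

test_that("effect sizes obey the t-to-r identity and scale invariance", {
  set.seed(4)
  n <- 25
  trait <- rnorm(n); fd <- runif(n)
  edges <- matrix(rnorm(n * 6), n, 6)
  em <- trait_fc(edges, trait, cbind(FD = fd))
  expect_equal(em$r_effect^2, em$t^2 / (em$t^2 + em$df), tolerance = 1e-12)
  expect_true(all(abs(em$r_effect) < 1))

  em_k <- trait_fc(edges, 10 * trait, cbind(FD = fd))
  expect_equal(em_k$beta, em$beta / 10, tolerance = 1e-12)
  expect_equal(em_k$t, em$t, tolerance = 1e-12)
  expect_equal(em_k$r_effect, em$r_effect, tolerance = 1e-12)
})

test_that("effect-size percentiles interpolate linearly and are monotone", {
  expect_equal(effect_percentile(rep(0.07, 12), 98), 0.07)
  expect_equal(effect_percentile(rep(-0.07, 12), 50), 0.07)  # uses |r|
  grid <- seq(0.01, 1, by = 0.01)
  expect_equal(effect_percentile(grid, 98), 0.9802, tolerance = 1e-12)
  expect_equal(effect_percentile(grid, 100), 1.0)
  qs <- vapply(c(10, 50, 90, 98, 100), effect_percentile, 0, effect = grid)
  expect_false(is.unsorted(qs))
  expect_error(effect_percentile(numeric(0)), "edges")
  expect_error(effect_percentile(grid, 0), "q must")
})

test_that("trait-motion correlations report both coefficients with p-values", {
  fd <- c(0.1, 0.25, 0.3, 0.45, 0.6, 0.75, 0.8, 0.9)
  r <- trait_fd_corr(fd, fd)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$spearman_rho, 1)

  # strictly monotone non-linear transform: Spearman stays 1, Pearson drops
  r2 <- trait_fd_corr(exp(3 * fd), fd)
  expect_equal(r2$spearman_rho, 1)
  expect_lt(r2$pearson_r, 1)
  expect_lt(r2$spearman_p, 0.05)

  set.seed(5)
  r3 <- trait_fd_corr(rnorm(1e4), runif(1e4))
  expect_lt(abs(r3$pearson_r), 0.03)
  expect_error(trait_fd_corr(rep(1, 5), runif(5)), "constant")
})

test_that("matrix similarity correlates edge vectors of equal ordering", {
  set.seed(6)
  a <- rnorm(45)
  expect_equal(matrix_similarity(a, a), list(pearson_r = 1, spearman_rho = 1))
  s <- matrix_similarity(a, -a)
  expect_equal(s$pearson_r, -1)
  expect_equal(s$spearman_rho, -1)
  x <- c(1.2, -0.4, 0.8, 0.1)
  y <- c(0.9, -0.2, 1.1, -0.3)
  expect_equal(matrix_similarity(x, y)$pearson_r, cor_oracle(x, y),
               tolerance = 1e-12)
  expect_error(matrix_similarity(a, a[-1]), "length")
})

test_that("variance reduction follows the squared-rho formula and rank invariance", {
  expect_equal(relative_reduction(0.73, 0.23), 1 - 0.23 / 0.73,
               tolerance = 1e-12)
  expect_error(relative_reduction(0, 0.2), "undefined")

  set.seed(7)
  n <- 400
  fd <- exp(rnorm(n, -1.3, 0.5))
  v_before <- fd^1.4 * exp(rnorm(n, 0, 0.15))    # strongly motion-coupled
  v_after <- exp(rnorm(n, 0, 0.3))               # decoupled after denoising
  va <- variance_reduction(v_before, v_after, fd)
  expect_gt(va$var_explained_before, 0.7)
  expect_gt(va$relative_reduction, 0.9)
  expect_equal(va$relative_reduction,
               1 - (va$rho_after / va$rho_before)^2, tolerance = 1e-12)

  # identical variances: zero reduction
  v0 <- variance_reduction(v_before, v_before, fd)
  expect_equal(v0$relative_reduction, 0, tolerance = 1e-12)

  # invariance under strictly monotone FD transforms (rank-based model)
  va2 <- variance_reduction(v_before, v_after, fd^3 * 10)
  expect_equal(va2$relative_reduction, va$relative_reduction,
               tolerance = 1e-12)

  expect_error(variance_reduction(c(-1, v_before[-1]), v_after, fd),
               "positive")
})
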