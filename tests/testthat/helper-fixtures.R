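# Shared fixtures: everything is generated in code at test time.

toy_ts <- function(n_nodes = 5, n_frames = 40, seed = 1, fd = NULL, tr = 0.8,
                   run_starts = 1L) {
  set.seed(seed)
  if (is.null(fd)) fd <- runif(n_frames, 0.02, 0.6)
  parcel_ts(matrix(rnorm(n_nodes * n_frames), n_nodes, n_frames), fd,
            run_starts = run_starts, tr = tr)
}

tiny_cohort <- function(n_participants = 12, n_nodes = 16, n_frames = 64,
                        seed = 1, ...) {
  generate_cohort(n_nodes = n_nodes, n_frames = n_frames,
                  n_participants = n_participants, seed = seed, ...)
}

# brute-force OLS via explicit normal equations: coefficients, t-values,
# and residuals for y (vector) on design X
ols_oracle <- function(X, y) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- as.numeric(sqrt(sigma2 * diag(XtXi)))
  list(beta = as.numeric(beta), t = as.numeric(beta) / se, se = se,
       residuals = as.numeric(res), df = df)
}

# direct-formula Pearson correlation (covariance over sd product)
cor_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# hand construction of a half_summary (for regression-stage tests)
fake_half <- function(z_low, z_high, fd_low, fd_high, n_nodes) {
  structure(list(
    edges_low = structure(list(z = z_low, n_nodes = n_nodes),
                          class = "edge_vector"),
    edges_high = structure(list(z = z_high, n_nodes = n_nodes),
                           class = "edge_vector"),
    fd_low = fd_low, fd_high = fd_high,
    n_low = 10L, n_high = 10L
  ), class = "half_summary")
}
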