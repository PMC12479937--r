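#' Stouffer's combined Z
#'
#' @param z Numeric vector of per-modality z-scores.
#' @return \code{sum(z) / sqrt(length(z))}.
#' @export
stouffer_z <- function(z) {
  if (length(z) == 0L) return(0)
  sum(z) / sqrt(length(z))
}

# residuals of Y (n x E) on design (1, x); errors if x is constant
.residualize <- function(Y, x) {
  if (stats::var(x) == 0) {
    stop("design rank-deficient: motion covariate is constant across participants")
  }
  X <- cbind(1, x)
  B <- solve(crossprod(X), crossprod(X, Y))
  Y - X %*% B
}

# per-edge OLS of Y on (1, trait, covariates); returns trait beta, t, df
.impact_t <- function(Y, trait, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, trait = trait)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("too few participants for the design (n <= p)")
  cx <- crossprod(X)
  ch <- tryCatch(chol(cx), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < sqrt(.Machine$double.eps) * max(diag(ch)))) {
    stop("rank-deficient design")
  }
  cxi <- chol2inv(ch)
  B <- cxi %*% crossprod(X, Y)
  res <- Y - X %*% B
  df <- n - p
  sigma2 <- .colSums(res^2, n, ncol(Y)) / df
  se <- sqrt(sigma2 * cxi[2L, 2L])
  beta <- B[2L, ]
  t <- ifelse(se > 0, beta / se, 0)
  structure(list(beta = unname(beta), t = unname(t), df = df),
            class = "impact_map")
}

#' Across-participant residual difference of split-half edges
#'
#' For each edge, the low-half Fisher-z values are regressed (across
#' participants) on an intercept and the low-half mean FD, and likewise for
#' the high half; the returned matrix is the per-participant difference
#' \code{residual_high - residual_low}. This removes the between-participant
#' motion effect from each half before the trait regression.
#'
#' @param halves List of \code{half_summary} objects, one per participant.
#' @return Participant x edge numeric matrix.
#' @export
residual_difference <- function(halves) {
  stopifnot(length(halves) >= 3L,
            all(vapply(halves, inherits, TRUE, "half_summary")))
  Ylow <- do.call(rbind, lapply(halves, function(h) h$edges_low$z))
  Yhigh <- do.call(rbind, lapply(halves, function(h) h$edges_high$z))
  fd_low <- vapply(halves, function(h) h$fd_low, 0)
  fd_high <- vapply(halves, function(h) h$fd_high, 0)
  .residual_difference_mat(Ylow, Yhigh, fd_low, fd_high)
}

.residual_difference_mat <- function(Ylow, Yhigh, fd_low, fd_high) {
  .residualize(Yhigh, fd_high) - .residualize(Ylow, fd_low)
}

#' Trait regression on the split-half residual differences
#'
#' Per-edge OLS of the residual-difference matrix on an intercept, the
#' trait, and optional covariates. The trait coefficient and its t-value
#' are the edgewise motion impact statistics.
#'
#' @param diff Participant x edge matrix from [residual_difference()].
#' @param trait Per-participant trait values.
#' @param covariates Optional per-participant covariate matrix/data frame.
#' @return An object of class \code{impact_map}: \code{beta}, \code{t},
#'   \code{df}.
#' @export
impact_glm <- function(diff, trait, covariates = NULL) {
  diff <- as.matrix(diff)
  if (nrow(diff) != length(trait)) stop("participants do not match")
  .impact_t(diff, trait, covariates)
}

#' @export
print.impact_map <- function(x, ...) {
  cat(sprintf("<impact_map> %d edges, df = %d, t range %.3g .. %.3g\n",
              length(x$t), x$df, min(x$t), max(x$t)))
  invisible(x)
}

# Per-edge ranks within the full exchangeable ensemble {observed} U
# {permutations} (P + 1 members). Every member's count is the number of
# ensemble statistics at least as large as its own, so the observed count
# equals the add-one formula (1 + #{null >= obs}) and every member
# is treated identically - ranking the observed against the nulls while
# ranking each permutation against itself would give the observed z a
# systematically wider range. z uses half-count smoothing,
# qnorm(1 - (count - 0.5)/(P + 1)), which keeps every z finite.
.npc_ranks <- function(s_obs, s_null) {
  P <- nrow(s_null)
  cnt <- .npc_counts_cpp(s_null, s_obs)
  # counts take values in 1..P+1: evaluate the z transform once per count
  tab <- stats::qnorm(1 - (seq_len(P + 1L) - 0.5) / (P + 1))
  zp <- tab[cnt$cnt_perm]
  dim(zp) <- dim(s_null)
  list(p_obs = cnt$cnt_obs / (P + 1),
       z_obs = tab[cnt$cnt_obs],
       z_perm = zp)
}

#' Non-parametric combining with Stouffer's function
#'
#' Treats each edge as a separate modality: per-edge empirical p-values are
#' computed against the permutation null (one-sided in a given direction,
#' or on |t| for \code{"two_sided"}), converted to z-scores, and combined
#' as \code{sum(z)/sqrt(E)}. The omnibus p-value ranks the observed
#' combined Z against combined Z's recomputed for every permutation by the
#' same two-pass recipe.
#'
#' @param observed An \code{impact_map} or numeric vector of per-edge
#'   statistics.
#' @param null P x E matrix of per-edge statistics from permuted splits.
#' @param direction \code{"two_sided"}, or a per-edge (or scalar) vector of
#'   +/-1 giving the one-sided direction.
#' @param include Optional logical vector restricting the combined edge
#'   set; per-edge p/z are still computed for all edges.
#' @return An object of class \code{npc_result}: \code{Z}, \code{p},
#'   \code{edge_z}, \code{edge_p}, \code{perm_Z}, \code{perm_z},
#'   \code{n_perm}, \code{include}.
#' @export
npc_stouffer <- function(observed, null, direction = "two_sided",
                         include = NULL) {
  t_obs <- if (inherits(observed, "impact_map")) observed$t
           else as.numeric(observed)
  null <- as.matrix(null)
  E <- length(t_obs); P <- nrow(null)
  if (ncol(null) != E) stop("null ensemble edge count mismatch")
  if (P < 1L) stop("null ensemble is empty")
  if (is.null(include)) include <- rep(TRUE, E)
  if (identical(direction, "two_sided")) {
    s_obs <- abs(t_obs); s_null <- abs(null)
  } else {
    d <- rep_len(as.numeric(direction), E)
    s_obs <- d * t_obs
    s_null <- sweep(null, 2L, d, `*`)
  }
  rks <- .npc_ranks(s_obs, s_null)
  if (!any(include)) {
    warning("empty included-edge set; returning Z = 0, p = 1")
    return(structure(list(Z = 0, p = 1, edge_z = rks$z_obs,
                          edge_p = rks$p_obs, perm_Z = rep(0, P),
                          perm_z = rks$z_perm, n_perm = P,
                          include = include),
                     class = "npc_result"))
  }
  m <- sum(include)
  Z <- sum(rks$z_obs[include]) / sqrt(m)
  perm_Z <- rowSums(rks$z_perm[, include, drop = FALSE]) / sqrt(m)
  p <- (1 + sum(perm_Z >= Z)) / (1 + P)
  structure(list(Z = Z, p = p, edge_z = rks$z_obs, edge_p = rks$p_obs,
                 perm_Z = perm_Z, perm_z = rks$z_perm, n_perm = P,
                 include = include),
            class = "npc_result")
}

#' @export
print.npc_result <- function(x, ...) {
  cat(sprintf("<npc_result> Z = %.4g, p = %.4g (%d permutations, %d/%d edges combined)\n",
              x$Z, x$p, x$n_perm, sum(x$include), length(x$include)))
  invisible(x)
}

# One directional score: combine, over the sign-matched edge set, the
# one-sided edge z's in direction d. Because the edge set is selected by
# the observed impact signs, the permutation reference re-derives each
# permutation's own sign-matched set before combining ("treating that
# permutation as observed"); ranking permutations against the observed set
# alone would be anticonservative by construction.
.directional_npc <- function(t_obs, null_t, d, ungated) {
  s_obs <- d * t_obs
  s_null <- sweep(null_t, 2L, d, `*`)
  rks <- .npc_ranks(s_obs, s_null)
  set_obs <- ungated & s_obs > 0
  P <- nrow(null_t)
  if (!any(set_obs)) {
    warning("empty directional edge set; Z = 0, p = 1")
    return(list(Z = 0, p = 1, set = set_obs))
  }
  Z <- sum(rks$z_obs[set_obs]) / sqrt(sum(set_obs))
  mask <- (s_null > 0) & rep(ungated, each = P)
  m_j <- rowSums(mask)
  Z_j <- ifelse(m_j > 0, rowSums(rks$z_perm * mask) / sqrt(pmax(m_j, 1L)), 0)
  list(Z = Z, p = (1 + sum(Z_j >= Z)) / (1 + P), set = set_obs)
}

#' Motion overestimation and underestimation scores
#'
#' Edges with |trait-FC t| <= \code{gate} are ignored (the sign of the
#' trait-FC effect is too uncertain there). Among the remaining edges, the
#' overestimation score combines edges whose motion impact shares the sign
#' of the trait-FC effect (one-sided in that direction); the
#' underestimation score combines edges of opposite sign (one-sided
#' against the trait-FC direction). The two edge sets are disjoint. The
#' permutation p-values re-derive each permutation's own sign-matched edge
#' set, so the selection step is part of the null statistic.
#'
#' @param impact An \code{impact_map} (observed edgewise motion impact).
#' @param trait_fc_t Per-edge t-values of the trait-FC effect.
#' @param null P x E null ensemble of edgewise impact t-values.
#' @param gate t-threshold for trusting the trait-FC sign (default 2).
#' @return List with \code{over_z}, \code{over_p}, \code{under_z},
#'   \code{under_p}, and logical edge sets \code{over_set},
#'   \code{under_set}.
#' @export
directional_scores <- function(impact, trait_fc_t, null, gate = 2) {
  t_imp <- if (inherits(impact, "impact_map")) impact$t else as.numeric(impact)
  trait_fc_t <- as.numeric(trait_fc_t)
  if (length(trait_fc_t) != length(t_imp)) stop("trait_fc_t length mismatch")
  null <- as.matrix(null)
  ungated <- abs(trait_fc_t) > gate
  d <- sign(trait_fc_t)
  over <- .directional_npc(t_imp, null, d, ungated)
  under <- .directional_npc(t_imp, null, -d, ungated)
  list(over_z = over$Z, over_p = over$p, under_z = under$Z,
       under_p = under$p, over_set = over$set, under_set = under$set,
       gate = gate)
}

# normalize a dataset argument into list(participants, traits)
.as_dataset <- function(x) {
  if (inherits(x, "synthetic_cohort") || inherits(x, "fc_cohort")) {
    list(participants = x$participants, traits = x$traits)
  } else if (is.list(x) && all(vapply(x, inherits, TRUE, "parcel_ts"))) {
    list(participants = x, traits = NULL)
  } else {
    stop("dataset must be a cohort object or a list of parcel_ts")
  }
}

.resolve_column <- function(value, traits, what) {
  if (is.character(value) && length(value) == 1L) {
    if (is.null(traits) || !value %in% names(traits)) {
      stop(sprintf("%s column '%s' not found in the cohort trait table",
                   what, value))
    }
    traits[[value]]
  } else {
    as.numeric(value)
  }
}

#' Run the full split-half motion impact analysis
#'
#' Orchestrates the pipeline: FD-based split per participant, per-half edge
#' vectors and mean FD, across-participant motion residualization of each
#' half, trait regression on the residual differences, motion-blocks
#' permutation null, and non-parametric combining into omnibus,
#' overestimation, and underestimation motion impact scores. The trait-FC
#' effect used to gate the directional scores is computed on the full
#' (unsplit) edges with mean FD as a covariate.
#'
#' @param x A cohort object ([generate_cohort()], [read_cohort()]) or a
#'   named list of \code{parcel_ts}.
#' @param trait Trait column name (in the cohort's trait table) or a
#'   per-participant numeric vector.
#' @param covariates Optional: character vector of trait-table column
#'   names, or a per-participant numeric matrix/data frame.
#' @param n_perm Number of block permutations (default 1000).
#' @param alpha Significance level recorded with the result (default 0.05).
#' @param gate Trait-FC t-threshold for the directional scores (default 2).
#' @param seed Integer master seed; per-permutation seeds are derived from
#'   it, so results do not depend on how permutations are scheduled.
#' @return An object of class \code{motion_impact}; see Details.
#' @details The result contains \code{omnibus_z}/\code{omnibus_p} (two-
#'   sided edgewise combining), \code{over_z}/\code{over_p} and
#'   \code{under_z}/\code{under_p} (directional scores), \code{edge_z} and
#'   \code{edge_p} (per-edge two-sided permutation z/p), \code{impact}
#'   (edgewise beta/t/df), \code{trait_fc} (trait-FC effect used for
#'   gating), \code{null_t} (P x E permutation ensemble), \code{perm_z}
#'   (per-permutation two-sided edge z's, for node-level recombination),
#'   and the configuration (n_perm, alpha, gate, seed).
#' @export
run_shaman <- function(x, trait, covariates = NULL, n_perm = 1000,
                       alpha = 0.05, gate = 2, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  ds <- .as_dataset(x)
  parts <- ds$participants
  n <- length(parts)
  if (n < 3L) stop("need at least 3 participants")
  trait_v <- .resolve_column(trait, ds$traits, "trait")
  if (length(trait_v) != n) stop("trait length does not match participants")
  cov_m <- NULL
  if (!is.null(covariates)) {
    cov_m <- if (is.character(covariates)) {
      as.matrix(ds$traits[covariates])
    } else {
      as.matrix(covariates)
    }
    if (nrow(cov_m) != n) stop("covariate rows do not match participants")
  }
  nn <- unique(vapply(parts, n_nodes, 0L))
  if (length(nn) != 1L) stop("participants differ in node count")
  E <- n_edges(nn)

  # per-participant sufficient statistics: per-motion-block packed
  # crossproducts (permutations reassign whole blocks, so each half's
  # covariance is a sum of cached block matrices)
  Xs <- lapply(parts, `[[`, "data")
  Stots <- lapply(Xs, tcrossprod)
  stots <- lapply(Xs, rowSums)
  fds <- lapply(parts, `[[`, "fd")
  fdsum <- vapply(fds, sum, 0)
  nf <- vapply(Xs, ncol, 0L)
  assignments <- lapply(parts, function(ts) {
    assign_halves(ts$fd, ts$run_starts)
  })
  blk <- lapply(assignments, `[[`, "blocks")
  cache <- lapply(seq_len(n), function(i) {
    b <- blk[[i]]
    bs <- .block_stats_cpp(Xs[[i]], b$start, b$end)
    bs$len <- b$end - b$start + 1L
    bs$fdblk <- vapply(seq_len(nrow(b)),
                       function(k) sum(fds[[i]][b$start[k]:b$end[k]]), 0)
    bs
  })
  packSs <- lapply(cache, `[[`, "packS")
  sblks <- lapply(cache, `[[`, "sblk")
  packTots <- lapply(cache, `[[`, "packTot")
  sTots <- lapply(cache, `[[`, "sTot")
  lens <- lapply(cache, `[[`, "len")
  fdblks <- lapply(cache, `[[`, "fdblk")
  fdTots <- fdsum

  Xd <- cbind(1, trait_v)
  if (!is.null(cov_m)) Xd <- cbind(Xd, cov_m)
  # edge-major (E x n) buffers reused across permutation batches: one pass
  # over each participant's block cache serves a whole batch
  batchK <- max(1L, min(16L, as.integer(3e8 / (2 * 8 * as.numeric(E) * n))))
  Yls <- lapply(seq_len(batchK), function(k) matrix(0, E, n))
  Yhs <- lapply(seq_len(batchK), function(k) matrix(0, E, n))
  FdLow <- matrix(0, n, batchK)
  FdHigh <- matrix(0, n, batchK)

  obs_lows <- lapply(blk, function(b) which(b$label == "low"))
  .fill_perm_edges_batch_cpp(packSs, sblks, packTots, sTots, lens, fdblks,
                             fdTots, list(obs_lows), Yls[1L], Yhs[1L],
                             FdLow, FdHigh)
  obs <- .impact_t(.residual_difference_mat(t(Yls[[1L]]), t(Yhs[[1L]]),
                                            FdLow[, 1L], FdHigh[, 1L]),
                   trait_v, cov_m)

  # trait-FC effect on the full edges, FC ~ trait + mean FD (+ covariates)
  z_full <- t(vapply(seq_len(n), function(i) {
    .edges_from_stats_cpp(Stots[[i]], stots[[i]], nf[i])
  }, numeric(E)))
  mfd <- fdsum / nf
  tfc <- trait_fc(z_full, trait_v, cbind(FD = mfd, cov_m))

  # permutation null: per-permutation seeds derived from the master seed;
  # within a permutation, participants are permuted in a fixed order
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  null_t <- matrix(0, n_perm, E)
  pidx <- 1L
  while (pidx <= n_perm) {
    kk <- min(batchK, n_perm - pidx + 1L)
    lows_batch <- vector("list", kk)
    for (k in seq_len(kk)) {
      set.seed(perm_seeds[pidx + k - 1L])
      lows_batch[[k]] <- lapply(seq_len(n), function(i) {
        .permute_block_ids(lens[[i]], nf[i])
      })
    }
    .fill_perm_edges_batch_cpp(packSs, sblks, packTots, sTots, lens, fdblks,
                               fdTots, lows_batch, Yls[seq_len(kk)],
                               Yhs[seq_len(kk)], FdLow, FdHigh)
    for (k in seq_len(kk)) {
      null_t[pidx + k - 1L, ] <- .impact_row_cpp(Yls[[k]], Yhs[[k]],
                                                 FdLow[, k], FdHigh[, k], Xd)
    }
    pidx <- pidx + kk
  }

  omni <- npc_stouffer(obs, null_t, direction = "two_sided")
  dir <- directional_scores(obs, tfc$t, null_t, gate = gate)

  structure(list(
    omnibus_z = omni$Z, omnibus_p = omni$p,
    over_z = dir$over_z, over_p = dir$over_p,
    under_z = dir$under_z, under_p = dir$under_p,
    edge_z = omni$edge_z, edge_p = omni$edge_p,
    perm_z = omni$perm_z,
    impact = obs, trait_fc = tfc,
    over_set = dir$over_set, under_set = dir$under_set,
    null_t = null_t, n_nodes = nn, n_perm = n_perm,
    alpha = alpha, gate = gate, seed = seed,
    participant_ids = names(parts)
  ), class = "motion_impact")
}

#' @export
print.motion_impact <- function(x, ...) {
  cat(sprintf("<motion_impact> %d nodes, %d edges, %d permutations (seed %d)\n",
              x$n_nodes, length(x$edge_z), x$n_perm, x$seed))
  cat(sprintf("  omnibus Z = %.3f (p = %.4g)\n", x$omnibus_z, x$omnibus_p))
  cat(sprintf("  overestimation Z = %.3f (p = %.4g), %d edges\n",
              x$over_z, x$over_p, sum(x$over_set)))
  cat(sprintf("  underestimation Z = %.3f (p = %.4g), %d edges\n",
              x$under_z, x$under_p, sum(x$under_set)))
  invisible(x)
}

#' Detection rate of the motion impact score across sample sizes
#'
#' For each sample size, simulates (or resamples) cohorts with a
#' user-supplied generator and reports the fraction of runs whose omnibus
#' motion impact score is significant at \code{alpha}.
#'
#' @param generator Function \code{(n, seed)} returning a cohort object
#'   whose trait table has a \code{trait} column.
#' @param sizes Integer vector of sample sizes.
#' @param reps Replicates per size (default 20).
#' @param n_perm Permutations per run (default 99).
#' @param alpha Significance level (default 0.05).
#' @param seed Master seed.
#' @return Data frame with \code{n}, \code{detections}, \code{reps},
#'   \code{rate}.
#' @export
power_analysis <- function(generator, sizes, reps = 20, n_perm = 99,
                           alpha = 0.05, seed = 1L) {
  stopifnot(is.function(generator), all(sizes > 0), reps >= 1)
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             2L * length(sizes) * reps),
                  nrow = 2L)
  k <- 0L
  out <- lapply(sizes, function(nsz) {
    det <- 0L
    for (r in seq_len(reps)) {
      k <<- k + 1L
      cohort <- generator(nsz, seeds[1L, k])
      res <- run_shaman(cohort, trait = "trait", n_perm = n_perm,
                        alpha = alpha, seed = seeds[2L, k])
      det <- det + (res$omnibus_p < alpha)
    }
    data.frame(n = nsz, detections = det, reps = reps, rate = det / reps)
  })
  do.call(rbind, out)
}
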