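#' Edgewise trait-FC effect matrix
#'
#' Massively univariate OLS of Fisher-z edges on a participant trait plus
#' covariates (conventionally mean FD): one regression per edge, returning
#' the trait coefficient, its t-value, and the t-derived effect-size
#' correlation \code{r = t / sqrt(t^2 + df)} (the partial correlation of
#' trait and edge given the covariates).
#'
#' @param edge_table Participant x edge matrix of Fisher-z values.
#' @param trait Per-participant trait values.
#' @param covariates Optional per-participant covariate matrix/data frame
#'   (e.g. mean FD).
#' @param predictor Name recorded for the predictor (default "trait").
#' @return An object of class \code{effect_matrix}: \code{beta}, \code{t},
#'   \code{df}, \code{r_effect}, \code{predictor}, \code{covariates},
#'   \code{model}.
#' @export
trait_fc <- function(edge_table, trait, covariates = NULL,
                     predictor = "trait") {
  edge_table <- as.matrix(edge_table)
  trait <- as.numeric(trait)
  if (nrow(edge_table) != length(trait)) stop("participants do not match")
  if (anyNA(edge_table) || anyNA(trait) ||
      (!is.null(covariates) && anyNA(covariates))) {
    stop("missing values must be excluded upstream (listwise)")
  }
  fit <- .impact_t(edge_table, trait, covariates)
  cov_names <- if (is.null(covariates)) character(0) else {
    cn <- colnames(as.matrix(covariates))
    if (is.null(cn)) paste0("cov", seq_len(ncol(as.matrix(covariates)))) else cn
  }
  structure(list(
    beta = fit$beta, t = fit$t, df = fit$df,
    r_effect = fit$t / sqrt(fit$t^2 + fit$df),
    predictor = predictor, covariates = cov_names,
    model = paste("FC ~", paste(c(predictor, cov_names), collapse = " + "))
  ), class = "effect_matrix")
}

#' Edgewise motion-FC effect matrix
#'
#' Per-edge OLS of Fisher-z edges on participant mean FD alone
#' (\code{FC ~ 1 + FD}); beta has units of Fisher-z change per mm FD.
#'
#' @param edge_table Participant x edge matrix of Fisher-z values.
#' @param mean_fd Per-participant mean FD (mm); must vary.
#' @return An \code{effect_matrix} (see [trait_fc()]).
#' @export
motion_fc <- function(edge_table, mean_fd) {
  mean_fd <- as.numeric(mean_fd)
  if (stats::var(mean_fd) == 0) stop("mean FD is constant across participants")
  trait_fc(edge_table, mean_fd, predictor = "FD")
}

#' @export
print.effect_matrix <- function(x, ...) {
  cat(sprintf("<effect_matrix> %s: %d edges, df = %d, max |r| = %.4g\n",
              x$model, length(x$t), x$df, max(abs(x$r_effect))))
  invisible(x)
}

#' Percentile of the absolute effect-size distribution
#'
#' @param effect An \code{effect_matrix} or numeric vector of effect-size
#'   correlations.
#' @param q Percentile in (0, 100]; default 98.
#' @return The q-th percentile of |r| across edges (linear interpolation
#'   between order statistics).
#' @export
effect_percentile <- function(effect, q = 98) {
  r <- if (inherits(effect, "effect_matrix")) effect$r_effect
       else as.numeric(effect)
  if (length(r) == 0L) stop("no edges")
  if (q <= 0 || q > 100) stop("q must be in (0, 100]")
  unname(stats::quantile(abs(r), q / 100, type = 7))
}

#' Correlation of a trait with head motion
#'
#' Pearson and Spearman correlations of a trait with participant mean FD,
#' with two-sided p-values (exact Spearman permutation distribution below
#' n = 10, t-approximation otherwise).
#'
#' @param trait,mean_fd Per-participant numeric vectors.
#' @return List with \code{pearson_r}, \code{pearson_p},
#'   \code{spearman_rho}, \code{spearman_p}, \code{n}.
#' @export
trait_fd_corr <- function(trait, mean_fd) {
  trait <- as.numeric(trait); mean_fd <- as.numeric(mean_fd)
  n <- length(trait)
  if (n < 3L) stop("need at least 3 participants")
  if (stats::var(trait) == 0 || stats::var(mean_fd) == 0) {
    stop("constant input")
  }
  pe <- stats::cor.test(trait, mean_fd, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(trait, mean_fd, method = "spearman", exact = n < 10)
  )
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value, n = n)
}

#' Edge-for-edge similarity of two effect or connectivity matrices
#'
#' @param a,b \code{effect_matrix} objects, \code{edge_vector} objects, or
#'   numeric edge vectors in the same ordering.
#' @return List with \code{pearson_r} and \code{spearman_rho}.
#' @export
matrix_similarity <- function(a, b) {
  vec <- function(x) {
    if (inherits(x, "effect_matrix")) x$beta
    else if (inherits(x, "edge_vector")) x$z
    else as.numeric(x)
  }
  va <- vec(a); vb <- vec(b)
  if (length(va) != length(vb)) stop("edge vectors differ in length (ordering mismatch?)")
  list(pearson_r = stats::cor(va, vb),
       spearman_rho = stats::cor(va, vb, method = "spearman"))
}

#' Relative reduction in motion-related signal variance
#'
#' @param rho2_before,rho2_after Proportions of between-participant signal
#'   variance explained by motion (squared Spearman rho) before and after
#'   denoising.
#' @return \code{1 - rho2_after / rho2_before}.
#' @export
relative_reduction <- function(rho2_before, rho2_after) {
  if (rho2_before <= 0) stop("reduction undefined when rho_before is 0")
  1 - rho2_after / rho2_before
}

#' Denoising performance via the log-log variance-vs-motion model
#'
#' Rank-based version of the log-log regression of per-participant mean
#' parcel signal variance on mean FD: Spearman's rho of log(variance) vs
#' log(mean FD) before and after denoising, the implied proportions of
#' variance explained (rho squared), and the relative reduction
#' \code{1 - (rho_after/rho_before)^2}. Spearman's rho is invariant to the
#' log (any strictly monotone) transform; the logs are kept for fidelity
#' to the model and therefore require positive inputs.
#'
#' @param var_before,var_after Per-participant mean node signal variance
#'   before/after denoising (positive).
#' @param mean_fd Per-participant mean FD (positive, mm).
#' @return List with \code{rho_before}, \code{rho_after},
#'   \code{var_explained_before}, \code{var_explained_after},
#'   \code{relative_reduction}.
#' @export
variance_reduction <- function(var_before, var_after, mean_fd) {
  if (any(var_before <= 0) || any(var_after <= 0) || any(mean_fd <= 0)) {
    stop("variances and FD must be positive (logs must be defined)")
  }
  rb <- stats::cor(log(var_before), log(mean_fd), method = "spearman")
  ra <- stats::cor(log(var_after), log(mean_fd), method = "spearman")
  if (rb == 0) stop("reduction undefined when rho_before is 0")
  list(rho_before = rb, rho_after = ra,
       var_explained_before = rb^2, var_explained_after = ra^2,
       relative_reduction = relative_reduction(rb^2, ra^2))
}
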