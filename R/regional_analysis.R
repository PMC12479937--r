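#' Node-level motion impact scores
#'
#' Stouffer combination of the per-edge z-scores over the edges incident to
#' each node. If the per-permutation edge z matrix is supplied, node-level
#' permutation p-values are obtained by recombining the same null ensemble
#' over each node's edge set.
#'
#' @param edge_z Per-edge z-scores (e.g. \code{$edge_z} of a
#'   \code{motion_impact}), or a \code{motion_impact} object (in which case
#'   \code{perm_z} and \code{n_nodes} are taken from it).
#' @param n_nodes Number of nodes (ignored when a \code{motion_impact} is
#'   given).
#' @param perm_z Optional P x E matrix of per-permutation edge z-scores.
#' @param keep_nodes Optional integer vector of nodes still in play; edges
#'   touching excluded nodes are dropped. Nodes outside this set get
#'   \code{NA} scores.
#' @return Data frame with \code{node}, \code{n_edges}, \code{z}, \code{p}
#'   (NA when \code{perm_z} is absent or a node has no remaining edges).
#' @export
node_scores <- function(edge_z, n_nodes = NULL, perm_z = NULL,
                        keep_nodes = NULL) {
  if (inherits(edge_z, "motion_impact")) {
    x <- edge_z
    if (is.null(perm_z)) perm_z <- x$perm_z
    n_nodes <- x$n_nodes
    edge_z <- x$edge_z
  }
  if (is.null(n_nodes)) stop("n_nodes is required")
  pairs <- edge_pairs(n_nodes)
  if (length(edge_z) != nrow(pairs)) stop("edge_z length does not match n_nodes")
  if (is.null(keep_nodes)) keep_nodes <- seq_len(n_nodes)
  active <- pairs[, 1L] %in% keep_nodes & pairs[, 2L] %in% keep_nodes
  z <- rep(NA_real_, n_nodes)
  p <- rep(NA_real_, n_nodes)
  deg <- integer(n_nodes)
  for (k in keep_nodes) {
    idx <- which(active & (pairs[, 1L] == k | pairs[, 2L] == k))
    deg[k] <- length(idx)
    if (length(idx) == 0L) next        # isolated node: score undefined
    z[k] <- stouffer_z(edge_z[idx])
    if (!is.null(perm_z)) {
      zp <- rowSums(perm_z[, idx, drop = FALSE]) / sqrt(length(idx))
      p[k] <- (1 + sum(zp >= z[k])) / (1 + nrow(perm_z))
    }
  }
  data.frame(node = seq_len(n_nodes), n_edges = deg, z = z, p = p)
}

#' Iterative node exclusion until the omnibus score loses significance
#'
#' Starting from all nodes, repeatedly computes the omnibus motion impact
#' p-value over the remaining edges (recombining the same permutation
#' ensemble restricted to those edges), excludes the node with the largest
#' node-level score (ties: lowest index), and stops once the omnibus p
#' exceeds \code{alpha} or no nodes remain. The number of exclusions
#' performed counts the regions contributing to the motion impact.
#'
#' @param edge_z Per-edge z-scores or a \code{motion_impact} object.
#' @param perm_z P x E per-permutation edge z matrix (taken from the
#'   \code{motion_impact} when one is given).
#' @param n_nodes Number of nodes (likewise).
#' @param alpha Significance level (default 0.05).
#' @return List with \code{order} (excluded node ids, in order),
#'   \code{omnibus_p_path} (omnibus p before each exclusion, starting with
#'   the all-node p), and \code{n_contributing}.
#' @export
exclusion_trace <- function(edge_z, perm_z = NULL, n_nodes = NULL,
                            alpha = 0.05) {
  if (inherits(edge_z, "motion_impact")) {
    x <- edge_z
    perm_z <- x$perm_z; n_nodes <- x$n_nodes; edge_z <- x$edge_z
  }
  if (is.null(perm_z) || is.null(n_nodes)) {
    stop("perm_z and n_nodes are required")
  }
  pairs <- edge_pairs(n_nodes)
  P <- nrow(perm_z)
  keep <- seq_len(n_nodes)
  order_out <- integer(0)
  p_path <- numeric(0)
  repeat {
    active <- which(pairs[, 1L] %in% keep & pairs[, 2L] %in% keep)
    if (length(active) == 0L) {
      # no edges left: remaining nodes are excluded trivially
      order_out <- c(order_out, keep)
      break
    }
    Z <- stouffer_z(edge_z[active])
    Zp <- rowSums(perm_z[, active, drop = FALSE]) / sqrt(length(active))
    p <- (1 + sum(Zp >= Z)) / (1 + P)
    p_path <- c(p_path, p)
    if (p > alpha) break
    ns <- node_scores(edge_z, n_nodes, keep_nodes = keep)
    zk <- ns$z[keep]
    worst <- keep[which(zk == max(zk, na.rm = TRUE))][1L]  # ties: lowest id
    order_out <- c(order_out, worst)
    keep <- setdiff(keep, worst)
  }
  list(order = order_out, omnibus_p_path = p_path,
       n_contributing = length(order_out))
}

#' Per-node root-mean-square projection of an effect matrix
#'
#' @param effect Symmetric node x node matrix (the diagonal is ignored).
#' @return Per-node \code{sqrt(mean of squared off-diagonal row entries)}.
#' @export
parcel_rms <- function(effect) {
  effect <- as.matrix(effect)
  n <- nrow(effect)
  if (n < 2L || ncol(effect) != n) stop("need a symmetric matrix with >= 2 nodes")
  sqrt((rowSums(effect^2) - diag(effect)^2) / (n - 1))
}
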