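#' Parcellated BOLD timeseries with aligned framewise displacement
#'
#' Container for one participant's (possibly concatenated) resting-state
#' timeseries: a node x frame matrix of parcel-averaged BOLD, the per-frame
#' framewise displacement (FD, mm) used for motion splitting and censoring,
#' the frame indices at which scan runs begin, and the repetition time.
#'
#' @param data Numeric matrix, nodes as rows, frames as columns.
#' @param fd Numeric vector of per-frame framewise displacement in mm;
#'   length must equal the number of frames.
#' @param run_starts Integer vector of 1-based frame indices where runs
#'   begin; strictly increasing, first element 1. Default: a single run.
#' @param tr Repetition time in seconds (default 0.8).
#' @return An object of class \code{parcel_ts}.
#' @export
parcel_ts <- function(data, fd, run_starts = 1L, tr = 0.8) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  fd <- as.numeric(fd)
  run_starts <- as.integer(run_starts)
  if (!all(is.finite(data))) stop("timeseries contains non-finite values")
  if (!all(is.finite(fd))) stop("fd contains non-finite values")
  if (any(fd < 0)) stop("fd must be non-negative")
  if (length(fd) != ncol(data)) {
    stop(sprintf("fd length (%d) does not match frame count (%d)",
                 length(fd), ncol(data)))
  }
  if (length(run_starts) < 1L || run_starts[1L] != 1L ||
      is.unsorted(run_starts, strictly = TRUE) ||
      any(run_starts > ncol(data))) {
    stop("run_starts must be strictly increasing 1-based indices starting at 1")
  }
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stop("tr must be > 0")
  structure(list(data = data, fd = fd, run_starts = run_starts, tr = tr),
            class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> %d nodes x %d frames, %d run(s), TR %.3g s, mean FD %.4g mm\n",
              nrow(x$data), ncol(x$data), length(x$run_starts), x$tr,
              mean(x$fd)))
  invisible(x)
}

n_frames <- function(ts) ncol(ts$data)
n_nodes <- function(ts) nrow(ts$data)

#' Node pairs in the fixed edge ordering
#'
#' The package stores edge vectors in row-major upper-triangle order: all
#' pairs (i, j) with i < j, sorted by i ascending then j ascending.
#'
#' @param n_nodes Number of nodes.
#' @return Two-column integer matrix (\code{i}, \code{j}) of 1-based node
#'   indices, one row per edge.
#' @export
edge_pairs <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 2L) stop("need at least 2 nodes")
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- sequence((n_nodes - 1L):1L, from = 2:n_nodes)
  cbind(i = i, j = j)
}

#' Number of edges for a node count
#' @param n_nodes Number of nodes.
#' @return \code{n_nodes * (n_nodes - 1) / 2}.
#' @export
n_edges <- function(n_nodes) as.integer(n_nodes * (n_nodes - 1) / 2)

# Extract the row-major upper triangle of a symmetric matrix as a vector.
# Column-major traversal of the lower triangle yields exactly this order.
upper_vec <- function(m) m[lower.tri(m)]

#' Reconstruct a symmetric node x node matrix from an edge vector
#'
#' @param z Edge vector in the package ordering (see [edge_pairs()]).
#' @param n_nodes Number of nodes.
#' @param diag Value placed on the diagonal (default 0).
#' @return Symmetric \code{n_nodes x n_nodes} matrix.
#' @export
edges_to_matrix <- function(z, n_nodes, diag = 0) {
  if (length(z) != n_edges(n_nodes)) {
    stop("edge vector length does not match node count")
  }
  m <- matrix(0, n_nodes, n_nodes)
  m[lower.tri(m)] <- z
  m <- m + t(m)
  diag(m) <- diag
  m
}

#' Fisher-z edge vector of a timeseries
#'
#' Pairwise Pearson correlations between node timeseries, clipped to
#' +/-(1 - 1e-7) and atanh (Fisher z) transformed, in the fixed row-major
#' upper-triangle ordering.
#'
#' @param x A \code{parcel_ts} or a node x frame numeric matrix.
#' @return An object of class \code{edge_vector}: list with \code{z}
#'   (length \code{n_nodes*(n_nodes-1)/2}) and \code{n_nodes}.
#' @export
fc_edges <- function(x) {
  m <- if (inherits(x, "parcel_ts")) x$data else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 nodes")
  if (ncol(m) < 3L) stop("need at least 3 frames to estimate correlations")
  v <- apply(m, 1L, stats::var)
  if (any(v == 0)) {
    stop(sprintf("zero-variance node(s): %s",
                 paste(which(v == 0), collapse = ", ")))
  }
  r <- stats::cor(t(m))
  z <- atanh(clip_r(upper_vec(r)))
  structure(list(z = z, n_nodes = nrow(m)), class = "edge_vector")
}

# clip correlations away from +/-1 so atanh stays finite
clip_r <- function(r, eps = 1e-7) pmin(pmax(r, -(1 - eps)), 1 - eps)

#' @export
print.edge_vector <- function(x, ...) {
  cat(sprintf("<edge_vector> %d nodes, %d Fisher-z edges (range %.3g .. %.3g)\n",
              x$n_nodes, length(x$z), min(x$z), max(x$z)))
  invisible(x)
}

#' Censor high-motion frames
#'
#' Removes frames whose FD is at or above \code{threshold} (a frame is kept
#' iff \code{fd < threshold}, strict). Run boundaries are remapped to the
#' surviving frames.
#'
#' @param ts A \code{parcel_ts}.
#' @param threshold FD cutoff in mm; \code{Inf} disables censoring.
#' @return List with \code{ts} (censored \code{parcel_ts}) and \code{mask}
#'   (list with per-frame logical \code{keep}, \code{threshold},
#'   \code{n_kept}).
#' @export
censor_frames <- function(ts, threshold) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a positive number (or Inf for no censoring)")
  }
  keep <- ts$fd < threshold
  mask <- list(keep = keep, threshold = threshold, n_kept = sum(keep))
  if (!any(keep)) stop("all frames censored: empty timeseries")
  # new index of each run start = kept frames strictly before it
  rs <- vapply(ts$run_starts,
               function(s) sum(keep[seq_len(s - 1L)]) + 1L, integer(1))
  rs <- unique(pmin(rs, sum(keep)))
  out <- parcel_ts(ts$data[, keep, drop = FALSE], ts$fd[keep],
                   run_starts = rs, tr = ts$tr)
  list(ts = out, mask = mask)
}

#' Minimum-duration inclusion rule
#'
#' @param ts A \code{parcel_ts}.
#' @param min_minutes Minimum duration in minutes (default 8).
#' @return \code{TRUE} iff \code{n_frames * tr >= min_minutes * 60}.
#' @export
meets_minimum <- function(ts, min_minutes = 8) {
  stopifnot(inherits(ts, "parcel_ts"))
  n_frames(ts) * ts$tr >= min_minutes * 60
}

#' Frames required for a given duration
#'
#' @param min_minutes Duration in minutes (default 8).
#' @param tr Repetition time in seconds (default 0.8).
#' @return Smallest frame count whose duration is at least
#'   \code{min_minutes} (600 at the defaults).
#' @export
min_frames <- function(min_minutes = 8, tr = 0.8) {
  as.integer(ceiling(min_minutes * 60 / tr))
}

#' Clamp a timeseries to its earliest frames
#'
#' Retains the first \code{max_frames} frames in temporal order; shorter
#' inputs pass through unchanged. Used to equalize data quantity across
#' participants (600 frames = 8 minutes at TR 0.8 s).
#'
#' @param ts A \code{parcel_ts}.
#' @param max_frames Maximum number of frames to keep (default 600).
#' @return A \code{parcel_ts}.
#' @export
clamp_frames <- function(ts, max_frames = 600) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (max_frames < 1) stop("max_frames must be >= 1")
  if (n_frames(ts) <= max_frames) return(ts)
  keep <- seq_len(max_frames)
  rs <- ts$run_starts[ts$run_starts <= max_frames]
  parcel_ts(ts$data[, keep, drop = FALSE], ts$fd[keep],
            run_starts = rs, tr = ts$tr)
}

#' Mean framewise displacement
#' @param ts A \code{parcel_ts} (or numeric FD vector).
#' @return Arithmetic mean FD in mm.
#' @export
mean_fd <- function(ts) {
  fd <- if (inherits(ts, "parcel_ts")) ts$fd else as.numeric(ts)
  if (length(fd) == 0L) stop("empty fd")
  mean(fd)
}
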