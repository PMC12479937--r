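#' Split frames into low- and high-motion halves
#'
#' Frames are stably sorted by FD (ties broken by temporal order); the
#' lowest \code{ceiling(n/2)} frames are labeled \code{"low"} and the rest
#' \code{"high"}. Contiguous same-label frame runs, additionally broken at
#' scan-run boundaries, form the motion blocks used by the permutation
#' scheme.
#'
#' @param fd Numeric vector of per-frame FD (mm).
#' @param run_starts 1-based frame indices where scan runs begin.
#' @return An object of class \code{split_assignment}: per-frame
#'   \code{label} ("low"/"high"), a \code{blocks} data frame (1-based
#'   inclusive \code{start}, \code{end}, \code{label}), and a
#'   \code{permuted} flag.
#' @export
assign_halves <- function(fd, run_starts = 1L) {
  fd <- as.numeric(fd)
  n <- length(fd)
  if (n < 2L) stop("need at least 2 frames to split")
  ord <- order(fd)                      # stable: ties keep temporal order
  n_low <- as.integer(ceiling(n / 2))
  label <- rep("high", n)
  label[ord[seq_len(n_low)]] <- "low"
  new_split_assignment(label, run_starts, permuted = FALSE)
}

new_split_assignment <- function(label, run_starts, permuted) {
  n <- length(label)
  run_starts <- as.integer(run_starts)
  # block boundary wherever the label changes or a new run begins
  newblk <- c(TRUE, label[-1L] != label[-n])
  newblk[run_starts] <- TRUE
  id <- cumsum(newblk)
  start <- which(newblk)
  end <- c(start[-1L] - 1L, n)
  blocks <- data.frame(start = start, end = end, label = label[start],
                       stringsAsFactors = FALSE)
  structure(list(label = label, blocks = blocks, run_starts = run_starts,
                 permuted = permuted),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> %d frames (%d low / %d high), %d blocks%s\n",
              length(x$label), sum(x$label == "low"),
              sum(x$label == "high"), nrow(x$blocks),
              if (x$permuted) ", permuted" else ""))
  invisible(x)
}

#' Motion-blocks permutation of a split
#'
#' Reassigns whole motion blocks (not individual frames) to the two halves,
#' preserving the temporal dependence structure of the un-permuted split.
#' Blocks are shuffled uniformly and assigned to half A until A's frame
#' count first reaches half the frames; the remainder go to half B. A fair
#' coin decides whether A is the "low" or "high" half. The multiset of
#' block lengths is unchanged.
#'
#' @param assignment A \code{split_assignment} with at least 2 blocks.
#' @param seed Optional integer seed for reproducibility.
#' @return A permuted \code{split_assignment}.
#' @export
permute_assignment <- function(assignment, seed = NULL) {
  stopifnot(inherits(assignment, "split_assignment"))
  blocks <- assignment$blocks
  if (nrow(blocks) < 2L) {
    stop("cannot permute a single-block assignment; ",
         "more frames or finer FD variation are needed")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(assignment$label)
  low <- .permute_blocks(blocks$start, blocks$end, n)
  label <- rep("high", n)
  label[low] <- "low"
  new_split_assignment(label, assignment$run_starts, permuted = TRUE)
}

# Lean core of the motion-blocks permutation: returns the 1-based ids of
# the blocks forming the low half. Consumes the RNG (a block shuffle, then
# a fair coin); callers seed as needed.
.permute_block_ids <- function(len, n, min_frames = 3L) {
  B <- length(len)
  for (try in 1:100) {
    ord <- sample.int(B)
    cum <- cumsum(len[ord])
    k <- which(cum >= n / 2)[1L]        # A filled once it holds >= n/2 frames
    in_a <- if (k == B) {
      # the final block alone pushed A over n/2: keep it as A so that B
      # (all earlier blocks) stays non-empty
      ord[B]
    } else {
      ord[seq_len(k)]
    }
    n_a <- sum(len[in_a])
    # a dominant block can leave one half too short to correlate; redraw
    if (n_a >= min_frames && n - n_a >= min_frames) {
      return(if (stats::runif(1) < 0.5) in_a else seq_len(B)[-in_a])
    }
  }
  stop("could not find a block permutation leaving >= ", min_frames,
       " frames per half; more frames or finer FD variation are needed")
}

# Same permutation expressed as low-half frame indices. Any non-empty
# split is a legal assignment here; downstream correlation stages impose
# their own minimum-frame requirements.
.permute_blocks <- function(start, end, n) {
  ids <- .permute_block_ids(end - start + 1L, n, min_frames = 1L)
  sort(sequence(end[ids] - start[ids] + 1L, from = start[ids]))
}

#' Per-half edge vectors and motion summaries
#'
#' Gathers each half's frames (temporal order preserved), computes the
#' Fisher-z edge vector of each half, and the per-half mean FD.
#'
#' @param ts A \code{parcel_ts}.
#' @param assignment A \code{split_assignment} for the same frames.
#' @return An object of class \code{half_summary}: \code{edges_low},
#'   \code{edges_high} (edge vectors), \code{fd_low}, \code{fd_high}
#'   (mean FD, mm), \code{n_low}, \code{n_high}.
#' @export
summarize_half <- function(ts, assignment) {
  stopifnot(inherits(ts, "parcel_ts"), inherits(assignment, "split_assignment"))
  if (length(assignment$label) != n_frames(ts)) {
    stop("assignment length does not match frame count")
  }
  low <- assignment$label == "low"
  if (sum(low) < 3L || sum(!low) < 3L) {
    stop("each half needs at least 3 frames")
  }
  structure(list(
    edges_low = fc_edges(ts$data[, low, drop = FALSE]),
    edges_high = fc_edges(ts$data[, !low, drop = FALSE]),
    fd_low = mean(ts$fd[low]),
    fd_high = mean(ts$fd[!low]),
    n_low = sum(low),
    n_high = sum(!low)
  ), class = "half_summary")
}

#' @export
print.half_summary <- function(x, ...) {
  cat(sprintf("<half_summary> low: %d frames (mean FD %.4g), high: %d frames (mean FD %.4g)\n",
              x$n_low, x$fd_low, x$n_high, x$fd_high))
  invisible(x)
}
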