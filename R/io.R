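#' Assemble a cohort from in-memory participants
#'
#' @param participants Named list of \code{parcel_ts}.
#' @param traits Data frame with an \code{id} column matching participant
#'   names, plus trait/covariate columns.
#' @return An object of class \code{fc_cohort}.
#' @export
fc_cohort <- function(participants, traits = NULL) {
  if (is.null(names(participants)) || anyDuplicated(names(participants))) {
    stop("participants must be uniquely named")
  }
  stopifnot(all(vapply(participants, inherits, TRUE, "parcel_ts")))
  nn <- unique(vapply(participants, n_nodes, 0L))
  if (length(nn) != 1L) stop("participants differ in node count")
  if (!is.null(traits)) {
    if (!"id" %in% names(traits)) stop("trait table needs an 'id' column")
    traits <- traits[match(names(participants), traits$id), , drop = FALSE]
  }
  structure(list(participants = participants, traits = traits),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf("<fc_cohort> %d participants, %d nodes\n",
              length(x$participants), n_nodes(x$participants[[1]])))
  invisible(x)
}

#' Write a cohort to delimited-text files
#'
#' One nodes x frames TSV and one single-column FD file per participant, a
#' trait CSV, and a JSON manifest (participant ids, file paths, 0-based run
#' starts, TR, and - for simulated cohorts - the full generation config
#' including seed and applied positive-definiteness shrinkage).
#'
#' @param cohort An \code{fc_cohort} or \code{synthetic_cohort}.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  parts <- cohort$participants
  entries <- lapply(names(parts), function(id) {
    ts <- parts[[id]]
    ts_file <- paste0(id, "_timeseries.tsv")
    fd_file <- paste0(id, "_fd.tsv")
    utils::write.table(format(ts$data, digits = 17, trim = TRUE),
                       file.path(dir, ts_file), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    writeLines(format(ts$fd, digits = 17, trim = TRUE),
               file.path(dir, fd_file))
    list(id = id, timeseries = ts_file, fd = fd_file,
         run_starts = ts$run_starts - 1L, tr = ts$tr)
  })
  if (!is.null(cohort$traits)) {
    utils::write.csv(cohort$traits, file.path(dir, "traits.csv"),
                     row.names = FALSE)
  }
  manifest <- list(participants = entries,
                   trait_table = if (is.null(cohort$traits)) NULL else "traits.csv",
                   config = cohort$config)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a cohort from a manifest
#'
#' Validates that every referenced file exists and parses, that FD length
#' matches the frame count (errors name the offending participant), and
#' applies listwise exclusion (with a warning) for participants missing
#' from the trait table or with missing trait values.
#'
#' @param manifest Path to a \code{manifest.json} written by
#'   [write_cohort()], or the directory containing it.
#' @return An \code{fc_cohort}.
#' @export
read_cohort <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.json")
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  dir <- dirname(manifest)
  parts <- list()
  for (e in m$participants) {
    tsp <- file.path(dir, e$timeseries)
    fdp <- file.path(dir, e$fd)
    for (f in c(tsp, fdp)) if (!file.exists(f)) {
      stop(sprintf("participant %s: missing file %s", e$id, f))
    }
    dat <- as.matrix(utils::read.table(tsp, sep = "\t", header = FALSE,
                                       colClasses = "numeric"))
    dimnames(dat) <- NULL
    fd <- as.numeric(readLines(fdp))
    if (anyNA(dat) || anyNA(fd)) {
      stop(sprintf("participant %s: non-numeric cells", e$id))
    }
    if (length(fd) != ncol(dat)) {
      stop(sprintf("participant %s: fd length %d does not match %d frames",
                   e$id, length(fd), ncol(dat)))
    }
    parts[[e$id]] <- parcel_ts(dat, fd,
                               run_starts = unlist(e$run_starts) + 1L,
                               tr = e$tr)
  }
  traits <- NULL
  if (!is.null(m$trait_table)) {
    traits <- utils::read.csv(file.path(dir, m$trait_table),
                              stringsAsFactors = FALSE)
    present <- names(parts) %in% traits$id
    complete <- rep(TRUE, length(parts))
    idx <- match(names(parts), traits$id)
    complete[present] <- stats::complete.cases(traits[idx[present], ,
                                                      drop = FALSE])
    drop <- !present | !complete
    if (any(drop)) {
      warning(sprintf("listwise exclusion of %d participant(s) with missing trait data: %s",
                      sum(drop), paste(names(parts)[drop], collapse = ", ")))
      parts <- parts[!drop]
    }
  }
  fc_cohort(parts, traits)
}

#' Default parcel label table (synthetic 394-node layout)
#'
#' A two-column node/network table with 333 cortical parcels across 13
#' networks plus 61 subcortical parcels, matching the node count of the
#' 333-cortical + 61-subcortical parcellation scheme. Network sizes are a
#' synthetic approximation for labeling and grouping output; they are not
#' the published parcel coordinates.
#'
#' @param path Path to a label TSV (columns \code{node}, \code{network},
#'   \code{division}); defaults to the shipped fixture.
#' @return Data frame with \code{node} (0-based id), \code{network},
#'   \code{division}.
#' @export
read_parcel_labels <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "parcel_labels_394_synthetic.tsv",
                        package = "shaman")
  }
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Analysis configuration
#'
#' @param trait Trait column name.
#' @param covariates Covariate column names (default none).
#' @param censor_threshold FD censoring cutoff in mm (default \code{Inf} =
#'   no censoring).
#' @param min_minutes Minimum post-censoring duration (default 8).
#' @param clamp_frames Optional frame clamp (default \code{NULL} = none).
#' @param n_perm Permutations (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param gate Trait-FC t gate for directional scores (default 2).
#' @param seed Integer seed (default 1).
#' @return A \code{run_config} list.
#' @export
run_config <- function(trait, covariates = character(0),
                       censor_threshold = Inf, min_minutes = 8,
                       clamp_frames = NULL, n_perm = 1000, alpha = 0.05,
                       gate = 2, seed = 1L) {
  if (min_minutes <= 0 || alpha <= 0 || alpha > 1 || gate < 0 ||
      n_perm < 1 || censor_threshold <= 0) {
    stop("invalid configuration value")
  }
  structure(list(trait = trait, covariates = covariates,
                 censor_threshold = censor_threshold,
                 min_minutes = min_minutes, clamp_frames = clamp_frames,
                 n_perm = as.integer(n_perm), alpha = alpha, gate = gate,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a configuration as JSON (exact round trip)
#' @param config A \code{run_config}.
#' @param path File path.
#' @return \code{path} / the \code{run_config}.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (is.infinite(x$censor_threshold)) x$censor_threshold <- "Inf"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$censor_threshold, "Inf")) x$censor_threshold <- Inf
  x$covariates <- as.character(unlist(x$covariates))
  do.call(run_config, x[!vapply(x, is.null, TRUE)])
}

#' Apply censoring, minimum-duration, and clamping rules to a cohort
#'
#' Censors frames at the configured FD threshold, drops participants with
#' less than \code{min_minutes} of surviving data, and optionally clamps
#' each survivor to the earliest \code{clamp_frames} frames.
#'
#' @param cohort An \code{fc_cohort} or \code{synthetic_cohort}.
#' @param censor_threshold FD cutoff (mm); \code{Inf} = none.
#' @param min_minutes Minimum duration (default 8).
#' @param clamp_frames Optional frame clamp.
#' @return List with \code{cohort} (filtered \code{fc_cohort}),
#'   \code{excluded} (ids), \code{n_censored_frames} (per survivor).
#' @export
apply_qc <- function(cohort, censor_threshold = Inf, min_minutes = 8,
                     clamp_frames = NULL) {
  parts <- cohort$participants
  kept <- list(); censored <- integer(0); excluded <- character(0)
  for (id in names(parts)) {
    cc <- tryCatch(censor_frames(parts[[id]], censor_threshold),
                   error = function(e) NULL)   # fully censored
    if (is.null(cc) || !meets_minimum(cc$ts, min_minutes)) {
      excluded <- c(excluded, id)
      next
    }
    ts <- cc$ts
    if (!is.null(clamp_frames)) ts <- clamp_frames(ts, clamp_frames)
    kept[[id]] <- ts
    censored[id] <- sum(!cc$mask$keep)
  }
  if (length(kept) == 0L) stop("all participants excluded by QC")
  traits <- cohort$traits
  if (!is.null(traits)) traits <- traits[traits$id %in% names(kept), ,
                                         drop = FALSE]
  list(cohort = fc_cohort(kept, traits), excluded = excluded,
       n_censored_frames = censored)
}

#' Participant exclusion and trait-shift report across censoring thresholds
#'
#' For each FD threshold: censors every participant, applies the
#' minimum-duration rule, and reports how many participants are excluded
#' and by how much each numeric trait's mean shifts (in percent) relative
#' to the uncensored included sample; shifts above 1 percent are flagged.
#'
#' @param cohort An \code{fc_cohort}/\code{synthetic_cohort} with a trait
#'   table.
#' @param thresholds Positive FD cutoffs in mm (e.g. \code{c(0.1, 0.2,
#'   0.3)}).
#' @param min_minutes Minimum duration rule (default 8).
#' @param flag_pct Shift threshold for flagging, percent (default 1).
#' @return Data frame with one row per (threshold, trait): \code{threshold},
#'   \code{n_excluded}, \code{trait}, \code{mean_uncensored},
#'   \code{mean_censored}, \code{shift_pct}, \code{flagged}.
#' @export
censoring_sweep <- function(cohort, thresholds, min_minutes = 8,
                            flag_pct = 1) {
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  traits <- cohort$traits
  if (is.null(traits)) stop("cohort has no trait table")
  num_cols <- names(traits)[vapply(traits, is.numeric, TRUE)]
  base_ids <- names(cohort$participants)[
    vapply(cohort$participants, meets_minimum, TRUE,
           min_minutes = min_minutes)]
  base <- traits[traits$id %in% base_ids, , drop = FALSE]
  out <- list()
  for (th in thresholds) {
    surv <- character(0)
    for (id in base_ids) {
      ok <- tryCatch({
        cc <- censor_frames(cohort$participants[[id]], th)
        meets_minimum(cc$ts, min_minutes)
      }, error = function(e) FALSE)   # fully censored participants drop out
      if (ok) surv <- c(surv, id)
    }
    kept <- traits[traits$id %in% surv, , drop = FALSE]
    for (tr in num_cols) {
      m0 <- mean(base[[tr]]); m1 <- mean(kept[[tr]])
      shift <- if (m0 == 0) ifelse(m1 == 0, 0, Inf) else 100 * (m1 - m0) / abs(m0)
      out[[length(out) + 1L]] <- data.frame(
        threshold = th, n_excluded = length(base_ids) - length(surv),
        trait = tr, mean_uncensored = m0, mean_censored = m1,
        shift_pct = shift, flagged = abs(shift) > flag_pct)
    }
  }
  do.call(rbind, out)
}

#' Write / read an edge vector as delimited text
#'
#' One Fisher-z value per line, preceded by header comment lines recording
#' the node count and the fixed edge ordering.
#'
#' @param edges An \code{edge_vector} (see [fc_edges()]).
#' @param path File path.
#' @return \code{path} / an \code{edge_vector}.
#' @export
write_edges <- function(edges, path) {
  stopifnot(inherits(edges, "edge_vector"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_nodes: %d", edges$n_nodes),
               "# ordering: row-major upper triangle, 0-based (i < j)",
               format(edges$z, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  nn <- as.integer(sub(".*n_nodes:\\s*", "", lines[hdr][1]))
  z <- as.numeric(lines[!hdr])
  if (length(z) != n_edges(nn)) stop("edge count does not match header node count")
  structure(list(z = z, n_nodes = nn), class = "edge_vector")
}

#' Write a split assignment for audit
#'
#' A per-frame label column (\code{frame}, 0-based, and \code{label}) plus
#' a block table (\code{start}, \code{end} as 0-based half-open frame
#' ranges, \code{label}).
#'
#' @param assignment A \code{split_assignment}.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_assignment <- function(assignment, dir) {
  stopifnot(inherits(assignment, "split_assignment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(frame = seq_along(assignment$label) - 1L,
               label = assignment$label),
    file.path(dir, "frame_labels.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  blocks <- assignment$blocks
  utils::write.table(
    data.frame(start = blocks$start - 1L, end = blocks$end,
               label = blocks$label),
    file.path(dir, "blocks.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(dir)
}

#' Write a motion impact result to disk
#'
#' A JSON file with the scores, p-values, and configuration, plus TSVs of
#' the edgewise z and impact-t values reconstructed as symmetric node x
#' node matrices (edge ordering documented in the JSON).
#'
#' @param x A \code{motion_impact}.
#' @param dir Output directory.
#' @return The JSON path, invisibly.
#' @export
write_motion_impact <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(omnibus_z = x$omnibus_z, omnibus_p = x$omnibus_p,
             over_z = x$over_z, over_p = x$over_p,
             under_z = x$under_z, under_p = x$under_p,
             n_nodes = x$n_nodes, n_perm = x$n_perm, alpha = x$alpha,
             gate = x$gate, seed = x$seed,
             edge_ordering = "row-major upper triangle, 0-based (i < j)")
  jsonlite::write_json(js, file.path(dir, "motion_impact.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(edges_to_matrix(x$edge_z, x$n_nodes),
                     file.path(dir, "edge_z.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(edges_to_matrix(x$impact$t, x$n_nodes),
                     file.path(dir, "impact_t.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(file.path(dir, "motion_impact.json"))
}
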