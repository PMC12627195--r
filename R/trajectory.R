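# Mouse-trajectory preprocessing and serial-bias trajectory statistics.
#
# Raw cursor paths (screen-centered pixels, y up) are cut at movement onset
# (first sample strictly more than a pixel threshold from the start),
# resampled onto an even normalized-time grid over [onset, click], and
# rotated so the target's wheel direction lies on the positive vertical
# axis; the rotated x-coordinate h(t) then carries all bias, with positive
# h on the clockwise side of the target, matching the sign of response
# errors.

trapz <- function(t, y) sum(diff(t) * (head(y, -1) + y[-1]) / 2)

#' Detect movement onset of a cursor trajectory
#'
#' The first sample whose Euclidean distance from the starting point (the
#' screen center, where the cursor is reset before each response) strictly
#' exceeds `threshold_px`.
#'
#' @param traj Data frame with `timestamp_ms`, `x_px`, `y_px`
#'   (time-sorted, screen-centered coordinates).
#' @param threshold_px Onset threshold in pixels.
#' @return List `index` (row of the onset sample), `latency_ms` (its
#'   timestamp) and `usable`; a trajectory that never leaves the threshold
#'   circle, or whose onset is the final sample, is flagged unusable.
#' @export
detect_onset <- function(traj, threshold_px = 10) {
  if (nrow(traj) < 3L) stop("trajectory needs at least 3 samples")
  d <- sqrt(traj$x_px^2 + traj$y_px^2)
  idx <- which(d > threshold_px)[1]
  if (is.na(idx) || idx == nrow(traj))
    return(list(index = NA_integer_, latency_ms = NA_real_,
                usable = FALSE))
  list(index = idx, latency_ms = traj$timestamp_ms[idx], usable = TRUE)
}

#' Resample a trajectory onto a normalized time grid
#'
#' Linear interpolation of cursor position onto `n_grid` evenly spaced
#' points over `[onset, click]`, with movement onset at 0 and the final
#' click at 1. The default 101-point grid embeds the 5%-step nodes used by
#' the time-resolved model exactly.
#'
#' @param traj Data frame with `timestamp_ms`, `x_px`, `y_px`.
#' @param onset Onset list from [detect_onset()] (or an onset row index).
#' @param n_grid Number of grid points including both endpoints.
#' @return List `t` (grid on `[0, 1]`), `x`, `y`, `onset_latency_ms`.
#' @export
normalize_time <- function(traj, onset = detect_onset(traj),
                           n_grid = 101L) {
  if (is.numeric(onset)) onset <- list(index = onset,
                                       latency_ms =
                                         traj$timestamp_ms[onset],
                                       usable = TRUE)
  if (!isTRUE(onset$usable)) stop("trajectory is unusable (no onset)")
  i0 <- onset$index
  n <- nrow(traj)
  t0 <- traj$timestamp_ms[i0]; t1 <- traj$timestamp_ms[n]
  if (t1 <= t0) stop("onset and click coincide")
  tt <- (traj$timestamp_ms[i0:n] - t0) / (t1 - t0)
  grid <- seq(0, 1, length.out = n_grid)
  list(t = grid,
       x = approx(tt, traj$x_px[i0:n], grid, ties = "ordered")$y,
       y = approx(tt, traj$y_px[i0:n], grid, ties = "ordered")$y,
       onset_latency_ms = onset$latency_ms)
}

#' Rotate positions so the target direction is vertical
#'
#' Rigid rotation taking the target's wheel direction onto the positive
#' y-axis. The returned horizontal coordinate is positive on the clockwise
#' side of the target.
#'
#' @param x,y Cursor coordinates (screen-centered, y up).
#' @param target_deg Target wheel angle in degrees (0 = up, clockwise
#'   positive).
#' @return List `h` (horizontal offsets) and `v` (radial progress along the
#'   target direction).
#' @export
rotate_to_target <- function(x, y, target_deg) {
  th <- target_deg * pi / 180
  list(h = x * cos(th) - y * sin(th),
       v = x * sin(th) + y * cos(th))
}

#' Align one trajectory: onset, normalized time, target rotation
#'
#' @param traj Data frame with `timestamp_ms`, `x_px`, `y_px`.
#' @param target_deg Target wheel angle in degrees.
#' @param threshold_px Onset threshold (pixels).
#' @param n_grid Normalized-time grid size.
#' @return Object of class `"aligned_traj"`: list `t`, `h`, `v`,
#'   `onset_latency_ms`, `target_deg`, `usable`. Unusable trajectories
#'   return `usable = FALSE` with empty components.
#' @export
align_trajectory <- function(traj, target_deg, threshold_px = 10,
                             n_grid = 101L) {
  onset <- detect_onset(traj, threshold_px)
  if (!onset$usable)
    return(structure(list(t = NULL, h = NULL, v = NULL,
                          onset_latency_ms = NA_real_,
                          target_deg = target_deg, usable = FALSE),
                     class = "aligned_traj"))
  nt <- normalize_time(traj, onset, n_grid)
  rot <- rotate_to_target(nt$x, nt$y, target_deg)
  structure(list(t = nt$t, h = rot$h, v = rot$v,
                 onset_latency_ms = nt$onset_latency_ms,
                 target_deg = target_deg, usable = TRUE),
            class = "aligned_traj")
}

#' Trajectory area under the curve, with and without endpoint bias
#'
#' Trapezoid integral of the horizontal offset h(t) over normalized
#' movement time. The endpoint-excluded variant integrates
#' `h(t) - t * h(1)`: subtracting the straight linear ramp to the final
#' cursor position is the unique linear detrending that zeroes the endpoint
#' while preserving h(0), so the two variants differ by exactly `h(1) / 2`
#' under the trapezoid rule.
#'
#' @param aligned An `"aligned_traj"` from [align_trajectory()] (or any
#'   list with `t` and `h`).
#' @param scale Unit scale factor applied to both AUCs (e.g. 100 to express
#'   normalized time in percent).
#' @return List `auc_with`, `auc_without` (px per unit normalized time) and
#'   `endpoint` (h(1), px).
#' @export
compute_auc <- function(aligned, scale = 1) {
  t <- aligned$t; h <- aligned$h
  if (is.null(t) || is.null(h)) stop("aligned trajectory is empty")
  endpoint <- h[length(h)]
  with_ep <- trapz(t, h)
  without_ep <- trapz(t, h - t * endpoint)
  list(auc_with = scale * with_ep, auc_without = scale * without_ep,
       endpoint = endpoint)
}

#' Per-response trajectory statistics
#'
#' Aligns every recorded trajectory and computes its onset latency, AUCs
#' and horizontal deviations at the 5%-step normalized-time nodes. Unusable
#' trajectories (cursor never beyond the onset threshold) are retained with
#' `usable = FALSE` and `NA` statistics, so their trials can still enter
#' report-error analyses.
#'
#' @param trajectories Long-format data frame: `participant`, `trial_index`,
#'   `report_type`, `timestamp_ms`, `x_px`, `y_px`, `target_deg`.
#' @param threshold_px,n_grid Passed to [align_trajectory()].
#' @param n_points Number of 1/`n_points`-step nodes (the node at 100%
#'   equals the endpoint offset).
#' @param scale AUC unit scale factor.
#' @return Data frame with one row per response: identifiers,
#'   `latency_ms`, `usable`, `endpoint`, `auc_with`, `auc_without`, and
#'   `h_1` ... `h_<n_points>`.
#' @export
preprocess_trajectories <- function(trajectories, threshold_px = 10,
                                    n_grid = 101L, n_points = 20L,
                                    scale = 1) {
  stopifnot((n_grid - 1L) %% n_points == 0L)
  node_idx <- 1L + seq_len(n_points) * ((n_grid - 1L) %/% n_points)
  f <- interaction(trajectories$participant, trajectories$trial_index,
                   trajectories$report_type, drop = TRUE, sep = "\r")
  groups <- split(seq_len(nrow(trajectories)), f)
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    tj <- trajectories[rows, ]
    tj <- tj[order(tj$timestamp_ms), ]
    al <- align_trajectory(tj[c("timestamp_ms", "x_px", "y_px")],
                           tj$target_deg[1], threshold_px, n_grid)
    base <- data.frame(participant = tj$participant[1],
                       trial_index = tj$trial_index[1],
                       report_type = tj$report_type[1],
                       latency_ms = al$onset_latency_ms,
                       usable = al$usable)
    if (al$usable) {
      auc <- compute_auc(al, scale)
      hs <- al$h[node_idx]
    } else {
      auc <- list(auc_with = NA_real_, auc_without = NA_real_,
                  endpoint = NA_real_)
      hs <- rep(NA_real_, n_points)
    }
    base$endpoint <- auc$endpoint
    base$auc_with <- auc$auc_with
    base$auc_without <- auc$auc_without
    hmat <- matrix(hs, nrow = 1,
                   dimnames = list(NULL, paste0("h_", seq_len(n_points))))
    out[[g]] <- cbind(base, hmat)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

join_trial_stats <- function(trials, stats, convention, tol = 1) {
  trials$.bin <- assign_condition(trials, convention, tol)
  merged <- merge(trials, stats,
                  by = c("participant", "trial_index", "report_type"),
                  sort = FALSE)
  if (nrow(merged) < nrow(stats))
    stop("orphan trajectories: no matching trial record")
  merged
}

#' Condition-binned mean trajectory AUCs
#'
#' The AUC analogue of [summarize_conditions()]: per participant x report
#' type x relative-color bin, the plain mean (AUC is linear, not circular)
#' of per-trial AUCs with and without endpoint bias, with the +/-180 edge
#' condition synthesized as for errors. Output feeds [fit_dog_hbm()] with
#' `response = "auc_with"` or `"auc_without"`.
#'
#' @param trials Trial-record data frame.
#' @param trajectories Long-format trajectory data frame, or `NULL` when
#'   `stats` is supplied.
#' @param stats Optional precomputed [preprocess_trajectories()] output.
#' @param convention,edge See [assign_condition()] and [synthesize_edge()].
#' @param scale AUC unit scale factor (used when preprocessing here).
#' @param threshold_px,n_grid Passed to preprocessing.
#' @return Data frame `participant`, `report_type`, `bin_center`,
#'   `auc_with`, `auc_without`, `n` (ten bins per cell).
#' @export
auc_condition_summaries <- function(trials, trajectories = NULL,
                                    stats = NULL,
                                    convention = "prev_minus_current",
                                    edge = "average", scale = 1,
                                    threshold_px = 10, n_grid = 101L) {
  if (is.null(stats))
    stats <- preprocess_trajectories(trajectories, threshold_px, n_grid,
                                     scale = scale)
  d <- join_trial_stats(trials, stats, convention)
  d <- d[d$usable & !is.na(d$.bin), ]
  grp <- interaction(d$participant, d$report_type, d$.bin, drop = TRUE,
                     sep = "\r")
  key <- do.call(rbind, strsplit(levels(grp), "\r", fixed = TRUE))
  agg <- data.frame(participant = key[, 1], report_type = key[, 2],
                    bin_center = as.numeric(key[, 3]),
                    auc_with = as.vector(tapply(d$auc_with, grp, mean)),
                    auc_without = as.vector(tapply(d$auc_without, grp,
                                                   mean)),
                    n = as.vector(tapply(d$auc_with, grp, length)))
  agg <- agg[order(agg$participant, agg$report_type, agg$bin_center), ]
  rownames(agg) <- NULL
  synthesize_edge(agg, value = c("auc_with", "auc_without"), edge = edge)
}

#' Condition-binned horizontal deviation profiles
#'
#' Mean horizontal cursor deviation at each 5%-step normalized-time node,
#' per participant x report type x relative-color bin, with the +/-180 edge
#' synthesized per node. Output feeds [fit_dog_hbm_time()].
#'
#' @inheritParams auc_condition_summaries
#' @param n_points Number of time nodes.
#' @return Data frame `participant`, `report_type`, `time_point` (node as
#'   fraction of movement time), `bin_center`, `mean_h`, `n`.
#' @export
deviation_profiles <- function(trials, trajectories = NULL, stats = NULL,
                               convention = "prev_minus_current",
                               edge = "average", n_points = 20L,
                               threshold_px = 10, n_grid = 101L) {
  if (is.null(stats))
    stats <- preprocess_trajectories(trajectories, threshold_px, n_grid,
                                     n_points = n_points)
  d <- join_trial_stats(trials, stats, convention)
  d <- d[d$usable & !is.na(d$.bin), ]
  grp <- interaction(d$participant, d$report_type, d$.bin, drop = TRUE,
                     sep = "\r")
  key <- do.call(rbind, strsplit(levels(grp), "\r", fixed = TRUE))
  parts <- vector("list", n_points)
  for (k in seq_len(n_points)) {
    col <- paste0("h_", k)
    cell <- data.frame(participant = key[, 1], report_type = key[, 2],
                       time_point = k / n_points,
                       bin_center = as.numeric(key[, 3]),
                       mean_h = as.vector(tapply(d[[col]], grp, mean)),
                       n = as.vector(tapply(d[[col]], grp, length)))
    # median-split subsets can leave sparse cells without edge bins
    parts[[k]] <- synthesize_edge(cell, value = "mean_h", edge = edge,
                                  on_missing = "skip")
  }
  out <- do.call(rbind, parts)
  out <- out[order(out$participant, out$report_type, out$time_point,
                   out$bin_center), ]
  rownames(out) <- NULL
  out
}

#' Median split by movement-onset latency
#'
#' Within each participant x report type, responses at or below the median
#' onset latency are labelled `"early"`, the rest `"late"` (the
#' median-valued response goes to the early set, a deterministic
#' convention). Cells with fewer than 2 usable responses, or where all
#' latencies are tied (leaving the late set empty), are flagged with a
#' warning.
#'
#' @param stats Per-response statistics (e.g. from
#'   [preprocess_trajectories()]) with `participant`, `report_type`,
#'   `latency_ms`.
#' @return `stats` with an `onset_group` column (`NA` for unusable rows).
#' @export
median_split_by_onset <- function(stats) {
  stats$onset_group <- NA_character_
  cells <- unique(stats[c("participant", "report_type")])
  flagged <- character(0)
  for (i in seq_len(nrow(cells))) {
    sel <- stats$participant == cells$participant[i] &
      stats$report_type == cells$report_type[i] &
      !is.na(stats$latency_ms)
    lat <- stats$latency_ms[sel]
    cell_id <- paste(cells$participant[i], cells$report_type[i], sep = "/")
    if (length(lat) < 2L) {
      flagged <- c(flagged, cell_id)
      next
    }
    med <- median(lat)
    grp <- ifelse(lat <= med, "early", "late")
    if (all(grp == "early")) flagged <- c(flagged, cell_id)
    stats$onset_group[sel] <- grp
  }
  if (length(flagged) > 0)
    warning(sprintf("degenerate median split in %d cell(s): %s",
                    length(flagged),
                    paste(head(flagged, 5), collapse = ", ")))
  stats
}
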