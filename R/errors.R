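# From trial records to condition-binned circular mean errors: the response
# variable of the DoG fit. Handles the relative-color sign convention, the
# exclusion rules (random condition, first trial, off-grid offsets) and the
# synthesis of the +/-180 edge condition from the two -144/+144 edges.

CONDITION_BINS <- seq(-144, 144, by = 36)

#' Signed response error of a trial
#'
#' Angular distance between the chosen and the true target color; positive
#' errors are clockwise of the target.
#'
#' @param response,target Angles in degrees (vectors recycle).
#' @return Signed errors in `(-180, 180]`.
#' @export
compute_error <- function(response, target) {
  if (any(is.na(response)) || any(is.na(target)))
    stop("missing response or target")
  signed_difference(response, target)
}

#' Relative-color condition of a trial
#'
#' The previous trial's target expressed relative to the current one:
#' `x = wrap(prev_target - target)` under the default convention, so
#' positive `x` means the previous target was clockwise of the current.
#' Random-condition trials and trials without a previous target are
#' excluded (`NA` bin); a non-random trial whose offset is not within
#' `tol` of the 36-degree grid indicates corrupted data and is an error.
#'
#' @param trials Data frame with `target_deg`, `prev_target_deg`,
#'   `is_random`.
#' @param convention `"prev_minus_current"` (default) or
#'   `"current_minus_prev"`, which flips the sign of `x`.
#' @param tol Grid-membership tolerance in degrees.
#' @return Numeric vector of bin centers in `{-144, ..., +144}`, `NA` where
#'   excluded.
#' @export
assign_condition <- function(trials,
                             convention = c("prev_minus_current",
                                            "current_minus_prev"),
                             tol = 1) {
  convention <- match.arg(convention)
  x <- rep(NA_real_, nrow(trials))
  ok <- !is.na(trials$prev_target_deg)
  x[ok] <- signed_difference(trials$prev_target_deg[ok],
                             trials$target_deg[ok])
  if (convention == "current_minus_prev") x <- -x
  bin <- rep(NA_real_, length(x))
  bin[ok] <- CONDITION_BINS[apply(abs(outer(x[ok], CONDITION_BINS, "-")),
                                  1, which.min)]
  off <- ok & !trials$is_random & abs(x - bin) > tol
  if (any(off))
    stop(sprintf(
      "%d non-random trial(s) have relative colors off the 36-degree grid",
      sum(off)))
  bin[trials$is_random] <- NA
  bin
}

#' Condition-binned circular mean errors
#'
#' Per participant x report type x relative-color bin: the circular mean of
#' signed response errors and the trial count. Random-condition trials,
#' first trials (no previous target) and - optionally - trials immediately
#' following a random trial are excluded. Cells with no trials are reported
#' with a warning rather than silently dropped.
#'
#' @param trials Trial-record data frame (see [simulate_experiment()] or
#'   [read_trials()]).
#' @param convention,tol Passed to [assign_condition()].
#' @param exclude_post_random Also exclude the trial after each
#'   random-condition trial.
#' @return Data frame `participant`, `report_type`, `bin_center`,
#'   `mean_error`, `n` with the nine raw bins per cell.
#' @export
summarize_conditions <- function(trials,
                                 convention = "prev_minus_current",
                                 tol = 1, exclude_post_random = FALSE) {
  trials$.bin <- assign_condition(trials, convention, tol)
  trials$.err <- compute_error(trials$response_deg, trials$target_deg)
  if (exclude_post_random) {
    post <- with(trials, ave(is_random, participant, report_type,
                             FUN = function(z) c(FALSE, z[-length(z)])))
    trials$.bin[post == 1] <- NA
  }
  keep <- !is.na(trials$.bin)
  d <- trials[keep, ]
  grp <- split(d$.err, list(d$participant, d$report_type, d$.bin),
               drop = TRUE, sep = "\r")
  key <- do.call(rbind, strsplit(names(grp), "\r", fixed = TRUE))
  agg <- data.frame(participant = key[, 1], report_type = key[, 2],
                    bin_center = as.numeric(key[, 3]),
                    mean_error = vapply(grp, circular_mean, numeric(1)),
                    n = vapply(grp, length, integer(1)))
  full <- expand.grid(participant = unique(trials$participant),
                      report_type = unique(trials$report_type),
                      bin_center = CONDITION_BINS, stringsAsFactors = FALSE)
  out <- merge(full, agg, all.x = TRUE, sort = FALSE)
  missing_cells <- is.na(out$n)
  if (any(missing_cells)) {
    warning(sprintf("%d empty condition cell(s): %s", sum(missing_cells),
                    paste(utils::head(apply(
                      out[missing_cells, c("participant", "report_type",
                                           "bin_center")], 1,
                      paste, collapse = "/"), 5), collapse = ", ")))
  }
  out <- out[order(out$participant, out$report_type, out$bin_center), ]
  rownames(out) <- NULL
  out[c("participant", "report_type", "bin_center", "mean_error", "n")]
}

#' Synthesize the +/-180 edge condition
#'
#' Appends, per participant x report type, a bin at +180 whose value is the
#' plain average of the -144 and +144 bin values (`edge = "average"`), for
#' continuity of the circular feature space; the nine raw bins are retained,
#' giving ten conditions in total. `edge = "flip"` instead uses the
#' sign-flipped average `(v(+144) - v(-144)) / 2`.
#'
#' @param summaries Data frame from [summarize_conditions()] (or any table
#'   with `participant`, `report_type`, `bin_center` and value columns).
#' @param value Name(s) of the value column(s) to average.
#' @param edge `"average"` or `"flip"`.
#' @param on_missing What to do when a cell lacks a -144 or +144 bin:
#'   `"error"` (default) or `"skip"` the cell's edge row with a warning
#'   (useful for sparse median-split subsets).
#' @return The input with one extra `bin_center == 180` row per cell.
#' @export
synthesize_edge <- function(summaries, value = "mean_error",
                            edge = c("average", "flip"),
                            on_missing = c("error", "skip")) {
  edge <- match.arg(edge)
  on_missing <- match.arg(on_missing)
  cells <- unique(summaries[c("participant", "report_type")])
  extra <- vector("list", nrow(cells))
  skipped <- 0L
  for (i in seq_len(nrow(cells))) {
    sel <- summaries$participant == cells$participant[i] &
      summaries$report_type == cells$report_type[i]
    lo <- summaries[sel & summaries$bin_center == -144, ]
    hi <- summaries[sel & summaries$bin_center == 144, ]
    if (nrow(lo) != 1L || nrow(hi) != 1L ||
        any(is.na(lo[value])) || any(is.na(hi[value]))) {
      if (on_missing == "skip") {
        skipped <- skipped + 1L
        next
      }
      stop(sprintf("edge bins -144/+144 missing for %s/%s",
                   cells$participant[i], cells$report_type[i]))
    }
    row <- lo
    row$bin_center <- 180
    for (v in value)
      row[[v]] <- if (edge == "average") (lo[[v]] + hi[[v]]) / 2
                  else (hi[[v]] - lo[[v]]) / 2
    if ("n" %in% names(row)) row$n <- lo$n + hi$n
    extra[[i]] <- row
  }
  if (skipped > 0L)
    warning(sprintf("edge synthesis skipped for %d cell(s) with missing %s",
                    skipped, "-144/+144 bins"))
  out <- rbind(summaries, do.call(rbind, extra))
  out <- out[order(out$participant, out$report_type, out$bin_center), ]
  rownames(out) <- NULL
  out
}

#' Cross-report correlations of individual bias amplitudes
#'
#' Pearson correlations, with `n - 2` degrees of freedom, between
#' participants' amplitude estimates for each pair of report types.
#'
#' @param alphas Data frame or matrix: one row per participant, one column
#'   per report type (at least 3 complete rows).
#' @return Data frame `pair`, `r`, `df`, `p_value`. Pairs involving a
#'   zero-variance column are flagged with `NA` and a warning.
#' @export
correlate_alphas <- function(alphas) {
  alphas <- as.data.frame(alphas)
  if (nrow(alphas) < 3L) stop("need at least 3 participants")
  if (any(is.na(alphas))) stop("missing amplitude values")
  combs <- utils::combn(names(alphas), 2)
  out <- data.frame(pair = apply(combs, 2, paste, collapse = ":"),
                    r = NA_real_, df = nrow(alphas) - 2L,
                    p_value = NA_real_)
  for (k in seq_len(ncol(combs))) {
    a <- alphas[[combs[1, k]]]; b <- alphas[[combs[2, k]]]
    if (sd(a) == 0 || sd(b) == 0) {
      warning(sprintf("zero variance in pair %s; correlation undefined",
                      out$pair[k]))
      next
    }
    ct <- cor.test(a, b)
    out$r[k] <- unname(ct$estimate)
    out$p_value[k] <- ct$p.value
  }
  out
}
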