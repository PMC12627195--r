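# Plain-text table formats. Both tables are comma-separated with a header
# row, preceded by one comment line carrying the schema version and
# provenance key=value pairs. Readers accept files without the comment line
# but reject a newer schema major version.

SCHEMA_VERSION <- "1.0"

TRIAL_COLUMNS <- c("participant", "task", "report_type", "trial_index",
                   "target_deg", "prev_target_deg", "response_deg",
                   "is_random")
TRAJ_COLUMNS <- c("participant", "trial_index", "report_type",
                  "timestamp_ms", "x_px", "y_px", "target_deg")

provenance_line <- function(provenance = NULL) {
  kv <- c(list(serialdog_schema = SCHEMA_VERSION), provenance)
  paste("#", paste(sprintf("%s=%s", names(kv), unlist(kv)),
                   collapse = " "))
}

check_schema <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("serialdog_schema=([0-9]+)\\.([0-9]+)",
                                 first))[[1]]
  if (length(m) == 3L) {
    major <- as.integer(m[2])
    ours <- as.integer(strsplit(SCHEMA_VERSION, ".", fixed = TRUE)[[1]][1])
    if (major > ours)
      stop(sprintf("file schema %s.%s is newer than supported %s",
                   m[2], m[3], SCHEMA_VERSION))
  }
  invisible(TRUE)
}

normalize_angle_col <- function(x, name) {
  out_of_range <- !is.na(x) & (x < 0 | x >= 360)
  if (any(out_of_range)) {
    warning(sprintf("%d value(s) in '%s' outside [0, 360) were wrapped",
                    sum(out_of_range), name))
    x[out_of_range] <- wrap_angle(x[out_of_range])
  }
  x
}

#' Write a trial table
#'
#' @param trials Trial-record data frame (see [read_trials()] for the
#'   schema).
#' @param path Output file path.
#' @param provenance Optional named list written into the header comment.
#' @export
write_trials <- function(trials, path, provenance = NULL) {
  stopifnot(all(TRIAL_COLUMNS %in% names(trials)))
  writeLines(provenance_line(provenance), path)
  suppressWarnings(write.table(trials[TRIAL_COLUMNS], path, sep = ",",
                               row.names = FALSE, append = TRUE,
                               qmethod = "double"))
  invisible(path)
}

#' Read a trial table
#'
#' Expected columns: `participant`, `task`, `report_type`, `trial_index`,
#' `target_deg`, `prev_target_deg`, `response_deg`, `is_random`; angles in
#' degrees (values outside `[0, 360)` are wrapped with a warning;
#' `prev_target_deg` may be empty on first trials).
#'
#' @param path CSV file path (optionally with a `#` provenance header).
#' @return Validated trial-record data frame.
#' @export
read_trials <- function(path) {
  check_schema(path)
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(d))
  if (length(missing_cols) > 0)
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("target_deg", "response_deg"))
    if (any(is.na(d[[col]])))
      stop(sprintf("unparseable or missing '%s' at row(s) %s", col,
                   paste(head(which(is.na(d[[col]]))), collapse = ", ")))
  for (col in c("target_deg", "prev_target_deg", "response_deg"))
    d[[col]] <- normalize_angle_col(d[[col]], col)
  d$is_random <- as.logical(d$is_random)
  key <- paste(d$participant, d$trial_index, d$report_type)
  if (anyDuplicated(key))
    stop("duplicate (participant, trial_index, report_type) rows")
  d
}

#' Write a trajectory table
#'
#' @param trajectories Long-format trajectory data frame.
#' @param path Output file path.
#' @param provenance Optional named list for the header comment.
#' @export
write_trajectories <- function(trajectories, path, provenance = NULL) {
  stopifnot(all(TRAJ_COLUMNS %in% names(trajectories)))
  writeLines(provenance_line(provenance), path)
  suppressWarnings(write.table(trajectories[TRAJ_COLUMNS], path,
                               sep = ",", row.names = FALSE,
                               append = TRUE, qmethod = "double"))
  invisible(path)
}

#' Read a trajectory table
#'
#' Long format: `participant`, `trial_index`, `report_type`,
#' `timestamp_ms`, `x_px`, `y_px`, `target_deg`. Rows are re-sorted by
#' timestamp within each response; duplicate timestamps within a response
#' are an error, as are trajectories without a matching trial when a trial
#' table is supplied.
#'
#' @param path CSV file path.
#' @param trials Optional trial table for referential-integrity checking.
#' @return Validated, time-sorted trajectory data frame.
#' @export
read_trajectories <- function(path, trials = NULL) {
  check_schema(path)
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRAJ_COLUMNS, names(d))
  if (length(missing_cols) > 0)
    stop("trajectory table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  d <- d[order(d$participant, d$trial_index, d$report_type,
               d$timestamp_ms), ]
  rownames(d) <- NULL
  key <- paste(d$participant, d$trial_index, d$report_type)
  if (any(ave(d$timestamp_ms, key, FUN = anyDuplicated) > 0))
    stop("non-increasing timestamps within a trajectory")
  if (!is.null(trials)) {
    trial_key <- unique(paste(trials$participant, trials$trial_index,
                              trials$report_type))
    orphan <- !(key %in% trial_key)
    if (any(orphan))
      stop(sprintf("%d trajectory sample(s) reference unknown trials",
                   sum(orphan)))
  }
  d
}
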