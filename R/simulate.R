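# Synthetic continuous color-report experiments with mouse tracking.
#
# The generator reproduces the statistical structure the analysis assumes:
# a 36-degree-step relative-color manipulation with an interleaved random
# condition, von Mises report errors whose mean follows a DoG of the
# previous trial's relative color, report-type-specific bias amplitudes,
# log-normal movement-onset latencies, and cursor trajectories whose
# within-movement bias follows a time-varying amplitude profile (decaying
# repulsion plus rising attraction) pinned to end at the trial's realized
# response.

REPORT_TYPES <- c("perceptual", "consolidation", "retrieval")

# Best & Fisher (1979) rejection sampler for the von Mises distribution.
# mu in degrees, returns degrees. Falls back to the wrapped-normal limit for
# very large concentration, where the rejection constants degenerate.
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa > 0, n >= 0)
  if (n == 0L) return(numeric(0))
  if (kappa > 5e4)
    return(wrap_signed(mu + rnorm(n, 0, sqrt(1 / kappa) * 180 / pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        theta <- sign(u[3] - 0.5) * acos(f)
        out[i] <- theta * 180 / pi
        break
      }
    }
  }
  wrap_signed(mu + out)
}

default_profiles <- function() {
  # Time-varying bias-amplitude profiles over normalized movement time.
  # NULL means a constant profile equal to the trial's endpoint amplitude
  # (bias fully present from movement onset, as when the target stays
  # visible). Consolidation couples the profile to movement-onset latency:
  # early-onset movements start from the perceptual (repulsive) residue and
  # hand over to the attractive memory trace mid-movement; late-onset
  # movements rely on the consolidated trace only.
  cons_early <- list(rep_amp = -5, rep_mid = 0.3, rep_scale = 0.08,
                     att_mid = 0.5, att_scale = 0.1)
  cons_late <- list(rep_amp = 0, rep_mid = 0.3, rep_scale = 0.08,
                    att_mid = 0.15, att_scale = 0.1)
  retr <- list(rep_amp = 0, rep_mid = 0.3, rep_scale = 0.08,
               att_mid = 0.2, att_scale = 0.1)
  list(perceptual = list(early = NULL, late = NULL),
       consolidation = list(early = cons_early, late = cons_late),
       retrieval = list(early = retr, late = retr))
}

#' Configuration of a synthetic serial-dependence experiment
#'
#' Defaults mirror the study design the analysis targets: 20 participants,
#' 150 perceptual-matching trials and 400 delayed working-memory trials each
#' (the latter yielding a consolidation and a retrieval report per trial),
#' relative target colors stepped in 36-degree increments across nine
#' conditions with a random condition roughly every tenth trial, and DoG
#' bias amplitudes of -0.8 (perceptual, repulsive), +1.6 (consolidation) and
#' +6.2 degrees (retrieval, attractive).
#'
#' @param n_participants Number of simulated participants.
#' @param n_perceptual_trials,n_wm_trials Trials per task.
#' @param alpha_true Named vector of generating DoG amplitudes (degrees) for
#'   `perceptual`, `consolidation`, `retrieval`.
#' @param w_true Generating DoG width (1/degrees).
#' @param beta_true Generating intercept (degrees).
#' @param kappa von Mises concentration of trial-level report noise, named
#'   per report type (a scalar is recycled). Defaults reflect that matching
#'   a visible target is far more precise (kappa 100, circular SD about 6
#'   degrees) than reporting from memory (30 and 20, about 11 and 13
#'   degrees, with precision degrading over the retention delay).
#' @param alpha_participant_sd SD (degrees) of a participant-level amplitude
#'   offset shared across report types; induces the positive cross-report
#'   correlation of individual biases and leaves a minority of participants
#'   with attractive perceptual biases.
#' @param random_trial_period A random-color trial appears about once per
#'   this many trials.
#' @param onset_latency List `meanlog`, `sdlog` of the log-normal
#'   movement-onset latency in ms.
#' @param movement List `meanlog`, `sdlog` of the log-normal movement
#'   duration in ms.
#' @param trajectory List of trajectory-generation settings:
#'   `n_move_samples`, `sample_ms` (pre-onset sampling interval),
#'   `wheel_radius_px`, `motor_noise_sd_px`, `radial_exp` (exponent of
#'   radial progress over normalized time; < 1 means fast early movement),
#'   and `profiles` (per report type and onset group; see Details).
#' @param seed Integer seed; the whole simulated dataset is a deterministic
#'   function of the configuration.
#'
#' @details Each profile is `NULL` (constant amplitude) or a list
#'   `rep_amp`, `rep_mid`, `rep_scale`, `att_mid`, `att_scale` defining a
#'   decaying repulsive logistic ramp plus a rising attractive one over
#'   normalized movement time; the attractive amplitude is solved so the
#'   profile ends at the trial's generating amplitude, which keeps endpoint
#'   clicks consistent with the report-error model.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_participants = 20L,
                       n_perceptual_trials = 150L,
                       n_wm_trials = 400L,
                       alpha_true = c(perceptual = -0.8,
                                      consolidation = 1.6,
                                      retrieval = 6.2),
                       w_true = 0.02,
                       beta_true = 0,
                       kappa = c(perceptual = 100, consolidation = 30,
                                 retrieval = 20),
                       alpha_participant_sd = 1,
                       random_trial_period = 10L,
                       onset_latency = list(meanlog = log(300), sdlog = 0.35),
                       movement = list(meanlog = log(700), sdlog = 0.2),
                       trajectory = list(),
                       seed = 1L) {
  traj_defaults <- list(n_move_samples = 40L, sample_ms = 16,
                        wheel_radius_px = 400, motor_noise_sd_px = 2,
                        radial_exp = 0.8, profiles = default_profiles())
  trajectory <- modifyList(traj_defaults, trajectory)
  if (length(kappa) == 1L && is.null(names(kappa)))
    kappa <- setNames(rep(kappa, length(REPORT_TYPES)), REPORT_TYPES)
  cfg <- list(n_participants = as.integer(n_participants),
              n_perceptual_trials = as.integer(n_perceptual_trials),
              n_wm_trials = as.integer(n_wm_trials),
              alpha_true = alpha_true, w_true = w_true,
              beta_true = beta_true, kappa = kappa,
              alpha_participant_sd = alpha_participant_sd,
              random_trial_period = as.integer(random_trial_period),
              onset_latency = onset_latency, movement = movement,
              trajectory = trajectory, seed = as.integer(seed))
  stopifnot(cfg$n_participants > 0, cfg$n_perceptual_trials > 0,
            cfg$n_wm_trials > 0, all(cfg$kappa > 0), cfg$w_true > 0,
            cfg$random_trial_period >= 2,
            all(REPORT_TYPES %in% names(cfg$alpha_true)),
            all(REPORT_TYPES %in% names(cfg$kappa)),
            cfg$alpha_participant_sd >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a target-color sequence with stepped relative-color conditions
#'
#' Non-random trials step from the previous trial's target by one of the
#' nine offsets -144, -108, ..., +144 degrees, drawn as shuffled balanced
#' blocks of the nine conditions. Approximately every `period`-th trial the
#' target is instead drawn uniformly on the wheel and flagged as the random
#' condition (exactly one such trial per complete block of `period` trials).
#'
#' @param n_trials Number of trials (at least 2).
#' @param period Random-condition spacing (at least 2).
#' @return A data frame with columns `target_deg` and `is_random`.
#' @export
generate_target_sequence <- function(n_trials, period = 10L) {
  n_trials <- as.integer(n_trials)
  period <- as.integer(period)
  if (n_trials < 2L) stop("'n_trials' must be at least 2")
  if (period < 2L) stop("'period' must be at least 2")

  steps_pool <- seq(-144, 144, by = 36)
  n_blocks <- ceiling(n_trials / length(steps_pool))
  step_queue <- as.vector(vapply(seq_len(n_blocks),
                                 function(i) sample(steps_pool),
                                 numeric(length(steps_pool))))

  is_random <- rep(FALSE, n_trials)
  full_blocks <- n_trials %/% period
  for (b in seq_len(full_blocks)) {
    lo <- (b - 1L) * period + 1L
    slot <- sample(setdiff(lo:(lo + period - 1L), 1L), 1L)
    is_random[slot] <- TRUE
  }
  rem <- n_trials %% period
  if (rem > 0L && runif(1) < rem / period) {
    lo <- full_blocks * period + 1L
    cand <- setdiff(lo:n_trials, 1L)
    if (length(cand) > 0L) is_random[sample(cand, 1L)] <- TRUE
  }

  target <- numeric(n_trials)
  target[1] <- runif(1, 0, 360)
  k <- 0L
  for (t in 2:n_trials) {
    if (is_random[t]) {
      target[t] <- runif(1, 0, 360)
    } else {
      k <- k + 1L
      target[t] <- wrap_angle(target[t - 1] + step_queue[k])
    }
  }
  data.frame(target_deg = target, is_random = is_random)
}

#' Simulate report errors for one task sequence
#'
#' Each response is the target plus a von Mises error whose mean direction
#' is the DoG bias evaluated at the previous target's relative color
#' (`beta_true` alone on the first trial, where no previous target exists).
#'
#' @param sequence Data frame from [generate_target_sequence()].
#' @param report_type One of `"perceptual"`, `"consolidation"`,
#'   `"retrieval"`.
#' @param config A [sim_config()].
#' @param alpha Generating amplitude override (degrees); defaults to
#'   `config$alpha_true[report_type]`.
#' @return A data frame of trial records: `task`, `report_type`,
#'   `trial_index`, `target_deg`, `prev_target_deg`, `response_deg`,
#'   `is_random`.
#' @export
simulate_errors <- function(sequence, report_type, config = sim_config(),
                            alpha = NULL) {
  report_type <- match.arg(report_type, REPORT_TYPES)
  if (is.null(alpha)) alpha <- unname(config$alpha_true[report_type])
  n <- nrow(sequence)
  prev <- c(NA, sequence$target_deg[-n])
  x <- rep(NA_real_, n)
  ok <- !is.na(prev)
  x[ok] <- signed_difference(prev[ok], sequence$target_deg[ok])
  mu <- rep(config$beta_true, n)
  mu[ok] <- dog(x[ok], alpha, config$w_true, config$beta_true)
  err <- rvonmises(n, mu, unname(config$kappa[report_type]))
  data.frame(task = if (report_type == "perceptual") "perceptual" else "wm",
             report_type = report_type,
             trial_index = seq_len(n),
             target_deg = sequence$target_deg,
             prev_target_deg = prev,
             response_deg = wrap_angle(sequence$target_deg + err),
             is_random = sequence$is_random)
}

# Time-varying bias amplitude over normalized movement time: a decaying
# repulsive logistic plus a rising attractive logistic, with the attractive
# amplitude solved so the profile ends exactly at alpha_end.
alpha_eff_profile <- function(s, alpha_end, prof) {
  if (is.null(prof)) return(rep(alpha_end, length(s)))
  L <- function(u, mid, scale) plogis((u - mid) / scale)
  rep_part <- function(u) prof$rep_amp * (1 - L(u, prof$rep_mid, prof$rep_scale))
  att_amp <- (alpha_end - rep_part(1)) / L(1, prof$att_mid, prof$att_scale)
  rep_part(s) + att_amp * L(s, prof$att_mid, prof$att_scale)
}

#' Simulate one mouse trajectory
#'
#' The cursor rests at the screen center, starts moving after `latency_ms`,
#' and progresses radially toward the color wheel while its angular position
#' follows the target plus the time-varying DoG bias
#' `dog(x; alpha_eff(s), w_true)` plus a linear ramp `s * resid` carrying the
#' trial's idiosyncratic response noise, so the final click lands exactly on
#' `target + dog(x; alpha_end) + resid` when motor noise is off.
#'
#' @param target Target wheel angle in degrees.
#' @param rel_color Relative color of the previous trial (degrees), or `NA`
#'   if undefined; `NA` suppresses the history bias.
#' @param config A [sim_config()].
#' @param report_type Report type selecting the default bias profile.
#' @param alpha_end Amplitude the profile must reach at the click; defaults
#'   to `config$alpha_true[report_type]`.
#' @param onset_group `"early"` or `"late"`; selects the profile variant.
#'   Defaults to whether `latency_ms` exceeds the latency distribution's
#'   median.
#' @param latency_ms Movement-onset latency; drawn from the configured
#'   log-normal when `NULL`.
#' @param move_ms Movement duration; drawn when `NULL`.
#' @param resid Trial-level angular residual (degrees) reached at the click.
#' @param motor_noise_sd Per-sample Gaussian pixel noise; defaults to the
#'   configured value.
#' @return Data frame `timestamp_ms`, `x_px`, `y_px` (origin at screen
#'   center, y up), with attributes `latency_ms` and `onset_group`.
#' @export
simulate_trajectory <- function(target, rel_color, config = sim_config(),
                                report_type = "consolidation",
                                alpha_end = NULL, onset_group = NULL,
                                latency_ms = NULL, move_ms = NULL,
                                resid = 0, motor_noise_sd = NULL) {
  report_type <- match.arg(report_type, REPORT_TYPES)
  tr <- config$trajectory
  if (is.null(alpha_end)) alpha_end <- unname(config$alpha_true[report_type])
  if (is.null(latency_ms))
    latency_ms <- rlnorm(1, config$onset_latency$meanlog,
                         config$onset_latency$sdlog)
  if (is.null(onset_group))
    onset_group <- if (latency_ms > exp(config$onset_latency$meanlog))
      "late" else "early"
  onset_group <- match.arg(onset_group, c("early", "late"))
  if (is.null(move_ms))
    move_ms <- rlnorm(1, config$movement$meanlog, config$movement$sdlog)
  if (is.null(motor_noise_sd)) motor_noise_sd <- tr$motor_noise_sd_px

  prof <- tr$profiles[[report_type]][[onset_group]]
  s <- seq_len(tr$n_move_samples) / tr$n_move_samples
  bias <- if (is.na(rel_color)) rep(0, length(s)) else
    dog(rel_color, alpha_eff_profile(s, alpha_end, prof), config$w_true, 0)
  g <- bias + s * resid
  r <- tr$wheel_radius_px * s^tr$radial_exp
  theta <- (target + g) * pi / 180
  pre_t <- seq(0, latency_ms, by = tr$sample_ms)
  n_pre <- length(pre_t)
  xs <- c(rep(0, n_pre), r * sin(theta))
  ys <- c(rep(0, n_pre), r * cos(theta))
  if (motor_noise_sd > 0) {
    idx <- (n_pre + 1L):length(xs)
    xs[idx] <- xs[idx] + rnorm(length(idx), 0, motor_noise_sd)
    ys[idx] <- ys[idx] + rnorm(length(idx), 0, motor_noise_sd)
  }
  out <- data.frame(timestamp_ms = c(pre_t, latency_ms + s * move_ms),
                    x_px = xs, y_px = ys)
  attr(out, "latency_ms") <- latency_ms
  attr(out, "onset_group") <- onset_group
  out
}

#' Simulate a complete experiment
#'
#' Per participant: one perceptual-matching task (one report per trial) and
#' one delayed working-memory task (a consolidation and a retrieval report
#' per trial, sharing targets). A participant-level amplitude offset, drawn
#' once and added to all three report types, induces correlated individual
#' biases. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param trajectories Generate mouse trajectories? Disable for speed when
#'   only report errors are analyzed.
#' @return An object of class `"serial_sim"`: list with `trials` (one row
#'   per report), `trajectories` (long format, one row per cursor sample;
#'   `NULL` if disabled), `latencies` (generating onset latency per
#'   report), `truth_alphas` (the realized per-participant generating
#'   amplitudes, for recovery checks), and `config`.
#' @export
simulate_experiment <- function(config = sim_config(), trajectories = TRUE) {
  set.seed(config$seed)
  trial_parts <- list()
  traj_parts <- list()
  lat_parts <- list()
  truth_parts <- list()

  one_traj <- function(pid, row, report_type, alpha_cell) {
    x <- if (is.na(row$prev_target_deg)) NA else
      signed_difference(row$prev_target_deg, row$target_deg)
    err <- signed_difference(row$response_deg, row$target_deg)
    mean_bias <- if (is.na(x)) config$beta_true else
      dog(x, alpha_cell, config$w_true, config$beta_true)
    tj <- simulate_trajectory(row$target_deg, x, config, report_type,
                              alpha_end = alpha_cell,
                              resid = err - mean_bias)
    tj$participant <- pid
    tj$trial_index <- row$trial_index
    tj$report_type <- report_type
    tj$target_deg <- row$target_deg
    tj
  }

  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", p)
    a_i <- rnorm(1, 0, config$alpha_participant_sd)

    seq_perc <- generate_target_sequence(config$n_perceptual_trials,
                                         config$random_trial_period)
    seq_wm <- generate_target_sequence(config$n_wm_trials,
                                       config$random_trial_period)
    blocks <- list(
      simulate_errors(seq_perc, "perceptual", config,
                      alpha = unname(config$alpha_true["perceptual"]) + a_i),
      simulate_errors(seq_wm, "consolidation", config,
                      alpha = unname(config$alpha_true["consolidation"]) + a_i),
      simulate_errors(seq_wm, "retrieval", config,
                      alpha = unname(config$alpha_true["retrieval"]) + a_i))
    alphas <- unname(config$alpha_true[REPORT_TYPES]) + a_i
    names(alphas) <- REPORT_TYPES
    truth_parts[[p]] <- data.frame(participant = pid, t(alphas))

    for (b in blocks) {
      b$participant <- pid
      trial_parts[[length(trial_parts) + 1L]] <-
        b[c("participant", setdiff(names(b), "participant"))]
      if (trajectories) {
        tjs <- lapply(seq_len(nrow(b)), function(i)
          one_traj(pid, b[i, ], b$report_type[1], alphas[[b$report_type[1]]]))
        lat_parts[[length(lat_parts) + 1L]] <- data.frame(
          participant = pid, trial_index = b$trial_index,
          report_type = b$report_type[1],
          latency_ms = vapply(tjs, attr, numeric(1), "latency_ms"),
          onset_group = vapply(tjs, attr, character(1), "onset_group"))
        traj_parts[[length(traj_parts) + 1L]] <- do.call(rbind, tjs)
      }
    }
  }

  trials <- do.call(rbind, trial_parts)
  rownames(trials) <- NULL
  trajs <- NULL
  lats <- NULL
  if (trajectories) {
    trajs <- do.call(rbind, traj_parts)
    trajs <- trajs[c("participant", "trial_index", "report_type",
                     "timestamp_ms", "x_px", "y_px", "target_deg")]
    rownames(trajs) <- NULL
    lats <- do.call(rbind, lat_parts)
    rownames(lats) <- NULL
  }
  truth <- do.call(rbind, truth_parts)
  rownames(truth) <- NULL
  structure(list(trials = trials, trajectories = trajs, latencies = lats,
                 truth_alphas = truth, config = config),
            class = "serial_sim")
}

#' @export
print.serial_sim <- function(x, ...) {
  cat("Simulated serial-dependence experiment\n")
  cat(sprintf("  %d participants, %d report rows (%s)\n",
              length(unique(x$trials$participant)), nrow(x$trials),
              paste(unique(x$trials$report_type), collapse = ", ")))
  if (!is.null(x$trajectories))
    cat(sprintf("  %d trajectory samples across %d responses\n",
                nrow(x$trajectories), nrow(x$latencies)))
  cat(sprintf("  seed %d; true amplitudes: %s\n", x$config$seed,
              paste(sprintf("%s %+0.2f", names(x$config$alpha_true),
                            x$config$alpha_true), collapse = ", ")))
  invisible(x)
}
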