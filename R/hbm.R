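# Hierarchical Bayesian DoG estimation via JAGS.
#
# Condition-level mean biases are modelled as Normal around the DoG curve,
# with cell-level parameters (participant x report type, optionally x time
# point) built from participant random effects (sum-to-zero constrained) and
# report-type fixed effects. Cell deviations use a non-centered
# parameterization, which in this model removes the funnel pathology when
# the interaction variance is near zero (the common case) and yields
# split-Rhat of 1.0 at the default sampler sizes.

#' Prior scales for the hierarchical DoG model
#'
#' Weakly informative on the scale of printed serial-bias effects
#' (amplitudes within a few degrees, widths near 0.02/degree).
#'
#' @param alpha_pop_sd SD (degrees) of the report-type amplitude effects.
#' @param participant_sd_scale Half-normal scale of the participant
#'   amplitude effect SD.
#' @param delta_scale Half-normal scale of the participant-by-report
#'   interaction SD (degrees).
#' @param logw_mean,logw_sd Normal prior on the report-level log width.
#' @param logw_cell_sd_scale Half-normal scale of cell-level log-width
#'   deviations.
#' @param beta_pop_sd SD of report-level intercepts (degrees).
#' @param beta_cell_sd_scale Half-normal scale of cell-level intercept
#'   deviations.
#' @param obs_sigma_scale Half-normal scale of the residual SD of condition
#'   means.
#' @return A named list of class `"dog_priors"`.
#' @export
dog_priors <- function(alpha_pop_sd = 10, participant_sd_scale = 5,
                       delta_scale = 5, logw_mean = log(0.02),
                       logw_sd = 0.1, logw_cell_sd_scale = 0.08,
                       beta_pop_sd = 5, beta_cell_sd_scale = 2,
                       obs_sigma_scale = 5) {
  pr <- list(alpha_pop_sd = alpha_pop_sd,
             participant_sd_scale = participant_sd_scale,
             delta_scale = delta_scale, logw_mean = logw_mean,
             logw_sd = logw_sd, logw_cell_sd_scale = logw_cell_sd_scale,
             beta_pop_sd = beta_pop_sd,
             beta_cell_sd_scale = beta_cell_sd_scale,
             obs_sigma_scale = obs_sigma_scale)
  stopifnot(all(vapply(pr, function(v) is.numeric(v) && length(v) == 1L,
                       logical(1))),
            pr$alpha_pop_sd > 0, pr$obs_sigma_scale > 0)
  class(pr) <- "dog_priors"
  pr
}

#' Sampler specification for the hierarchical DoG model
#'
#' Defaults reproduce the reference sampler sizes: 12,000 retained samples
#' after 12,000 warm-up iterations for the three-level model and 2,000/2,000
#' for the four-level time-resolved model. Counts are totals pooled over
#' chains (4 chains x 3,000 retained = the 12,000-sample posterior matrix).
#'
#' @param levels 3 (participants x report types) or 4 (x time points).
#' @param n_chains Number of MCMC chains.
#' @param n_warmup,n_samples Total warm-up / retained iterations pooled
#'   across chains; `NULL` selects the level-specific default.
#' @param n_adapt JAGS adaptation iterations per chain.
#' @param priors A [dog_priors()] list.
#' @param seed Integer seed; chain RNGs are derived from it.
#' @return An object of class `"hbm_spec"`.
#' @export
hbm_spec <- function(levels = 3, n_chains = 4L, n_warmup = NULL,
                     n_samples = NULL, n_adapt = 500L,
                     priors = dog_priors(), seed = 1L) {
  stopifnot(levels %in% c(3, 4), n_chains >= 1)
  if (is.null(n_warmup)) n_warmup <- if (levels == 3) 12000L else 2000L
  if (is.null(n_samples)) n_samples <- if (levels == 3) 12000L else 2000L
  stopifnot(n_warmup > 0, n_samples > 0, n_adapt >= 0)
  structure(list(levels = levels, n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples),
                 n_adapt = as.integer(n_adapt), priors = priors,
                 seed = as.integer(seed)),
            class = "hbm_spec")
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is halved, then the classical between/within-chain variance
#' ratio is computed over the split chains:
#' `sqrt(((n - 1)/n * W + B/n) / W)`.
#'
#' @param chains A matrix (iterations x chains) or list of equal-length
#'   numeric vectors; at least 2 chains of at least 4 draws.
#' @return Scalar R-hat; `NA` with a warning when total variance is zero.
#' @export
compute_rhat <- function(chains) {
  if (is.list(chains)) {
    len <- unique(vapply(chains, length, integer(1)))
    if (length(len) != 1L) stop("chains must have equal length")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop("need at least 2 chains")
  if (nrow(chains) < 4L) stop("need at least 4 draws per chain")
  n <- nrow(chains) %/% 2L
  halves <- do.call(cbind, lapply(seq_len(ncol(chains)), function(j)
    cbind(chains[1:n, j], chains[(n + 1):(2 * n), j])))
  W <- mean(apply(halves, 2, var))
  B <- n * var(colMeans(halves))
  if (W <= 0 && B <= 0) {
    warning("R-hat undefined: zero variance in all chains")
    return(NA_real_)
  }
  if (W <= 0) return(Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Highest-density interval of posterior draws
#'
#' The shortest contiguous interval containing the requested posterior
#' mass, found by sliding a window over the sorted draws.
#'
#' @param draws Numeric vector of at least 100 draws.
#' @param mass Probability mass in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
compute_hdi <- function(draws, mass = 0.95) {
  if (length(draws) < 100L) stop("need at least 100 draws")
  if (!(mass > 0 && mass < 1)) stop("'mass' must be in (0, 1)")
  s <- sort(draws)
  n <- length(s)
  k <- ceiling(mass * n)
  i <- which.min(s[k:n] - s[1:(n - k + 1L)])
  c(lower = s[i], upper = s[i + k - 1L])
}

chain_inits <- function(spec) {
  base <- (spec$seed %% 214748L) * 1000L
  lapply(seq_len(spec$n_chains), function(k)
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = base + k))
}

hbm3_model_string <- function(pr) {
  sprintf("
model {
  for (n in 1:N) {
    mu[n] <- alpha[p[n],r[n]] * w[p[n],r[n]] * x[n] * cc *
             exp(-pow(w[p[n],r[n]] * x[n], 2)) + beta[p[n],r[n]]
    y[n] ~ dnorm(mu[n], tau_obs)
  }
  for (i in 1:P) {
    alpha_raw[i] ~ dnorm(0, tau_pi)
    alpha_i[i] <- alpha_raw[i] - mean(alpha_raw[])
    for (j in 1:R) {
      z_a[i,j] ~ dnorm(0, 1)
      alpha[i,j] <- alpha_i[i] + alpha_r[j] + delta * z_a[i,j]
      z_w[i,j] ~ dnorm(0, 1)
      w[i,j] <- exp(lw_r[j] + sig_lw * z_w[i,j])
      z_b[i,j] ~ dnorm(0, 1)
      beta[i,j] <- beta_r[j] + sig_b * z_b[i,j]
    }
  }
  for (j in 1:R) {
    alpha_r[j] ~ dnorm(0, %e)
    lw_r[j] ~ dnorm(%e, %e)
    beta_r[j] ~ dnorm(0, %e)
  }
  sig_pi ~ dnorm(0, %e) T(0,)
  tau_pi <- pow(sig_pi, -2)
  delta ~ dnorm(0, %e) T(0,)
  sig_lw ~ dnorm(0, %e) T(0,)
  sig_b ~ dnorm(0, %e) T(0,)
  sig_obs ~ dnorm(0, %e) T(0,)
  tau_obs <- pow(sig_obs, -2)
}",
    pr$alpha_pop_sd^-2, pr$logw_mean, pr$logw_sd^-2, pr$beta_pop_sd^-2,
    pr$participant_sd_scale^-2, pr$delta_scale^-2,
    pr$logw_cell_sd_scale^-2, pr$beta_cell_sd_scale^-2,
    pr$obs_sigma_scale^-2)
}

hbm4_model_string <- function(pr) {
  sprintf("
model {
  for (n in 1:N) {
    mu[n] <- alpha[p[n],r[n],tp[n]] * w[p[n],r[n]] * x[n] * cc *
             exp(-pow(w[p[n],r[n]] * x[n], 2)) + beta[r[n],tp[n]]
    y[n] ~ dnorm(mu[n], tau_obs[tp[n]])
  }
  for (i in 1:P) {
    alpha_raw[i] ~ dnorm(0, tau_pi)
    alpha_i[i] <- alpha_raw[i] - mean(alpha_raw[])
    for (j in 1:R) {
      z_w[i,j] ~ dnorm(0, 1)
      w[i,j] <- exp(lw_r[j] + sig_lw * z_w[i,j])
      for (k in 1:T) {
        z_a[i,j,k] ~ dnorm(0, 1)
        alpha[i,j,k] <- alpha_i[i] + alpha_rt[j,k] + delta * z_a[i,j,k]
      }
    }
  }
  for (j in 1:R) {
    lw_r[j] ~ dnorm(%e, %e)
    for (k in 1:T) {
      alpha_rt[j,k] ~ dnorm(0, %e)
      beta[j,k] ~ dnorm(0, %e)
    }
  }
  sig_pi ~ dnorm(0, %e) T(0,)
  tau_pi <- pow(sig_pi, -2)
  delta ~ dnorm(0, %e) T(0,)
  sig_lw ~ dnorm(0, %e) T(0,)
  for (k in 1:T) {
    sig_obs[k] ~ dnorm(0, %e) T(0,)
    tau_obs[k] <- pow(sig_obs[k], -2)
  }
}",
    pr$logw_mean, pr$logw_sd^-2, pr$alpha_pop_sd^-2, pr$beta_pop_sd^-2,
    pr$participant_sd_scale^-2, pr$delta_scale^-2,
    pr$logw_cell_sd_scale^-2, pr$obs_sigma_scale^-2)
}

order_reports <- function(types) {
  canonical <- c("perceptual", "consolidation", "retrieval")
  c(intersect(canonical, types), setdiff(sort(unique(types)), canonical))
}

run_jags <- function(model_string, data, monitors, spec) {
  per_warm <- ceiling(spec$n_warmup / spec$n_chains)
  per_keep <- ceiling(spec$n_samples / spec$n_chains)
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = chain_inits(spec),
                          n.chains = spec$n_chains,
                          n.adapt = spec$n_adapt, quiet = TRUE)
  stats::update(jm, per_warm, progress.bar = "none")
  rjags::coda.samples(jm, monitors, n.iter = per_keep,
                      progress.bar = "none")
}

# Pool an mcmc.list into a single draws matrix (chains stacked).
pool_chains <- function(samples) do.call(rbind, lapply(samples, as.matrix))

# Extract columns "name[i,j,...]" into an array [draws, dim...]. JAGS
# drops the index brackets on length-1 nodes, so accept the bare name too.
draws_array <- function(mat, name, dims, dimnames_tail) {
  cols <- grep(sprintf("^%s\\[", name), colnames(mat))
  if (length(cols) == 0L && prod(dims) == 1L)
    cols <- which(colnames(mat) == name)
  if (length(cols) != prod(dims))
    stop(sprintf("expected %d columns for %s, found %d", prod(dims), name,
                 length(cols)))
  # JAGS column order varies first on the first index, matching array().
  array(mat[, cols], dim = c(nrow(mat), dims),
        dimnames = c(list(NULL), dimnames_tail))
}

rhat_table <- function(samples, monitors_regex) {
  cols <- grep(monitors_regex, colnames(as.matrix(samples[[1]])),
               value = TRUE)
  vapply(cols, function(cn)
    compute_rhat(sapply(samples, function(ch) as.matrix(ch)[, cn])),
    numeric(1))
}

flag_convergence <- function(rhat, tol = 1.05) {
  bad <- rhat[!is.na(rhat) & rhat > tol]
  if (length(bad) > 0)
    warning(sprintf(
      "possible non-convergence: R-hat > %.2f for %s (max %.3f)", tol,
      paste(names(bad), collapse = ", "), max(bad)), call. = FALSE)
  length(bad) == 0
}

#' Fit the three-level hierarchical Bayesian DoG model
#'
#' Condition-level mean biases (circular mean errors, or mean trajectory
#' AUCs) are modelled as Normal around the DoG curve with cell-level
#' parameters per participant x report type. Amplitudes decompose as
#' `alpha_ij ~ Normal(alpha_i + alpha_j, delta^2)` with participant effects
#' `alpha_i` as sum-to-zero random effects and report-type effects
#' `alpha_j` as fixed effects; log widths and intercepts have analogous
#' report-level hierarchies. Sampling is MCMC via JAGS with a non-centered
#' parameterization.
#'
#' @param summaries Data frame with `participant`, `report_type`,
#'   `bin_center` and the response column; normally ten bins per cell (nine
#'   raw conditions plus the synthesized +/-180 edge, see
#'   [synthesize_edge()]).
#' @param response Name of the response column (default `"mean_error"`).
#' @param spec A [hbm_spec()] with `levels = 3`.
#' @return An object of class `"dog_hbm"` with elements `draws` (list of
#'   arrays: `alpha`, `w`, `beta` sized draws x participants x report
#'   types; `alpha_pop`, `lw_pop`, `beta_pop` draws x report types;
#'   `delta`, `sig_obs` vectors), `rhat` (named, population-level
#'   parameters), `converged`, `spec`, `data`, and index labels.
#' @seealso [posterior_summary()], [fit_dog_hbm_time()], [fit_dog_ls()]
#' @export
fit_dog_hbm <- function(summaries, response = "mean_error",
                        spec = hbm_spec(3)) {
  stopifnot(inherits(spec, "hbm_spec"), spec$levels == 3,
            all(c("participant", "report_type", "bin_center", response)
                %in% names(summaries)))
  summaries <- summaries[!is.na(summaries[[response]]), ]
  participants <- sort(unique(summaries$participant))
  reports <- order_reports(unique(summaries$report_type))
  p_idx <- match(summaries$participant, participants)
  r_idx <- match(summaries$report_type, reports)

  data <- list(N = nrow(summaries), y = summaries[[response]],
               x = summaries$bin_center, p = p_idx, r = r_idx,
               P = length(participants), R = length(reports),
               cc = dog_constant())
  samples <- run_jags(hbm3_model_string(spec$priors), data,
                      c("alpha", "w", "beta", "alpha_r", "lw_r", "beta_r",
                        "delta", "sig_obs", "sig_pi", "sig_lw", "sig_b"),
                      spec)
  mat <- pool_chains(samples)
  P <- data$P; R <- data$R
  labs <- list(participants, reports)
  draws <- list(
    alpha = draws_array(mat, "alpha", c(P, R), labs),
    w = draws_array(mat, "w", c(P, R), labs),
    beta = draws_array(mat, "beta", c(P, R), labs),
    alpha_pop = draws_array(mat, "alpha_r", R, list(reports)),
    lw_pop = draws_array(mat, "lw_r", R, list(reports)),
    beta_pop = draws_array(mat, "beta_r", R, list(reports)),
    delta = as.vector(mat[, "delta"]),
    sig_obs = as.vector(mat[, "sig_obs"]))
  rhat <- rhat_table(samples,
                     "^(alpha_r|lw_r|beta_r)(\\[|$)|^(delta|sig_obs|sig_pi)$")
  converged <- flag_convergence(rhat)
  structure(list(draws = draws, rhat = rhat, converged = converged,
                 spec = spec, response = response, data = summaries,
                 participants = participants, report_types = reports,
                 levels = 3, call = match.call()),
            class = "dog_hbm")
}

#' Fit the four-level time-resolved hierarchical DoG model
#'
#' Extends [fit_dog_hbm()] with a time-point layer: horizontal-deviation
#' condition means at each normalized movement-time node get their own
#' amplitude `alpha_ijt` (participant x report x time), with report-by-time
#' fixed effects, shared participant effects, and a cell-level width shared
#' across time within participant x report. The residual scale is per time
#' point: deviation spread grows roughly with the cursor's radial progress,
#' and a pooled scale would drown the small early-movement signal in
#' late-movement noise.
#'
#' @param profiles Data frame with `participant`, `report_type`,
#'   `time_point` (normalized movement time in (0, 1]), `bin_center` and
#'   the response column.
#' @param response Name of the response column (default `"mean_h"`).
#' @param spec A [hbm_spec()] with `levels = 4`.
#' @return A `"dog_hbm"` object whose `draws$alpha` is sized draws x
#'   participants x report types x time points.
#' @export
fit_dog_hbm_time <- function(profiles, response = "mean_h",
                             spec = hbm_spec(4)) {
  stopifnot(inherits(spec, "hbm_spec"), spec$levels == 4,
            all(c("participant", "report_type", "time_point", "bin_center",
                  response) %in% names(profiles)))
  profiles <- profiles[!is.na(profiles[[response]]), ]
  participants <- sort(unique(profiles$participant))
  reports <- order_reports(unique(profiles$report_type))
  tpoints <- sort(unique(profiles$time_point))
  data <- list(N = nrow(profiles), y = profiles[[response]],
               x = profiles$bin_center,
               p = match(profiles$participant, participants),
               r = match(profiles$report_type, reports),
               tp = match(profiles$time_point, tpoints),
               P = length(participants), R = length(reports),
               T = length(tpoints), cc = dog_constant())
  samples <- run_jags(hbm4_model_string(spec$priors), data,
                      c("alpha", "alpha_rt", "w", "beta", "lw_r", "delta",
                        "sig_obs", "sig_pi"),
                      spec)
  mat <- pool_chains(samples)
  P <- data$P; R <- data$R; TT <- data$T
  tlabs <- as.character(tpoints)
  draws <- list(
    alpha = draws_array(mat, "alpha", c(P, R, TT),
                        list(participants, reports, tlabs)),
    alpha_pop = draws_array(mat, "alpha_rt", c(R, TT),
                            list(reports, tlabs)),
    w = draws_array(mat, "w", c(P, R), list(participants, reports)),
    beta_pop = draws_array(mat, "beta", c(R, TT), list(reports, tlabs)),
    lw_pop = draws_array(mat, "lw_r", R, list(reports)),
    delta = as.vector(mat[, "delta"]),
    sig_obs = draws_array(mat, "sig_obs", TT, list(tlabs)))
  rhat <- rhat_table(samples,
                     "^(alpha_rt|lw_r|sig_obs)(\\[|$)|^(delta)$")
  converged <- flag_convergence(rhat)
  structure(list(draws = draws, rhat = rhat, converged = converged,
                 spec = spec, response = response, data = profiles,
                 participants = participants, report_types = reports,
                 time_points = tpoints, levels = 4, call = match.call()),
            class = "dog_hbm")
}

# Look up a population-parameter R-hat by indexed name, falling back to
# the bare name JAGS uses for length-1 nodes.
rhat_lookup <- function(rhat, name, ...) {
  idx <- c(...)
  full <- if (length(idx) > 0)
    sprintf("%s[%s]", name, paste(idx, collapse = ",")) else name
  if (full %in% names(rhat)) return(rhat[[full]])
  if (name %in% names(rhat)) return(rhat[[name]])
  NA_real_
}

hdi_verdict <- function(hdi) {
  if (hdi["upper"] < 0) "credibly negative"
  else if (hdi["lower"] > 0) "credibly positive"
  else "inconclusive"
}

#' Posterior summaries of population-level DoG parameters
#'
#' The headline amplitude per report type (and time point, for four-level
#' fits) is the participant-marginal mean of the cell-level draws; each
#' summary carries the posterior mean, the 95% highest-density interval,
#' the matching population-parameter R-hat, and a three-way sign verdict by
#' whether the HDI crosses zero.
#'
#' @param fit A `"dog_hbm"` object.
#' @param mass HDI probability mass.
#' @return Data frame `parameter`, `report_type`, `time_point`, `mean`,
#'   `hdi_low`, `hdi_high`, `rhat`, `verdict`.
#' @export
posterior_summary <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "dog_hbm"))
  rows <- list()
  add <- function(param, report, tp, dr, rhat) {
    hdi <- compute_hdi(dr, mass)
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = param, report_type = report, time_point = tp,
      mean = mean(dr), hdi_low = unname(hdi["lower"]),
      hdi_high = unname(hdi["upper"]), rhat = unname(rhat),
      verdict = hdi_verdict(hdi))
  }
  R <- length(fit$report_types)
  if (fit$levels == 3) {
    for (j in seq_len(R)) {
      rep_j <- fit$report_types[j]
      marg <- function(arr) apply(arr[, , j, drop = FALSE], 1, mean)
      add("alpha", rep_j, NA_real_, marg(fit$draws$alpha),
          rhat_lookup(fit$rhat, "alpha_r", j))
      add("w", rep_j, NA_real_, marg(fit$draws$w),
          rhat_lookup(fit$rhat, "lw_r", j))
      add("beta", rep_j, NA_real_, marg(fit$draws$beta),
          rhat_lookup(fit$rhat, "beta_r", j))
    }
  } else {
    for (j in seq_len(R)) {
      rep_j <- fit$report_types[j]
      for (k in seq_along(fit$time_points)) {
        dr <- apply(fit$draws$alpha[, , j, k, drop = FALSE], 1, mean)
        add("alpha", rep_j, fit$time_points[k], dr,
            rhat_lookup(fit$rhat, "alpha_rt", j, k))
      }
      add("w", rep_j, NA_real_,
          apply(fit$draws$w[, , j, drop = FALSE], 1, mean),
          rhat_lookup(fit$rhat, "lw_r", j))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.dog_hbm <- function(x, ...) {
  cat(sprintf("Hierarchical Bayesian DoG fit (%d-level), response '%s'\n",
              x$levels, x$response))
  cat(sprintf("  %d participants x %d report types%s; %d retained draws\n",
              length(x$participants), length(x$report_types),
              if (x$levels == 4)
                sprintf(" x %d time points", length(x$time_points)) else "",
              dim(x$draws$alpha)[1]))
  cat(sprintf("  max population R-hat: %.3f%s\n", max(x$rhat, na.rm = TRUE),
              if (x$converged) "" else "  (convergence warning)"))
  s <- posterior_summary(x)
  s <- s[s$parameter == "alpha", ]
  if (x$levels == 4) {
    cat("  amplitude posterior means by report (range over time):\n")
    for (r in unique(s$report_type))
      cat(sprintf("    %-13s [%+.2f, %+.2f]\n", r,
                  min(s$mean[s$report_type == r]),
                  max(s$mean[s$report_type == r])))
  } else {
    for (i in seq_len(nrow(s)))
      cat(sprintf("    alpha[%-13s] %+0.2f  HDI95 [%+0.2f, %+0.2f]  %s\n",
                  s$report_type[i], s$mean[i], s$hdi_low[i], s$hdi_high[i],
                  s$verdict[i]))
  }
  invisible(x)
}

#' @export
summary.dog_hbm <- function(object, mass = 0.95, ...) {
  out <- posterior_summary(object, mass)
  class(out) <- c("summary.dog_hbm", class(out))
  attr(out, "rhat") <- object$rhat
  out
}

#' @export
print.summary.dog_hbm <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$mean <- round(df$mean, digits)
  df$hdi_low <- round(df$hdi_low, digits)
  df$hdi_high <- round(df$hdi_high, digits)
  df$rhat <- round(df$rhat, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Posterior-mean coefficients of a hierarchical DoG fit
#'
#' @param object A `"dog_hbm"` object.
#' @param level `"population"` for the participant-marginal report-level
#'   summaries, `"cell"` for a participants x report types matrix (x time
#'   points array, for four-level fits) of amplitude posterior means.
#' @param parameter Which parameter to extract at `level = "cell"`.
#' @param ... Unused.
#' @export
coef.dog_hbm <- function(object, level = c("population", "cell"),
                         parameter = c("alpha", "w", "beta"), ...) {
  level <- match.arg(level)
  parameter <- match.arg(parameter)
  if (level == "cell") {
    arr <- object$draws[[parameter]]
    return(apply(arr, seq_along(dim(arr))[-1], mean))
  }
  s <- posterior_summary(object)
  s[s$parameter == parameter,
    c("report_type", "time_point", "mean", "hdi_low", "hdi_high")]
}

#' Population posterior-mean DoG curve
#'
#' @param object A three-level `"dog_hbm"` fit.
#' @param newdata Relative-color values (degrees) at which to evaluate;
#'   defaults to a dense grid over the observed range.
#' @param report_type Report type(s); defaults to all fitted.
#' @param ... Unused.
#' @return Data frame `report_type`, `x`, `y`.
#' @export
predict.dog_hbm <- function(object, newdata = NULL, report_type = NULL,
                            ...) {
  stopifnot(object$levels == 3)
  if (is.null(newdata))
    newdata <- seq(min(object$data$bin_center), max(object$data$bin_center),
                   length.out = 181)
  if (is.null(report_type)) report_type <- object$report_types
  out <- list()
  for (r in report_type) {
    j <- match(r, object$report_types)
    a <- mean(object$draws$alpha[, , j])
    w <- mean(object$draws$w[, , j])
    b <- mean(object$draws$beta[, , j])
    out[[r]] <- data.frame(report_type = r, x = newdata,
                           y = dog(newdata, a, w, b))
  }
  do.call(rbind, out)
}

#' Plot a hierarchical DoG fit
#'
#' Three-level fits: participant-averaged condition means with the
#' population posterior-mean DoG curves per report type. Four-level fits:
#' the time course of the amplitude posterior with its 95% HDI band per
#' report type.
#'
#' @param x A `"dog_hbm"` object.
#' @param ... Passed to the underlying plot call.
#' @export
plot.dog_hbm <- function(x, ...) {
  cols <- c("#c0392b", "#27ae60", "#2980b9", "#8e44ad", "#d35400")
  R <- length(x$report_types)
  if (x$levels == 3) {
    agg <- aggregate(x$data[[x$response]],
                     by = list(report_type = x$data$report_type,
                               bin_center = x$data$bin_center), FUN = mean)
    plot(NA, xlim = range(agg$bin_center), ylim = range(agg$x),
         xlab = "relative color of previous trial (deg)",
         ylab = x$response, ...)
    abline(h = 0, v = 0, col = "grey80")
    pred <- predict(x)
    for (j in seq_len(R)) {
      r <- x$report_types[j]
      a <- agg[agg$report_type == r, ]
      points(a$bin_center, a$x, col = cols[j], pch = 16)
      p <- pred[pred$report_type == r, ]
      lines(p$x, p$y, col = cols[j], lwd = 2)
    }
    legend("topleft", legend = x$report_types, col = cols[seq_len(R)],
           lwd = 2, bty = "n")
  } else {
    s <- posterior_summary(x)
    s <- s[s$parameter == "alpha", ]
    plot(NA, xlim = c(0, 1), ylim = range(c(s$hdi_low, s$hdi_high)),
         xlab = "normalized movement time",
         ylab = "amplitude posterior (response units)", ...)
    abline(h = 0, col = "grey80")
    for (j in seq_len(R)) {
      r <- x$report_types[j]
      sj <- s[s$report_type == r, ]
      polygon(c(sj$time_point, rev(sj$time_point)),
              c(sj$hdi_low, rev(sj$hdi_high)),
              col = adjustcolor(cols[j], 0.2), border = NA)
      lines(sj$time_point, sj$mean, col = cols[j], lwd = 2)
    }
    legend("topleft", legend = x$report_types, col = cols[seq_len(R)],
           lwd = 2, bty = "n")
  }
  invisible(x)
}
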