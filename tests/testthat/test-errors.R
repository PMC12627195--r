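make_trials <- function(prev, target, response, random = FALSE,
                        participant = "P01", report = "consolidation") {
  n <- max(length(prev), length(target), length(response))
  data.frame(participant = participant, task = "wm", report_type = report,
             trial_index = seq_len(n), target_deg = rep_len(target, n),
             prev_target_deg = rep_len(prev, n),
             response_deg = rep_len(response, n),
             is_random = rep_len(random, n))
}

test_that("response error is the signed distance from the target", {
  expect_equal(compute_error(100, 90), 10)
  expect_equal(compute_error(5, 355), 10)
  expect_equal(compute_error(90, 90), 0)
  expect_error(compute_error(NA, 90), "missing")
})

test_that("condition assignment follows the previous-relative-to-current convention", {
  tr <- make_trials(prev = c(36, 324, NA), target = 0, response = 0)
  expect_equal(assign_condition(tr), c(36, -36, NA))
  expect_equal(assign_condition(tr, convention = "current_minus_prev"),
               c(-36, 36, NA))
  # random trials are excluded whatever their offset
  tr_rand <- make_trials(prev = 17, target = 0, response = 0, random = TRUE)
  expect_true(is.na(assign_condition(tr_rand)))
  # off-grid offsets on non-random trials are a data-integrity error
  tr_off <- make_trials(prev = 17, target = 0, response = 0)
  expect_error(assign_condition(tr_off), "off the 36-degree grid")
})

test_that("condition summaries reproduce noiseless DoG values and circular means", {
  set.seed(20)
  seq1 <- generate_target_sequence(150, 10)
  tr <- simulate_errors(seq1, "consolidation", sim_config(kappa = 1e9),
                        alpha = 2)
  tr$participant <- "P01"
  summ <- summarize_conditions(tr)
  expect_equal(nrow(summ), 9)
  expect_true(all(summ$n > 0))
  expect_equal(summ$mean_error, dog(summ$bin_center, 2, 0.02, 0),
               tolerance = 1e-3)

  # wrap robustness: adding 360 to any angle field changes nothing
  tr2 <- tr
  tr2$target_deg <- tr2$target_deg + 360
  tr2$response_deg <- tr2$response_deg + 360
  summ2 <- suppressWarnings(summarize_conditions(tr2))
  expect_equal(summ2$mean_error, summ$mean_error)

  # circular mean within a bin: errors +170 and -170 average to 180
  pair <- make_trials(prev = 36, target = c(0, 0),
                      response = c(170, 190))
  pair_summ <- suppressWarnings(summarize_conditions(pair))
  expect_equal(pair_summ$mean_error[pair_summ$bin_center == 36], 180)

  # excluding random trials leaves only the nine step conditions
  expect_setequal(unique(summ$bin_center), seq(-144, 144, by = 36))
})

test_that("post-random exclusion drops trials without changing bin centers", {
  set.seed(21)
  seq1 <- generate_target_sequence(300, 10)
  tr <- simulate_errors(seq1, "retrieval", sim_config())
  tr$participant <- "P01"
  strict <- summarize_conditions(tr, exclude_post_random = TRUE)
  lax <- summarize_conditions(tr)
  expect_setequal(unique(strict$bin_center), seq(-144, 144, by = 36))
  expect_lt(sum(strict$n), sum(lax$n))
})

test_that("edge synthesis appends a +/-180 bin averaging the two edges", {
  base <- expand.grid(participant = "P01", report_type = "consolidation",
                      bin_center = seq(-144, 144, by = 36),
                      stringsAsFactors = FALSE)
  base$mean_error <- 0
  base$n <- 10L
  base$mean_error[base$bin_center == -144] <- -1
  base$mean_error[base$bin_center == 144] <- 1
  out <- synthesize_edge(base)
  expect_equal(nrow(out), 10)
  expect_equal(out$mean_error[out$bin_center == 180], 0)

  base$mean_error[base$bin_center == -144] <- 0
  base$mean_error[base$bin_center == 144] <- 2
  expect_equal(synthesize_edge(base)$mean_error[10], 1)
  expect_equal(
    synthesize_edge(base, edge = "flip")$mean_error[10], 1)
  base$mean_error[base$bin_center == -144] <- 0.5
  expect_equal(
    synthesize_edge(base, edge = "flip")$mean_error[10], 0.75)

  expect_error(synthesize_edge(base[base$bin_center != 144, ]),
               "edge bins")
})

test_that("noiseless end-to-end recovery: simulate, summarize, least-squares fit", {
  cfg <- sim_config(n_participants = 2, n_perceptual_trials = 60,
                    n_wm_trials = 90, kappa = 1e6,
                    alpha_participant_sd = 0, seed = 6)
  sim <- simulate_experiment(cfg, trajectories = FALSE)
  summ <- synthesize_edge(summarize_conditions(sim$trials))
  for (rt in c("perceptual", "consolidation", "retrieval")) {
    d <- summ[summ$report_type == rt & summ$participant == "P01", ]
    f <- fit_dog_ls(d$bin_center, d$mean_error)
    expect_lt(abs(coef(f)["alpha"] - cfg$alpha_true[rt]), 0.05)
  }
})

test_that("cross-report amplitude correlations use n - 2 degrees of freedom", {
  a <- data.frame(perceptual = c(1, 2, 3, 4), consolidation = c(2, 4, 6, 8),
                  retrieval = c(1.5, 2.5, 3.5, 4.5))
  out <- correlate_alphas(a)
  expect_equal(out$r, rep(1, 3), tolerance = 1e-12)
  expect_equal(out$df, rep(2L, 3))
  a$retrieval <- c(5, 5, 5, 5)
  expect_warning(out2 <- correlate_alphas(a), "zero variance")
  expect_true(is.na(out2$r[out2$pair == "consolidation:retrieval"]))
  expect_error(correlate_alphas(a[1:2, ]), "at least 3")
  a$retrieval <- c(1, NA, 2, 3)
  expect_error(correlate_alphas(a), "missing")
})
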