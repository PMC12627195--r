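mk_traj <- function(ts, x, y) data.frame(timestamp_ms = ts, x_px = x,
                                         y_px = y)

test_that("movement onset is the first sample strictly beyond the threshold", {
  tr <- mk_traj(c(0, 50, 100, 150, 200), c(0, 5, 10, 15, 30), 0)
  on <- detect_onset(tr)
  expect_equal(on$index, 4)  # 10 px is not > 10
  expect_equal(on$latency_ms, 150)
  # a first sample already beyond threshold is itself the onset
  tr2 <- mk_traj(c(0, 50, 100), c(20, 30, 40), 0)
  expect_equal(detect_onset(tr2)$index, 1)
  # never leaving the threshold circle: unusable
  tr3 <- mk_traj(c(0, 50, 100), c(0, 3, 9), 0)
  expect_false(detect_onset(tr3)$usable)
  # onset on the final sample: unusable (no movement to normalize)
  tr4 <- mk_traj(c(0, 50, 100), c(0, 3, 30), 0)
  expect_false(detect_onset(tr4)$usable)
  expect_error(detect_onset(tr3[1:2, ]), "3 samples")
})

test_that("time normalization interpolates linearly with exact endpoints", {
  tr <- mk_traj(c(0, 100, 300), c(0, 20, 60), c(0, 10, 50))
  nt <- normalize_time(tr, detect_onset(tr), n_grid = 101)
  expect_equal(nt$t, seq(0, 1, length.out = 101))
  expect_equal(c(nt$x[1], nt$y[1]), c(20, 10))    # onset sample
  expect_equal(c(nt$x[101], nt$y[101]), c(60, 50)) # click sample
  expect_equal(nt$x[51], 40)                      # linear midpoint
  expect_equal(nt$y[51], 30)
  # resampling an already-on-grid path is the identity
  grid_tr <- mk_traj(seq(0, 1000, length.out = 101),
                     seq(0, 100, length.out = 101),
                     seq(0, 200, length.out = 101))
  nt2 <- normalize_time(grid_tr, list(index = 1, latency_ms = 0,
                                      usable = TRUE), n_grid = 101)
  expect_equal(nt2$x, grid_tr$x_px)
  expect_equal(nt2$y, grid_tr$y_px)
  same <- mk_traj(c(0, 0, 0), c(0, 20, 40), 0)
  expect_error(normalize_time(same, list(index = 2, latency_ms = 0,
                                         usable = TRUE)), "coincide")
})

test_that("rotation puts the target on the vertical axis and preserves radii", {
  # point on the target ray
  p <- rotate_to_target(50 * sin(pi / 2), 50 * cos(pi / 2), 90)
  expect_equal(p$h, 0, tolerance = 1e-12)
  expect_equal(p$v, 50)
  # point 90 degrees clockwise of the target at radius r
  r <- 70
  p2 <- rotate_to_target(r * sin(pi), r * cos(pi), 90)
  expect_equal(p2$h, r)
  expect_equal(p2$v, 0, tolerance = 1e-12)
  # rigid: radii invariant
  set.seed(30)
  x <- rnorm(50, 0, 100); y <- rnorm(50, 0, 100)
  rot <- rotate_to_target(x, y, 123)
  expect_equal(rot$h^2 + rot$v^2, x^2 + y^2)
})

test_that("AUC variants integrate h(t) and differ by exactly half the endpoint", {
  t <- seq(0, 1, length.out = 101)
  a1 <- compute_auc(list(t = t, h = rep(10, 101)))
  expect_equal(a1$auc_with, 10)
  expect_equal(a1$auc_without, 5)
  a2 <- compute_auc(list(t = t, h = 10 * t))
  expect_equal(a2$auc_with, 5)
  expect_equal(a2$auc_without, 0)
  a3 <- compute_auc(list(t = t, h = 10 * sin(pi * t)))
  expect_equal(a3$auc_with, 20 / pi, tolerance = 1e-3)
  expect_equal(a3$auc_without, a3$auc_with)  # endpoint is zero
  # decomposition identity holds exactly for arbitrary trajectories
  set.seed(31)
  for (i in 1:20) {
    h <- cumsum(rnorm(101))
    a <- compute_auc(list(t = t, h = h))
    expect_equal(a$auc_with - a$auc_without, h[101] / 2,
                 tolerance = 1e-12)
  }
  a4 <- compute_auc(list(t = t, h = rep(10, 101)), scale = 100)
  expect_equal(a4$auc_with, 1000)
})

test_that("mirrored relative colors mirror the whole deviation profile", {
  cfg <- sim_config()
  common <- list(config = cfg, report_type = "consolidation",
                 alpha_end = 1.6, onset_group = "early",
                 latency_ms = 300, move_ms = 700, motor_noise_sd = 0)
  tp <- do.call(simulate_trajectory, c(list(target = 90, rel_color = 72),
                                       common))
  tm <- do.call(simulate_trajectory, c(list(target = 90, rel_color = -72),
                                       common))
  ap <- align_trajectory(tp, 90)
  am <- align_trajectory(tm, 90)
  expect_equal(ap$h, -am$h, tolerance = 1e-9)
  aucp <- compute_auc(ap)
  aucm <- compute_auc(am)
  expect_equal(aucp$auc_with, -aucm$auc_with, tolerance = 1e-9)
  expect_equal(aucp$auc_without, -aucm$auc_without, tolerance = 1e-9)
})

test_that("per-response statistics carry the AUC identity and endpoint node", {
  st <- shared_stats()
  expect_equal(nrow(st), nrow(shared_sim()$trials))
  ok <- st$usable
  expect_equal(st$auc_with[ok] - st$auc_without[ok],
               st$endpoint[ok] / 2, tolerance = 1e-9)
  expect_equal(st$h_20[ok], st$endpoint[ok])
})

test_that("unusable trajectories are excluded from AUC summaries, not from trials", {
  sim <- shared_sim()
  st <- shared_stats()
  # fabricate one unusable response on a trial that enters the binned
  # analysis (non-random, has a previous target)
  tr <- sim$trials
  pick <- tr[!tr$is_random & tr$trial_index > 1 &
               tr$report_type == "consolidation", ][1, ]
  i <- which(st$participant == pick$participant &
               st$trial_index == pick$trial_index &
               st$report_type == "consolidation")
  st2 <- st
  st2$usable[i] <- FALSE
  st2[i, c("latency_ms", "endpoint", "auc_with", "auc_without",
           paste0("h_", 1:20))] <- NA
  summ <- auc_condition_summaries(sim$trials, stats = st2)
  summ_full <- auc_condition_summaries(sim$trials, stats = st)
  expect_equal(sum(summ$n[summ$bin_center != 180]),
               sum(summ_full$n[summ_full$bin_center != 180]) - 1)
  expect_equal(nrow(summ), 3 * 3 * 10)
})

test_that("deviation profiles cover all cells, nodes, and the edge bin", {
  sim <- shared_sim()
  prof <- deviation_profiles(sim$trials, stats = shared_stats())
  expect_equal(nrow(prof), 3 * 3 * 20 * 10)
  expect_equal(sort(unique(prof$time_point)), seq(0.05, 1, by = 0.05))
  expect_true(all(prof$bin_center %in% c(seq(-144, 144, 36), 180)))
})

test_that("median split assigns the median response to the early set", {
  st <- data.frame(participant = "P01", report_type = "consolidation",
                   latency_ms = c(100, 200, 300, 400))
  out <- median_split_by_onset(st)
  expect_equal(out$onset_group, c("early", "early", "late", "late"))
  st3 <- st[1:3, ]
  out3 <- median_split_by_onset(st3)
  expect_equal(out3$onset_group, c("early", "early", "late"))
  tied <- data.frame(participant = "P01", report_type = "consolidation",
                     latency_ms = rep(250, 4))
  expect_warning(outt <- median_split_by_onset(tied), "degenerate")
  expect_true(all(outt$onset_group == "early"))
  single <- data.frame(participant = "P01", report_type = "perceptual",
                       latency_ms = 100)
  expect_warning(median_split_by_onset(single), "degenerate")
})
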