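test_that("split R-hat is near 1 for stationary chains and large for separated ones", {
  set.seed(40)
  ch <- cbind(rnorm(4000), rnorm(4000))
  expect_lt(abs(compute_rhat(ch) - 1), 0.01)

  set.seed(42)
  sep <- cbind(rnorm(1000, 0, 1), rnorm(1000, 10, 1))
  r <- compute_rhat(sep)
  expect_gt(r, 1.5)
  expect_equal(r, 5.902628, tolerance = 1e-4)  # frozen reference value

  expect_warning(r0 <- compute_rhat(cbind(rep(1, 10), rep(1, 10))),
                 "zero variance")
  expect_true(is.na(r0))
  expect_error(compute_rhat(matrix(rnorm(10), ncol = 1)), "2 chains")
  expect_error(compute_rhat(matrix(rnorm(4), ncol = 2)), "4 draws")
})

test_that("split R-hat agrees with the coda diagnostic on well-mixed chains", {
  set.seed(41)
  ch <- matrix(rnorm(8000), ncol = 4)
  ours <- compute_rhat(ch)
  mc <- coda::mcmc.list(lapply(seq_len(4), function(j) coda::mcmc(ch[, j])))
  theirs <- coda::gelman.diag(mc, autoburnin = FALSE)$psrf[1, 1]
  expect_lt(abs(ours - theirs), 0.05)
})

test_that("the highest-density interval is the shortest mass-covering window", {
  set.seed(7)
  dr <- rnorm(1e5)
  hdi <- compute_hdi(dr)
  expect_equal(unname(hdi), c(-1.96, 1.96), tolerance = 0.05)
  expect_equal(unname(compute_hdi(rep(2.5, 200))), c(2.5, 2.5))
  set.seed(8)
  u <- runif(1e5)
  expect_equal(unname(diff(compute_hdi(u))), 0.95, tolerance = 0.01)
  expect_error(compute_hdi(rnorm(50)), "at least 100")
  expect_error(compute_hdi(rnorm(200), mass = 1.2), "in \\(0, 1\\)")
  # agrees with coda's HPD interval on a skewed posterior
  set.seed(9)
  sk <- rexp(5e4)
  expect_equal(unname(compute_hdi(sk)),
               as.vector(coda::HPDinterval(coda::mcmc(sk))),
               tolerance = 1e-3)
})

test_that("three-level fit returns labelled draws, diagnostics, and the sign pattern", {
  summ <- noiseless_summaries(n_participants = 3, noise_sd = 0.3,
                              seed = 13)
  fit <- fit_dog_hbm(summ, spec = fast_spec3(seed = 13, n = 600))
  expect_s3_class(fit, "dog_hbm")
  expect_equal(dim(fit$draws$alpha), c(600, 3, 3))
  expect_equal(dimnames(fit$draws$alpha)[[3]],
               c("perceptual", "consolidation", "retrieval"))
  expect_true(all(fit$draws$w > 0))
  expect_true(all(c("delta", "sig_obs") %in% names(fit$rhat) |
                    c("delta", "sig_obs") %in% names(fit$rhat)))
  s <- posterior_summary(fit)
  expect_setequal(names(s), c("parameter", "report_type", "time_point",
                              "mean", "hdi_low", "hdi_high", "rhat",
                              "verdict"))
  a <- s[s$parameter == "alpha", ]
  expect_lt(a$mean[a$report_type == "perceptual"], 0)
  expect_gt(a$mean[a$report_type == "consolidation"], 0)
  expect_gt(a$mean[a$report_type == "retrieval"], 0)
  expect_true(all(a$hdi_low < a$hdi_high))
  # verdicts are consistent with their own HDIs
  expect_equal(a$verdict == "credibly positive", a$hdi_low > 0)
  expect_equal(a$verdict == "credibly negative", a$hdi_high < 0)
  expect_output(print(fit), "Hierarchical Bayesian DoG fit")
})

test_that("posterior draws are reproducible bit-for-bit given seed and data", {
  summ <- noiseless_summaries(n_participants = 2, noise_sd = 0.2, seed = 3)
  f1 <- fit_dog_hbm(summ, spec = fast_spec3(seed = 5, n = 400))
  f2 <- fit_dog_hbm(summ, spec = fast_spec3(seed = 5, n = 400))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_dog_hbm(summ, spec = fast_spec3(seed = 6, n = 400))
  expect_false(identical(f1$draws$alpha, f3$draws$alpha))
})

test_that("near-null data leave all amplitude posteriors around zero", {
  summ <- noiseless_summaries(alphas = c(perceptual = 0,
                                         consolidation = 0,
                                         retrieval = 0),
                              n_participants = 4, noise_sd = 0.02,
                              seed = 17)
  fit <- fit_dog_hbm(summ, spec = fast_spec3(seed = 17, n = 600))
  a <- posterior_summary(fit)
  a <- a[a$parameter == "alpha", ]
  expect_true(all(a$hdi_low < 0.05 & a$hdi_high > -0.05))
  expect_true(all(abs(a$mean) < 0.3))
})

test_that("single-participant single-report fits work (degenerate hierarchy)", {
  summ <- noiseless_summaries(alphas = c(consolidation = 2),
                              n_participants = 1, noise_sd = 0.05,
                              seed = 19)
  fit <- fit_dog_hbm(summ, spec = fast_spec3(seed = 19, n = 600))
  expect_equal(dim(fit$draws$alpha), c(600, 1, 1))
  s <- posterior_summary(fit)
  expect_false(any(is.na(s$rhat[s$parameter == "alpha"])))
  expect_equal(s$mean[s$parameter == "alpha"], 2, tolerance = 0.2)
})

test_that("four-level fit resolves the time course of the amplitude", {
  set.seed(23)
  bins <- c(seq(-144, 144, by = 36), 180)
  tgrid <- c(0.25, 0.5, 0.75, 1)
  a_t <- c(-6, -2, 2, 6)
  prof <- expand.grid(participant = c("P01", "P02"),
                      report_type = "consolidation",
                      time_point = tgrid, bin_center = bins,
                      stringsAsFactors = FALSE)
  prof$mean_h <- dog(prof$bin_center,
                     a_t[match(prof$time_point, tgrid)], 0.02, 0) +
    rnorm(nrow(prof), 0, 0.4)
  fit <- fit_dog_hbm_time(prof, spec = fast_spec4(seed = 23, n = 400))
  expect_equal(dim(fit$draws$alpha), c(400, 2, 1, 4))
  s <- posterior_summary(fit)
  a <- s[s$parameter == "alpha", ]
  expect_equal(a$time_point, tgrid)
  expect_lt(a$mean[1], 0)
  expect_gt(a$mean[4], 0)
  expect_true(all(diff(a$mean) > 0))

  # a time-constant profile gives mutually overlapping HDIs across time
  prof$mean_h <- dog(prof$bin_center, 3, 0.02, 0) +
    rnorm(nrow(prof), 0, 0.4)
  fit2 <- fit_dog_hbm_time(prof, spec = fast_spec4(seed = 24, n = 400))
  a2 <- posterior_summary(fit2)
  a2 <- a2[a2$parameter == "alpha", ]
  expect_lt(max(a2$hdi_low), min(a2$hdi_high))
})
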