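test_that("mean profiles average cycles pointwise", {
  set.seed(51)
  one <- matrix(rnorm(303), 101, 3)
  expect_equal(mean_profile(list(one), "rotation"), one[, 3])
  expect_equal(mean_profile(list(one, -one), "flexion"), rep(0, 101))

  cycles <- replicate(5, matrix(rnorm(303), 101, 3), simplify = FALSE)
  manual <- Reduce(`+`, lapply(cycles, function(m) m[, 2])) / 5
  expect_equal(mean_profile(cycles, "abduction"), manual, tolerance = 1e-12)
  expect_error(mean_profile(list()), "non-empty")
})

test_that("cross-talk r-squared handles linear, orthogonal and flat profiles", {
  flex <- flexion_waveform(seq(0, 1, length.out = 101))
  expect_equal(crosstalk_r2(flex, 0.3 * flex + 2), 1, tolerance = 1e-12,
               ignore_attr = TRUE)

  x <- sin(2 * pi * (0:100) / 101)
  y <- cos(2 * pi * (0:100) / 101)  # orthogonal over the full period
  expect_lt(crosstalk_r2(x - mean(x), y - mean(y)), 1e-12)

  expect_warning(r2 <- crosstalk_r2(rep(1, 101), flex), "zero-variance")
  expect_equal(as.numeric(r2), 0)
  expect_true(attr(r2, "zero_variance"))
  expect_error(crosstalk_r2(1:5, 1:6), "equal length")
})

test_that("profile variance matches closed forms", {
  expect_equal(profile_variance(rep(3.2, 101)), 0)
  # sinusoid over one period on the 101-point grid: variance A^2 / 2
  A <- 4.7
  p <- A * sin(2 * pi * (0:100) / 100)
  expect_equal(profile_variance(p), A^2 / 2, tolerance = 1e-9)
  set.seed(8)
  q <- rnorm(101)
  expect_equal(profile_variance(2 * q), 4 * profile_variance(q),
               tolerance = 1e-12)
  expect_equal(profile_variance(q, "ml"), profile_variance(q) * 100 / 101,
               tolerance = 1e-12)
})

test_that("an identity correction leaves every metric unchanged", {
  # uncorrelated true waveforms, no noise, no misalignment -> P = identity
  cfg <- gait_sim_config(noise_sd = 0, coupling = 0, mis_angle = 0,
                         n_cycles = 3, seed = 61)
  sim <- simulate_subject(cfg)
  fit <- crosstalk_pca(sim$observed)
  expect_equal(coef(fit), diag(3), ignore_attr = TRUE, tolerance = 1e-12)
  m <- evaluate_subject(sim$observed, fit, truth = 0)
  expect_equal(m$r2_before, m$r2_after, tolerance = 1e-12)
  expect_equal(m$d2_flex_before, m$d2_flex_after, tolerance = 1e-12)
  expect_equal(m$d2_abd_before, m$d2_abd_after, tolerance = 1e-12)
  expect_equal(m$posture_error_before, m$posture_error_after,
               tolerance = 1e-12)
})

test_that("corrected metrics improve on a misaligned noisy subject", {
  cfg <- gait_sim_config(deformity = 5, seed = 62)
  sim <- simulate_subject(cfg)
  fit <- crosstalk_pca(sim$observed)
  m <- evaluate_subject(sim$observed, fit, truth = 5)
  expect_lt(m$r2_after, m$r2_before)
  expect_lt(m$d2_abd_after, m$d2_abd_before)
  expect_gt(m$d2_flex_after, m$d2_flex_before)
  expect_lt(abs(m$posture_error_after), abs(m$posture_error_before))
  # profile-mode r^2 is near but not exactly zero under cycle noise
  mp <- evaluate_subject(sim$observed, fit, r2_mode = "profile")
  expect_lt(mp$r2_after, 1e-2)
  expect_gt(mp$r2_before, 0.6)
})

test_that("group summaries aggregate with the documented SD conventions", {
  cfg <- gait_sim_config(n_cycles = 5, seed = 63)
  sims <- lapply(1:6, function(i) simulate_subject(cfg, i))
  mets <- lapply(sims, function(s)
    evaluate_subject(s$observed, crosstalk_pca(s$observed),
                     truth = cfg$deformity))
  g <- group_summary(mets)
  expect_setequal(g$metric, c("crosstalk_r2", "d2_flex", "d2_abd",
                              "posture_error"))
  r2row <- g[g$metric == "crosstalk_r2", ]
  vals <- vapply(mets, function(m) m$r2_before, numeric(1))
  expect_equal(r2row$mean_before, mean(vals), tolerance = 1e-12)
  expect_equal(r2row$sd_before, stats::sd(vals), tolerance = 1e-12)
  expect_false(attr(g, "single_subject"))

  g1 <- group_summary(mets[1])
  expect_true(all(g1$sd_before == 0))
  expect_true(attr(g1, "single_subject"))

  same <- group_summary(mets[c(1, 1, 1)])
  expect_true(all(same$sd_after == 0))
})
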