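make_trial <- function(n = 200, f = function(i) cbind(sin(i / 10),
                                                      cos(i / 15),
                                                      i / 50)) {
  raw_trial(f(seq_len(n)))
}

test_that("short gaps are refilled by a cubic spline, long gaps are kept", {
  i <- 1:120
  cubic <- 0.001 * i^3 - 0.05 * i^2 + 2 * i - 7
  A <- cbind(cubic, rev(cubic), cubic / 2)
  tr <- raw_trial(A)
  expect_identical(interpolate_gaps(tr)$angles, tr$angles)  # no gaps

  tr$angles[51:53, 1] <- NA                       # 3-frame gap
  tr$angles[80:88, 2] <- NA                       # 9-frame gap (fillable)
  tr$angles[20:30, 3] <- NA                       # 11-frame gap (kept)
  out <- interpolate_gaps(tr)
  expect_equal(out$angles[51:53, 1], cubic[51:53], tolerance = 1e-9)
  expect_equal(out$angles[80:88, 2], rev(cubic)[80:88], tolerance = 1e-9)
  expect_true(all(is.na(out$angles[20:30, 3])))
  expect_equal(attr(out, "unfilled")$length, 11L)

  tr10 <- raw_trial(A)
  tr10$angles[40:49, 1] <- NA                     # exactly 10 frames
  expect_true(all(is.na(interpolate_gaps(tr10)$angles[40:49, 1])))

  tr_bad <- raw_trial(A)
  tr_bad$angles[, 2] <- NA
  expect_error(interpolate_gaps(tr_bad), "unusable")
})

test_that("smoothing is the identity at zero roughness and denoises a sinusoid", {
  tr <- make_trial()
  expect_equal(smooth_trial(tr, roughness = 0)$angles, tr$angles,
               tolerance = 1e-9)

  set.seed(5)
  i <- 1:400
  clean <- 10 * sin(2 * pi * i / 100)
  noisy <- clean + rnorm(400, 0, 0.8)
  tr <- raw_trial(cbind(noisy, clean, 0 * i + 2))
  sm <- smooth_trial(tr)  # GCV-chosen roughness
  expect_lt(rms(sm$angles[, 1] - clean), rms(noisy - clean))
  expect_equal(sm$angles[, 3], rep(2, 400))  # constant channel unchanged
})

test_that("coordinate-based event detection finds heel strikes and toe offs", {
  n <- 300
  i <- seq_len(n)
  period <- 100
  heel <- 200 * sin(2 * pi * i / period)        # maxima at i = 25, 125, 225
  toe <- 150 * sin(2 * pi * i / period)         # minima at i = 75, 175, 275
  tr <- raw_trial(cbind(sin(i / 9), cos(i / 7), i / 100),
                  heel = heel, toe = toe, sacrum = rep(0, n))
  ev <- detect_events(tr)
  expect_length(ev$heel_strikes, 3)
  expect_true(all(abs(ev$heel_strikes - c(25, 125, 225)) <= 1))
  expect_true(all(abs(ev$toe_offs - c(75, 175, 275)) <= 1))

  drift <- raw_trial(cbind(i, i, i), heel = i, toe = -i, sacrum = rep(0, n))
  expect_error(detect_events(drift), "heel strikes")
  expect_error(detect_events(make_trial()), "marker")
})

test_that("stride segmentation resamples to 101 points and rejects gap cycles", {
  # a stride already sampled on 101 frames is preserved at the grid points
  cyc <- make_cycle(flexion_waveform(seq(0, 1, length.out = 101)))
  tr <- raw_trial(cyc)
  seg <- segment_cycles(tr, list(heel_strikes = c(1L, 101L)))
  expect_length(seg$cycles, 1)
  expect_equal(unclass(seg$cycles[[1]]), unname(cyc), tolerance = 1e-9,
               ignore_attr = TRUE)

  # a linear ramp resamples to the same ramp
  n <- 173
  ramp <- cbind(seq(0, 60, length.out = n), seq(-3, 3, length.out = n),
                rep(1, n))
  seg <- segment_cycles(raw_trial(ramp), list(heel_strikes = c(1L, n)))
  expect_equal(seg$cycles[[1]][, 1], seq(0, 60, length.out = 101),
               tolerance = 1e-9, ignore_attr = TRUE)

  # one gap stride and one clean stride -> exactly one cycle, one rejection
  A <- cbind(rep(seq(0, 59, length.out = 120), 2), 0, 0)
  A[30:45, 1] <- NA  # unfillable gap inside stride 1
  tr <- raw_trial(A)
  tr <- interpolate_gaps(tr)
  seg <- segment_cycles(tr, list(heel_strikes = c(1L, 120L, 239L)))
  expect_length(seg$cycles, 1)
  expect_equal(seg$rejected$reason, "unfilled gap")
  expect_equal(length(seg$cycles) + nrow(seg$rejected), 2)  # conservation
})

test_that("time normalization is idempotent", {
  set.seed(9)
  cfg <- gait_sim_config(seed = 2)
  cyc <- simulate_true_cycle(cfg)
  seg <- segment_cycles(raw_trial(unclass(cyc)),
                        list(heel_strikes = c(1L, 101L)))
  expect_equal(unclass(seg$cycles[[1]]), unclass(cyc), tolerance = 1e-9,
               ignore_attr = TRUE)
})
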