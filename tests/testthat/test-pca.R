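test_that("stacking concatenates cycles and averages columns correctly", {
  set.seed(21)
  cycles <- replicate(5, matrix(rnorm(303), 101, 3), simplify = FALSE)
  s <- stack_cycles(subject_side(cycles))
  expect_equal(nrow(s$X), 505)
  expect_equal(s$n_cycles, 5)
  # direct summation oracle
  manual <- sapply(1:3, function(j)
    sum(vapply(cycles, function(m) sum(m[, j]), numeric(1))) / 505)
  expect_equal(unname(s$means), manual, tolerance = 1e-12)

  one <- stack_cycles(subject_side(cycles[1]))
  expect_equal(nrow(one$X), 101)
  dup <- stack_cycles(subject_side(cycles[c(1, 1)]))
  expect_equal(dup$means, one$means)  # duplication invariance of the mean
})

test_that("angle covariance matches hand computation under the declared divisor", {
  X <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  C <- angle_covariance(X)  # unbiased: divide by n - 1 = 3
  expect_equal(unname(C), diag(c(2 / 3, 2 / 3, 0)), tolerance = 1e-12)
  Cn <- angle_covariance(X, divisor = "ml")
  expect_equal(unname(Cn), diag(c(1 / 2, 1 / 2, 0)), tolerance = 1e-12)

  expect_equal(unname(angle_covariance(matrix(5, 4, 3))),
               matrix(0, 3, 3))  # constant columns

  set.seed(3)
  x <- rnorm(50)
  X2 <- cbind(x, 2 * x, 0)
  C2 <- angle_covariance(X2)
  expect_equal(C2[1, 2], 2 * stats::var(x), tolerance = 1e-12)
  expect_equal(qr(C2)$rank, 1L)

  expect_error(angle_covariance(matrix(1, 1, 3)), "two observations")
})

test_that("eigendecomposition sorts values and matches the closed-form cubic", {
  e <- eigen_summary(diag(c(4, 9, 1)))
  expect_equal(e$values, c(9, 4, 1))
  expect_equal(e$var_explained, c(9, 4, 1) / 14)
  expect_equal(abs(e$vectors), diag(3)[, c(2, 1, 3)], tolerance = 1e-12)

  set.seed(31)
  for (i in 1:100) {
    C <- random_psd3()
    expect_equal(eigen_summary(C)$values, oracle_eigvals_sym3(C),
                 tolerance = 1e-8)
  }

  z <- eigen_summary(matrix(0, 3, 3))
  expect_true(z$degenerate)
  expect_true(all(is.na(z$var_explained)))
  expect_error(eigen_summary(matrix(1:9, 3, 3)), "symmetric")
})

test_that("eigenvector sorting maximizes the diagonal by enumeration", {
  # already aligned: identity permutation and signs
  tm <- sort_eigenvectors(diag(3))
  expect_equal(tm$P, diag(3), ignore_attr = TRUE)
  expect_equal(tm$permutation, c(1L, 2L, 3L))
  expect_equal(tm$signs, c(1, 1, 1))

  # columns scrambled to order (2, 3, 1) with column 1 negated
  W <- diag(3)[, c(2, 3, 1)]
  W[, 1] <- -W[, 1]
  tm <- sort_eigenvectors(W)
  expect_equal(tm$P, diag(3), ignore_attr = TRUE)

  # a slightly rotated basis keeps diagonal dominance: brute-force check
  set.seed(41)
  for (i in 1:10) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    W <- misalignment_matrix(5, ax)  # 5 degree rotation of the identity basis
    tm <- sort_eigenvectors(W)
    scores <- sapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                          c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)),
                     function(p) sum(abs(diag(W[, p]))))
    expect_equal(tm$permutation, c(1L, 2L, 3L))
    expect_equal(sum(abs(diag(tm$P))), max(scores), tolerance = 1e-12)
    expect_true(all(diag(tm$P) >= 0))
  }

  # exact tie: 45 degree rotation in the frontal-axial plane
  c45 <- sqrt(2) / 2
  W <- matrix(c(c45, c45, 0, -c45, c45, 0, 0, 0, 1), 3, 3)
  tm <- sort_eigenvectors(W)
  expect_true(tm$tie)
  expect_equal(tm$permutation, c(1L, 2L, 3L))  # lexicographic tie-break
})

test_that("applying the transfer matrix projects onto the principal axes", {
  cyc <- matrix(rnorm(303), 101, 3)
  expect_equal(unclass(apply_correction(cyc, diag(3))), cyc,
               ignore_attr = TRUE)

  # exact linear coupling: corrected frontal channel has zero variance
  alpha <- flexion_waveform(seq(0, 1, length.out = 101))
  X <- cbind(alpha, 0.2 * alpha, 0)
  tm <- sort_eigenvectors(eigen_summary(angle_covariance(X)))
  corr <- apply_correction(X, tm)
  expect_lt(stats::var(corr[, 2]), 1e-9)
  # direct projection oracle: principal axis of the rank-1 cloud
  u <- c(1, 0.2, 0) / sqrt(1.04)
  expect_equal(abs(tm$P[, 1]), abs(u), tolerance = 1e-9, ignore_attr = TRUE)

  expect_equal(transfer_to_posture(c(8, 5, 0), diag(3)),
               c(flexion = 8, abduction = 5, rotation = 0))
})

test_that("the fitted correction decorrelates, conserves variance, and is idempotent", {
  for (seed in 1:4) {
    cfg <- gait_sim_config(n_cycles = 10, seed = seed,
                           mis_angle = 6 + 2 * seed)
    sim <- simulate_subject(cfg)
    fit <- crosstalk_pca(sim$observed)
    P <- coef(fit)
    expect_lt(max(abs(crossprod(P) - diag(3))), 1e-9)
    expect_true(all(diag(P) >= 0))

    X <- do.call(rbind, fit$corrected)
    cors <- stats::cor(X)
    expect_lt(max(abs(cors[upper.tri(cors)])), 1e-10)  # whitened cross-talk

    before <- do.call(rbind, sim$observed$cycles)
    expect_equal(sum(diag(stats::cov(X))), sum(diag(stats::cov(before))),
                 tolerance = 1e-12)  # orthonormal transform conserves variance

    refit <- crosstalk_pca(subject_side(fit$corrected))
    expect_equal(coef(refit), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(do.call(rbind, refit$corrected), X, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate covariance is refused", {
  flat <- matrix(rep(c(1, 2, 3), each = 101), 101, 3)
  expect_error(crosstalk_pca(list(flat)), "rank")
  alpha <- flexion_waveform(seq(0, 1, length.out = 101))
  rank1 <- list(cbind(alpha, 0.2 * alpha, 0))
  expect_error(crosstalk_pca(rank1), "rank")
})

test_that("true angles are recovered when the method's assumptions hold", {
  # zero noise, zero coupling, uncorrelated true waveforms
  for (m in c(5, 10)) {
    cfg <- gait_sim_config(noise_sd = 0, coupling = 0, mis_angle = m,
                           seed = 17)
    sim <- simulate_subject(cfg)
    fit <- crosstalk_pca(sim$observed)
    err <- recovery_rms(fit$corrected, sim$truth$cycles)
    expect_lt(err[["flexion"]], 1)
    expect_lt(err[["abduction"]], 1)
    expect_lt(err[["rotation"]], 1)
  }
  # posture transfer under the same conditions
  cfg <- gait_sim_config(noise_sd = 0, coupling = 0, mis_angle = 10,
                         deformity = 5, seed = 23)
  sim <- simulate_subject(cfg)
  fit <- crosstalk_pca(sim$observed)
  expect_lt(abs(fit$posture_corrected[["abduction"]] - 5), 0.5)
  # null deformity stays null
  cfg0 <- gait_sim_config(noise_sd = 0, coupling = 0, mis_angle = 10,
                          deformity = 0, seed = 23)
  sim0 <- simulate_subject(cfg0)
  fit0 <- crosstalk_pca(sim0$observed)
  expect_lt(abs(fit0$posture_corrected[["abduction"]]), 0.5)
})
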