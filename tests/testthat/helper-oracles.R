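# Independent oracles used across the suite. These are deliberately written
# as direct transcriptions of closed forms, not calls into the package.

# Term-by-term symbolic expansion of Ry(a) %*% Rx(b) %*% Rz(c) (the default
# flexion-abduction-rotation sequence), angles in degrees.
oracle_rotation_yxz <- function(angles) {
  a <- angles[1] * pi / 180; b <- angles[2] * pi / 180; c <- angles[3] * pi / 180
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cc <- cos(c); sc <- sin(c)
  matrix(c(
    ca * cc + sa * sb * sc, -ca * sc + sa * sb * cc, sa * cb,
    cb * sc,                 cb * cc,               -sb,
    -sa * cc + ca * sb * sc, sa * sc + ca * sb * cc, ca * cb),
    nrow = 3, byrow = TRUE)
}

# Closed-form eigenvalues of a symmetric 3x3 matrix via the trigonometric
# solution of the characteristic cubic (Cardano form), descending order.
oracle_eigvals_sym3 <- function(A) {
  p1 <- A[1, 2]^2 + A[1, 3]^2 + A[2, 3]^2
  q <- sum(diag(A)) / 3
  p2 <- (A[1, 1] - q)^2 + (A[2, 2] - q)^2 + (A[3, 3] - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  if (p < .Machine$double.eps) return(rep(q, 3))
  B <- (A - q * diag(3)) / p
  detB <- B[1, 1] * (B[2, 2] * B[3, 3] - B[2, 3] * B[3, 2]) -
    B[1, 2] * (B[2, 1] * B[3, 3] - B[2, 3] * B[3, 1]) +
    B[1, 3] * (B[2, 1] * B[3, 2] - B[2, 2] * B[3, 1])
  r <- max(-1, min(1, detB / 2))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  sort(c(e1, e2, e3), decreasing = TRUE)
}

random_psd3 <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  crossprod(M) * stats::runif(1, 0.1, 10)
}

# A plain cycle matrix from three channel vectors (length 101)
make_cycle <- function(flex, abd = rep(0, 101), rot = rep(0, 101)) {
  cbind(flex, abd, rot)
}

# RMS helper
rms <- function(x) sqrt(mean(x^2))

# Per-channel RMS difference between two lists of cycles
recovery_rms <- function(corrected, truth) {
  d <- do.call(rbind, Map(function(a, b) unclass(a) - unclass(b),
                          corrected, truth))
  sqrt(colMeans(d^2))
}
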