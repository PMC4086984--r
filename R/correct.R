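#' Stack the cycles of a subject/side into one observation matrix
#'
#' Concatenates all cycles row-wise, in cycle order, into the
#' `(n * 101) x 3` matrix on which one covariance (and hence one transfer
#' matrix) per subject/side is computed.
#'
#' @param x a [subject_side()] (or list of cycles).
#' @return An object of class `"stacked_obs"`: list with the matrix `X`,
#'   the per-column means `means` (degrees) and `n_cycles`.
#' @export
stack_cycles <- function(x) {
  x <- as_subject_side(x)
  X <- do.call(rbind, x$cycles)
  structure(list(X = X, means = colMeans(X), n_cycles = length(x$cycles)),
            class = "stacked_obs")
}

#' Covariance matrix of stacked angle observations
#'
#' Symmetric positive semi-definite covariance of the mean-centered angle
#' columns, in squared degrees. The default divisor is the unbiased
#' `n - 1`; the choice does not affect eigenvectors or variance fractions.
#'
#' @param obs a `"stacked_obs"` (see [stack_cycles()]) or a numeric matrix
#'   with at least two rows.
#' @param divisor `"unbiased"` for `1/(n-1)` or `"ml"` for `1/n`.
#' @return 3x3 covariance matrix.
#' @export
angle_covariance <- function(obs, divisor = c("unbiased", "ml")) {
  divisor <- match.arg(divisor)
  X <- if (inherits(obs, "stacked_obs")) obs$X else as.matrix(obs)
  n <- nrow(X)
  if (n < 2L) stop("covariance needs at least two observations")
  C <- stats::cov(X)
  if (divisor == "ml") C <- C * (n - 1) / n
  C
}

#' Eigendecomposition of an angle covariance matrix
#'
#' Eigenvalues sorted in decreasing order with their unit eigenvectors and
#' variance contributions `lambda_j / sum(lambda)`. An all-zero (or
#' numerically rank-zero) covariance is flagged degenerate, as are
#' near-equal eigenvalue pairs, for which the principal axes are not
#' uniquely defined.
#'
#' @param C symmetric positive semi-definite 3x3 matrix (squared degrees).
#' @return An object of class `"eigen_summary"`: `values`, `vectors`
#'   (columns), `var_explained`, and logical `degenerate`.
#' @export
eigen_summary <- function(C) {
  C <- as.matrix(C)
  if (!all(dim(C) == c(3L, 3L)))
    stop("`C` must be 3x3")
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop("`C` must be symmetric")
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- e$values
  tot <- sum(vals)
  if (min(vals) < -1e-8 * max(1, abs(tot)))
    stop("`C` must be positive semi-definite")
  vals <- pmax(vals, 0)
  degenerate <- tot <= 1e-12 ||
    any(abs(diff(vals)) < 1e-10 * max(tot, 1e-300))
  structure(list(values = vals, vectors = e$vectors,
                 var_explained = if (tot > 1e-12) vals / tot
                                 else rep(NA_real_, 3L),
                 degenerate = degenerate),
            class = "eigen_summary")
}

#' @export
print.eigen_summary <- function(x, digits = 4, ...) {
  cat("Eigenvalues (deg^2):", format(x$values, digits = digits), "\n")
  cat("Variance contributions:",
      format(x$var_explained, digits = digits), "\n")
  if (x$degenerate) cat("(degenerate spectrum flagged)\n")
  invisible(x)
}

all_permutations3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                          c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

#' Sort and sign-fix eigenvectors into a transfer matrix
#'
#' Matches each principal axis to an anatomical angle: among the six column
#' permutations of the eigenvector matrix, the one maximizing the sum of
#' absolute diagonal entries is chosen (exhaustive enumeration), then column
#' signs are flipped so every diagonal entry is nonnegative -- corrected
#' flexion increases with raw flexion. Permutation ties within 1e-12 are
#' broken by the lexicographically smallest permutation and flagged.
#'
#' @param e an [eigen_summary()] (or an orthonormal 3x3 matrix of
#'   eigenvector columns in decreasing eigenvalue order).
#' @return An object of class `"transfer_matrix"`: orthonormal `P` whose
#'   column `i` is the eigenvector assigned to angle `i`, the `permutation`
#'   sigma (column `i` of `P` is source eigenvector `sigma[i]`), the sign
#'   flips `signs`, per-component `values` (eigenvalues after assignment),
#'   and a `tie` flag.
#' @export
sort_eigenvectors <- function(e) {
  if (inherits(e, "eigen_summary")) {
    W <- e$vectors; vals <- e$values
  } else {
    W <- as.matrix(e); vals <- rep(NA_real_, 3L)
  }
  if (max(abs(crossprod(W) - diag(3))) > 1e-9)
    stop("eigenvectors must be orthonormal")
  scores <- vapply(all_permutations3,
                   function(p) sum(abs(diag(W[, p, drop = FALSE]))),
                   numeric(1))
  best <- max(scores)
  hit <- which(scores > best - 1e-12)
  tie <- length(hit) > 1L
  perm <- all_permutations3[[hit[1L]]]  # permutations listed lexicographically
  P <- W[, perm, drop = FALSE]
  s <- ifelse(diag(P) < 0, -1, 1)
  P <- P %*% diag(s)
  dimnames(P) <- list(c("flexion", "abduction", "rotation"),
                      c("psi", "xi", "rho"))
  structure(list(P = P, permutation = perm, signs = s,
                 values = vals[perm], tie = tie),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, digits = 4, ...) {
  cat("Transfer matrix P (observed angles -> principal axes):\n")
  print(round(x$P, digits))
  cat("Permutation:", paste(x$permutation, collapse = " "),
      " signs:", paste(ifelse(x$signs > 0, "+", "-"), collapse = ""), "\n")
  if (x$tie) cat("(permutation tie broken lexicographically)\n")
  invisible(x)
}

as_P <- function(P) {
  if (inherits(P, "transfer_matrix")) P <- P$P
  P <- as.matrix(P)
  if (!all(dim(P) == c(3L, 3L)) ||
      max(abs(crossprod(P) - diag(3))) > 1e-9)
    stop("`P` must be an orthonormal 3x3 (transfer) matrix")
  P
}

#' Project angle samples onto the principal axes
#'
#' Maps every raw sample triple `(alpha, beta, gamma)` through `t(P)` to the
#' corrected angles `(psi, xi, rho)`. The transform is applied to the raw,
#' uncentered angles, so static offsets (e.g. a varus deformity) are carried
#' through the rotation rather than subtracted.
#'
#' @param cycle 101 x 3 angle matrix (or any n x 3 matrix of samples).
#' @param P a `"transfer_matrix"` or orthonormal 3x3 matrix.
#' @return matrix of corrected angles, same shape as the input.
#' @export
apply_correction <- function(cycle, P) {
  P <- as_P(P)
  X <- as.matrix(cycle)
  if (ncol(X) != 3L) stop("`cycle` must have three columns")
  out <- X %*% P
  colnames(out) <- c("flexion", "abduction", "rotation")
  if (nrow(out) == 101L) out <- angle_cycle(out)
  out
}

#' Correct a static posture trial with a gait-fitted transfer matrix
#'
#' Applies the transfer matrix fitted on a subject's gait cycles to the mean
#' angles of that subject's static posture trial, so the corrected
#' frontal-plane angle can be compared with a radiographic varus/valgus
#' measurement.
#'
#' @param posture length-3 vector of posture trial mean angles (degrees).
#' @param P the `"transfer_matrix"` fitted on the same subject/side.
#' @return named length-3 vector of corrected posture angles.
#' @export
transfer_to_posture <- function(posture, P) {
  P <- as_P(P)
  posture <- as.numeric(posture)
  if (length(posture) != 3L || !all(is.finite(posture)))
    stop("`posture` must be three finite angles")
  out <- as.numeric(posture %*% P)
  names(out) <- c("flexion", "abduction", "rotation")
  out
}

#' Fit the cross-talk correction for one subject/side
#'
#' Fits one principal component analysis on all gait cycles of a
#' subject/side stacked over time, sorts and sign-fixes the eigenvectors
#' into an orthonormal transfer matrix (see [sort_eigenvectors()]), and
#' projects every cycle -- and the posture trial, if present -- onto the
#' principal axes, which are taken as the corrected anatomical angles.
#'
#' The stacked corrected components are exactly uncorrelated, and because
#' the transform is orthonormal the total centered variance is preserved;
#' the correction moves cross-talk variance out of the ab/adduction channel
#' and into flexion/extension.
#'
#' @param x a [subject_side()] (or list of 101 x 3 cycles).
#' @param divisor covariance divisor, see [angle_covariance()].
#' @return An object of class `"crosstalk_pca"` with components `transfer`
#'   (the `"transfer_matrix"`), `eigen` (the `"eigen_summary"`), `corrected`
#'   (list of corrected cycles), `posture_corrected`, `means` (stacked
#'   column means), and the input `observed`.
#' @examples
#' cfg <- gait_sim_config(n_cycles = 5, seed = 42)
#' sim <- simulate_subject(cfg)
#' fit <- crosstalk_pca(sim$observed)
#' coef(fit)          # the transfer matrix
#' summary(fit)
#' @export
crosstalk_pca <- function(x, divisor = c("unbiased", "ml")) {
  divisor <- match.arg(divisor)
  x <- as_subject_side(x)
  obs <- stack_cycles(x)
  C <- angle_covariance(obs, divisor)
  e <- eigen_summary(C)
  if (sum(e$values > 1e-10 * max(e$values, 1e-300)) < 2L)
    stop("degenerate covariance (rank < 2): angles carry no correctable ",
         "cross-talk structure")
  tm <- sort_eigenvectors(e)
  corrected <- lapply(x$cycles, apply_correction, P = tm)
  posture_corrected <- if (!is.null(x$posture))
    transfer_to_posture(x$posture, tm)
  structure(list(transfer = tm, eigen = e, corrected = corrected,
                 posture_corrected = posture_corrected,
                 means = obs$means, n_cycles = obs$n_cycles,
                 divisor = divisor, observed = x,
                 call = match.call()),
            class = "crosstalk_pca")
}

#' @export
print.crosstalk_pca <- function(x, digits = 4, ...) {
  cat(sprintf("Cross-talk PCA correction: subject %s, %s side, %d cycle(s)\n",
              x$observed$subject, x$observed$side, x$n_cycles))
  print(x$transfer, digits = digits)
  cat("Variance contributions:",
      paste(format(x$eigen$var_explained, digits = digits), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
coef.crosstalk_pca <- function(object, ...) object$transfer$P

#' @export
fitted.crosstalk_pca <- function(object, ...) object$corrected

#' @rdname crosstalk_pca
#' @param object a fitted `"crosstalk_pca"`.
#' @param newdata a [subject_side()], a list of cycles, an n x 3 matrix of
#'   samples, or a length-3 angle triple; defaults to the training cycles.
#' @param ... unused.
#' @export
predict.crosstalk_pca <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$corrected)
  if (is.numeric(newdata) && is.null(dim(newdata)) &&
      length(newdata) == 3L)
    return(transfer_to_posture(newdata, object$transfer))
  if (is.matrix(newdata))
    return(apply_correction(newdata, object$transfer))
  nd <- as_subject_side(newdata)
  lapply(nd$cycles, apply_correction, P = object$transfer)
}

#' @export
residuals.crosstalk_pca <- function(object, ...) {
  Map(function(o, c) unclass(o) - unclass(c),
      object$observed$cycles, object$corrected)
}

#' @export
summary.crosstalk_pca <- function(object, ...) {
  met <- evaluate_subject(object$observed, object)
  structure(list(fit = object, metrics = met),
            class = "summary.crosstalk_pca")
}

#' @export
print.summary.crosstalk_pca <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  m <- x$metrics
  cat(sprintf("\nCross-talk r^2 (flexion vs abduction): %.4g -> %.4g\n",
              m$r2_before, m$r2_after))
  cat(sprintf("Profile variance, flexion   (deg^2): %.4g -> %.4g\n",
              m$d2_flex_before, m$d2_flex_after))
  cat(sprintf("Profile variance, abduction (deg^2): %.4g -> %.4g\n",
              m$d2_abd_before, m$d2_abd_after))
  cat(sprintf("Profile SD,       abduction (deg)  : %.4g -> %.4g\n",
              sqrt(m$d2_abd_before), sqrt(m$d2_abd_after)))
  if (!is.null(x$fit$posture_corrected)) {
    cat(sprintf("Posture abduction (deg): %.4g -> %.4g\n",
                x$fit$observed$posture[2], x$fit$posture_corrected[2]))
  }
  invisible(x)
}

#' Plot mean angle profiles before and after correction
#'
#' Draws the per-component mean profile over the gait cycle for the
#' observed (dashed) and corrected (solid) angles.
#'
#' @param x a fitted `"crosstalk_pca"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.crosstalk_pca <- function(x, ...) {
  pct <- 0:100
  labs <- c("Flexion/extension", "Ab/adduction", "Axial rotation")
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (j in 1:3) {
    before <- mean_profile(x$observed, j)
    after <- mean_profile(x$corrected, j)
    graphics::matplot(pct, cbind(before, after), type = "l",
                      lty = c(2, 1), col = c("grey40", "black"),
                      xlab = "Gait cycle (%)", ylab = "Angle (deg)",
                      main = labs[j], ...)
  }
  invisible(x)
}
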