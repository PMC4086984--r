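#' Pointwise mean profile across gait cycles
#'
#' Mean angle at each of the 101 gait cycle grid points across cycles, for
#' one component.
#'
#' @param cycles a [subject_side()] or a list of 101 x 3 cycle matrices.
#' @param component component name (`"flexion"`, `"abduction"`,
#'   `"rotation"`) or column index.
#' @return numeric vector of length 101 (degrees).
#' @export
mean_profile <- function(cycles, component = "flexion") {
  if (inherits(cycles, "subject_side")) cycles <- cycles$cycles
  if (!is.list(cycles) || length(cycles) < 1L)
    stop("`cycles` must be a non-empty list of cycles")
  if (is.character(component))
    component <- match(match.arg(component,
                                 c("flexion", "abduction", "rotation")),
                       c("flexion", "abduction", "rotation"))
  rowMeans(vapply(cycles, function(m) as.matrix(m)[, component],
                  numeric(nrow(as.matrix(cycles[[1]])))))
}

#' Cross-talk between two kinematic profiles
#'
#' Squared Pearson correlation between two angle series, the standard
#' measure of flexion-to-abduction cross-talk. If either input has zero
#' variance the correlation is undefined; 0 is returned with a warning and
#' attribute `zero_variance = TRUE`.
#'
#' @param x,y numeric vectors of equal length (typically 101-point
#'   profiles, or stacked samples).
#' @return squared correlation in `[0, 1]`.
#' @export
crosstalk_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (stats::var(x) <= 0 || stats::var(y) <= 0) {
    warning("zero-variance profile: cross-talk r^2 undefined, returning 0")
    return(structure(0, zero_variance = TRUE))
  }
  stats::cor(x, y)^2
}

#' Variance of a kinematic profile
#'
#' Variance of a 101-point angle profile about its mean, in squared
#' degrees; its square root (SD, in degrees) is often the more readable
#' scale and is reported alongside in summaries.
#'
#' @param profile numeric vector (degrees).
#' @param divisor `"unbiased"` for `1/(N-1)` (default) or `"ml"` for `1/N`.
#' @return variance in squared degrees.
#' @export
profile_variance <- function(profile, divisor = c("unbiased", "ml")) {
  divisor <- match.arg(divisor)
  n <- length(profile)
  v <- stats::var(profile)
  if (divisor == "ml") v <- v * (n - 1) / n
  v
}

#' Evaluate the correction for one subject/side
#'
#' Computes the three evaluation criteria before and after correction:
#' cross-talk r^2 between the flexion and abduction channels, profile
#' variance of the flexion and abduction mean profiles, and -- when a
#' posture trial and a ground-truth deformity are available -- the error of
#' the posture frontal-plane angle against the ground truth.
#'
#' `r2_mode = "stacked"` (default) computes the cross-talk correlation over
#' all stacked samples, the observations the PCA decorrelates, so the
#' corrected value is zero to machine precision. `"profile"` correlates the
#' two 101-point mean profiles instead; with cycle-to-cycle noise the
#' corrected profile correlation is near but not exactly zero.
#'
#' @param x the observed [subject_side()].
#' @param fit the [crosstalk_pca()] fit of `x`.
#' @param truth optional ground-truth frontal deformity in degrees (e.g.
#'   a radiographic varus/valgus measurement, or the generator's value).
#' @param r2_mode `"stacked"` or `"profile"`.
#' @return one-row data frame of class `"evaluation_metrics"`.
#' @export
evaluate_subject <- function(x, fit, truth = NULL,
                             r2_mode = c("stacked", "profile")) {
  r2_mode <- match.arg(r2_mode)
  x <- as_subject_side(x)
  stopifnot(inherits(fit, "crosstalk_pca"))
  if (!identical(length(x$cycles), length(fit$corrected)))
    stop("`fit` does not match `x`")
  r2_of <- function(cycles) {
    if (r2_mode == "stacked") {
      X <- do.call(rbind, cycles)
      crosstalk_r2(X[, 1], X[, 2])
    } else {
      crosstalk_r2(mean_profile(cycles, 1), mean_profile(cycles, 2))
    }
  }
  out <- data.frame(
    subject = x$subject, side = x$side, n_cycles = length(x$cycles),
    r2_before = as.numeric(r2_of(x$cycles)),
    r2_after = as.numeric(r2_of(fit$corrected)),
    d2_flex_before = profile_variance(mean_profile(x$cycles, 1)),
    d2_flex_after = profile_variance(mean_profile(fit$corrected, 1)),
    d2_abd_before = profile_variance(mean_profile(x$cycles, 2)),
    d2_abd_after = profile_variance(mean_profile(fit$corrected, 2)),
    posture_error_before = NA_real_, posture_error_after = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(truth) && !is.null(x$posture)) {
    out$posture_error_before <- x$posture[2] - truth
    out$posture_error_after <- fit$posture_corrected[2] - truth
  }
  class(out) <- c("evaluation_metrics", class(out))
  out
}

#' Group summary of evaluation metrics
#'
#' Mean and standard deviation of each evaluation metric across subjects,
#' per side, in the shape of a before/after summary table. With a single
#' subject the SD is reported as 0 and flagged (attribute
#' `single_subject`).
#'
#' @param metrics a list of (or single, or row-bound) `"evaluation_metrics"`.
#' @param side optional side filter (`"left"` or `"right"`).
#' @return data frame with columns `metric`, `side`, `n`, `mean_before`,
#'   `sd_before`, `mean_after`, `sd_after`.
#' @export
group_summary <- function(metrics, side = NULL) {
  if (inherits(metrics, "evaluation_metrics")) metrics <- list(metrics)
  m <- do.call(rbind, lapply(metrics, as.data.frame))
  if (!is.null(side)) m <- m[m$side == side, , drop = FALSE]
  if (nrow(m) < 1L) stop("no metrics to summarize")
  single <- FALSE
  one_side <- function(df, side_label) {
    quantities <- list(
      crosstalk_r2 = c("r2_before", "r2_after"),
      d2_flex = c("d2_flex_before", "d2_flex_after"),
      d2_abd = c("d2_abd_before", "d2_abd_after"),
      posture_error = c("posture_error_before", "posture_error_after"))
    rows <- lapply(names(quantities), function(q) {
      b <- df[[quantities[[q]][1]]]; a <- df[[quantities[[q]][2]]]
      b <- b[!is.na(b)]; a <- a[!is.na(a)]
      if (!length(b)) return(NULL)
      sdv <- function(v) if (length(v) < 2L) { single <<- TRUE; 0 }
                         else stats::sd(v)
      data.frame(metric = q, side = side_label, n = length(b),
                 mean_before = mean(b), sd_before = sdv(b),
                 mean_after = mean(a), sd_after = sdv(a))
    })
    do.call(rbind, rows)
  }
  out <- do.call(rbind, lapply(split(m, m$side), function(df)
    one_side(df, df$side[1])))
  rownames(out) <- NULL
  attr(out, "single_subject") <- single
  out
}
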