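#' Construct a raw frame-rate trial
#'
#' Holds unsegmented knee angle channels at the capture frame rate, with
#' missingness encoded as `NA`, plus optional anterior-posterior marker
#' coordinates used for gait event detection.
#'
#' @param angles T x 3 numeric matrix of angles in degrees; `NA` marks
#'   missing samples.
#' @param sample_rate sampling rate in Hz.
#' @param heel,toe,sacrum optional length-T anterior-posterior marker
#'   coordinates (mm) of the heel, toe and sacrum markers.
#' @return An object of class `"raw_trial"`.
#' @export
raw_trial <- function(angles, sample_rate = 100,
                      heel = NULL, toe = NULL, sacrum = NULL) {
  angles <- as.matrix(angles)
  if (ncol(angles) != 3L || nrow(angles) < 2L)
    stop("`angles` must be a T x 3 matrix with T >= 2")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("`sample_rate` must be positive")
  storage.mode(angles) <- "double"
  colnames(angles) <- c("flexion", "abduction", "rotation")
  for (m in list(heel, toe, sacrum))
    if (!is.null(m) && length(m) != nrow(angles))
      stop("marker tracks must have one sample per angle frame")
  structure(list(angles = angles, sample_rate = sample_rate,
                 heel = heel, toe = toe, sacrum = sacrum),
            class = "raw_trial")
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf("Raw trial: %d frames at %g Hz, %d missing sample(s)%s\n",
              nrow(x$angles), x$sample_rate, sum(is.na(x$angles)),
              if (is.null(x$heel)) "" else ", event markers present"))
  invisible(x)
}

# runs of NA in a logical vector -> data.frame(start, end, length)
na_runs <- function(miss) {
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Fill short gaps by cubic spline interpolation
#'
#' Gaps of at most `max_gap` consecutive missing frames in each angle
#' channel are filled with a cubic interpolating spline fitted to the valid
#' samples; longer gaps are left missing (cycles containing them are
#' rejected later by [segment_cycles()]). The "fmm" spline end condition is
#' used, which reproduces cubic polynomials exactly.
#'
#' @param trial a [raw_trial()].
#' @param max_gap longest gap (frames) that is filled; the default 9 pairs
#'   with the rejection of cycles holding gaps of 10 frames or more.
#' @return the trial with short gaps filled; remaining gaps are listed in
#'   `attr(, "unfilled")`.
#' @export
interpolate_gaps <- function(trial, max_gap = 9) {
  stopifnot(inherits(trial, "raw_trial"))
  if (max_gap < 0) stop("`max_gap` must be >= 0")
  A <- trial$angles
  unfilled <- list()
  for (ch in seq_len(ncol(A))) {
    y <- A[, ch]
    miss <- is.na(y)
    if (!any(miss)) next
    if (all(miss))
      stop("channel ", colnames(A)[ch],
           " is entirely missing: unusable trial")
    runs <- na_runs(miss)
    ok <- which(!miss)
    for (g in seq_len(nrow(runs))) {
      if (runs$length[g] > max_gap) {
        unfilled[[length(unfilled) + 1L]] <-
          data.frame(channel = colnames(A)[ch], start = runs$start[g],
                     end = runs$end[g], length = runs$length[g])
        next
      }
      idx <- runs$start[g]:runs$end[g]
      y[idx] <- stats::spline(ok, A[ok, ch], xout = idx,
                              method = "fmm")$y
    }
    A[, ch] <- y
  }
  trial$angles <- A
  attr(trial, "unfilled") <-
    if (length(unfilled)) do.call(rbind, unfilled) else NULL
  trial
}

#' Smooth angle channels with a cross-validated smoothing spline
#'
#' Each gap-free angle channel is fitted with a cubic smoothing spline.
#' By default the roughness penalty is chosen by generalized
#' cross-validation ([stats::smooth.spline()]); passing an explicit
#' `roughness` fixes the penalty (`lambda`), and `roughness = 0` is the
#' interpolating limit, returning the input unchanged.
#'
#' @param trial a gap-free [raw_trial()].
#' @param roughness `NULL` for GCV, or a nonnegative penalty weight.
#' @return the trial with smoothed angle channels.
#' @export
smooth_trial <- function(trial, roughness = NULL) {
  stopifnot(inherits(trial, "raw_trial"))
  A <- trial$angles
  if (anyNA(A))
    stop("smoothing requires a gap-free trial; run interpolate_gaps() first")
  if (!is.null(roughness)) {
    if (roughness < 0) stop("`roughness` must be >= 0")
    if (roughness == 0) return(trial)
  }
  x <- seq_len(nrow(A))
  for (ch in seq_len(ncol(A))) {
    if (stats::sd(A[, ch]) == 0) next  # constant channel is its own fit
    fit <- if (is.null(roughness))
      stats::smooth.spline(x, A[, ch])
    else
      stats::smooth.spline(x, A[, ch], lambda = roughness)
    A[, ch] <- stats::predict(fit, x)$y
  }
  trial$angles <- A
  trial
}

# strict local extrema of a series; ties broken by earliest frame
local_extrema <- function(y, what = c("max", "min")) {
  what <- match.arg(what)
  if (what == "min") y <- -y
  n <- length(y)
  out <- integer(0)
  i <- 2L
  while (i < n) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L  # plateau
      if (j < n && y[j + 1L] < y[j]) out <- c(out, i)  # earliest frame of tie
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Detect gait events from marker trajectories
#'
#' Coordinate-based event detection: heel strikes are the local maxima of
#' the heel-minus-sacrum anterior-posterior distance, toe offs the local
#' minima of the toe-minus-sacrum distance.
#'
#' @param trial a [raw_trial()] carrying heel, toe and sacrum tracks.
#' @return An object of class `"gait_events"`: list with integer frame
#'   vectors `heel_strikes` and `toe_offs`.
#' @export
detect_events <- function(trial) {
  stopifnot(inherits(trial, "raw_trial"))
  if (is.null(trial$heel) || is.null(trial$toe) || is.null(trial$sacrum))
    stop("event detection needs heel, toe and sacrum marker tracks")
  hs <- local_extrema(trial$heel - trial$sacrum, "max")
  to <- local_extrema(trial$toe - trial$sacrum, "min")
  if (length(hs) < 2L)
    stop("fewer than two heel strikes detected: no complete gait cycle")
  structure(list(heel_strikes = hs, toe_offs = to), class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("Gait events: %d heel strike(s), %d toe off(s)\n",
              length(x$heel_strikes), length(x$toe_offs)))
  invisible(x)
}

#' Segment strides and time-normalize to 101 points
#'
#' Cuts the trial at successive heel strikes and resamples each stride to
#' 101 points at equal intervals from 0 to 100 percent of the gait cycle,
#' by cubic spline interpolation of each angle channel. Strides containing
#' an unfilled gap are dropped, with the reason recorded.
#'
#' @param trial a [raw_trial()] (gaps filled where possible).
#' @param events a [gait_events()] object, or a list with element
#'   `heel_strikes` (e.g. event frames supplied by a manifest).
#' @return list with `cycles` (list of [angle_cycle()] matrices) and
#'   `rejected` (data frame of dropped strides with reasons); the two
#'   always account for every stride.
#' @export
segment_cycles <- function(trial, events) {
  stopifnot(inherits(trial, "raw_trial"))
  hs <- events$heel_strikes
  if (is.null(hs) || length(hs) < 2L)
    stop("need at least two heel strikes to segment a cycle")
  hs <- sort(as.integer(hs))
  if (hs[1] < 1L || hs[length(hs)] > nrow(trial$angles))
    stop("heel strike frames outside the trial")
  cycles <- list()
  rejected <- data.frame(stride = integer(0), reason = character(0))
  for (i in seq_len(length(hs) - 1L)) {
    rows <- hs[i]:hs[i + 1L]
    seg <- trial$angles[rows, , drop = FALSE]
    if (anyNA(seg)) {
      rejected <- rbind(rejected,
                        data.frame(stride = i, reason = "unfilled gap"))
      next
    }
    grid <- seq(hs[i], hs[i + 1L], length.out = 101L)
    out <- vapply(seq_len(3L), function(ch)
      stats::spline(rows, seg[, ch], xout = grid, method = "fmm")$y,
      numeric(101L))
    cycles[[length(cycles) + 1L]] <- angle_cycle(out)
  }
  list(cycles = cycles, rejected = rejected)
}
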