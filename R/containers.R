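#' Validate and label one time-normalized gait cycle
#'
#' A gait cycle is a 101 x 3 matrix of knee angles in degrees, rows indexed
#' 0..100 percent of the cycle (heel strike to ipsilateral heel strike),
#' columns flexion, abduction, rotation.
#'
#' @param x 101 x 3 numeric matrix (degrees), no missing values.
#' @return `x` with canonical column names and class `"angle_cycle"`.
#' @export
angle_cycle <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) != 101L || ncol(x) != 3L)
    stop("an angle cycle must be a 101 x 3 matrix, got ",
         nrow(x), " x ", ncol(x))
  if (!all(is.finite(x)))
    stop("an angle cycle must not contain missing values")
  storage.mode(x) <- "double"
  colnames(x) <- c("flexion", "abduction", "rotation")
  class(x) <- c("angle_cycle", class(unclass(x)))
  x
}

#' Bundle the gait cycles of one subject and side
#'
#' The unit on which one transfer matrix is fitted: all cycles of one
#' subject/side, optionally with the mean angles of a static posture trial.
#'
#' @param cycles list of 101 x 3 angle matrices (see [angle_cycle()]).
#' @param subject subject identifier.
#' @param side `"left"` or `"right"`.
#' @param posture optional length-3 vector of static trial mean angles
#'   (degrees), used for posture transfer.
#' @return An object of class `"subject_side"`.
#' @seealso [crosstalk_pca()], [simulate_subject()]
#' @export
subject_side <- function(cycles, subject = "S1",
                         side = c("right", "left"), posture = NULL) {
  side <- match.arg(side)
  if (!is.list(cycles) || length(cycles) < 1L)
    stop("`cycles` must be a non-empty list of 101 x 3 matrices")
  cycles <- lapply(cycles, angle_cycle)
  if (!is.null(posture)) {
    posture <- as.numeric(posture)
    if (length(posture) != 3L || !all(is.finite(posture)))
      stop("`posture` must be three finite angles (degrees)")
    names(posture) <- c("flexion", "abduction", "rotation")
  }
  structure(list(subject = subject, side = side,
                 cycles = cycles, posture = posture),
            class = "subject_side")
}

#' @export
print.subject_side <- function(x, ...) {
  cat(sprintf("Subject %s, %s side: %d gait cycle(s)%s\n",
              x$subject, x$side, length(x$cycles),
              if (is.null(x$posture)) "" else ", posture trial present"))
  invisible(x)
}

# coerce lists / matrices to subject_side where a fit expects one
as_subject_side <- function(x) {
  if (inherits(x, "subject_side")) return(x)
  if (is.list(x) && length(x) && is.matrix(x[[1]]))
    return(subject_side(x))
  if (is.matrix(x)) return(subject_side(list(x)))
  stop("expected a subject_side, a list of cycles, or a single cycle matrix")
}
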