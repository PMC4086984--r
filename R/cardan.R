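#' Cardan angle sequence convention
#'
#' Fixes the ordered rotation axes used to compose and decompose knee joint
#' angles. The default follows the standard gait convention implied by the
#' Plug-in-Gait segment frames: flexion/extension about the mediolateral
#' axis (`"y"`), ab/adduction about the anterior axis (`"x"`), axial rotation
#' about the longitudinal axis (`"z"`), applied in that order as intrinsic
#' rotations. Axes are right-handed; `x` points anteriorly, `y` to the
#' subject's left, `z` proximally (toward the hip).
#'
#' With this frame, positive ab/adduction corresponds to varus for a right
#' knee. For left-side data recorded in a mirrored lab convention, supply
#' `signs = c(1, -1, -1)` so that positive abduction means varus on both
#' sides; the signs are applied to angle triples on input and output.
#'
#' @param axes character vector of three distinct axis letters among
#'   `"x"`, `"y"`, `"z"`: the rotation axes of the flexion, abduction and
#'   rotation components, in sequence order.
#' @param signs numeric vector of three values in `{-1, 1}` mapping stored
#'   angles to the right-handed frame (side convention).
#' @param labels names of the three angle components.
#' @return An object of class `"cardan_convention"`.
#' @examples
#' conv <- cardan_convention()
#' cardan_to_matrix(c(30, 5, -2), conv)
#' @seealso [cardan_to_matrix()], [matrix_to_cardan()]
#' @export
cardan_convention <- function(axes = c("y", "x", "z"),
                              signs = c(1, 1, 1),
                              labels = c("flexion", "abduction", "rotation")) {
  axes <- match.arg(axes, c("x", "y", "z"), several.ok = TRUE)
  if (length(axes) != 3L || anyDuplicated(axes))
    stop("`axes` must be a permutation of c(\"x\", \"y\", \"z\")")
  if (length(signs) != 3L || !all(signs %in% c(-1, 1)))
    stop("`signs` must be three values in {-1, 1}")
  if (length(labels) != 3L) stop("`labels` must have length 3")
  structure(
    list(axes = axes, idx = match(axes, c("x", "y", "z")),
         signs = as.numeric(signs), labels = labels),
    class = "cardan_convention"
  )
}

#' @export
print.cardan_convention <- function(x, ...) {
  cat("Cardan sequence:",
      paste(sprintf("%s (%s)", x$labels, x$axes), collapse = " -> "), "\n")
  if (any(x$signs != 1))
    cat("Component signs:", paste(x$signs, collapse = ", "), "\n")
  invisible(x)
}

as_convention <- function(conv) {
  if (is.null(conv)) return(cardan_convention())
  if (!inherits(conv, "cardan_convention"))
    stop("`convention` must be created by cardan_convention()")
  conv
}

# Elementary active rotation about coordinate axis i (1=x, 2=y, 3=z), radians.
elementary_rotation <- function(i, theta) {
  c <- cos(theta); s <- sin(theta)
  R <- diag(3)
  if (i == 1L) { R[2, 2] <- c; R[2, 3] <- -s; R[3, 2] <- s; R[3, 3] <- c }
  if (i == 2L) { R[1, 1] <- c; R[1, 3] <- s; R[3, 1] <- -s; R[3, 3] <- c }
  if (i == 3L) { R[1, 1] <- c; R[1, 2] <- -s; R[2, 1] <- s; R[2, 2] <- c }
  R
}

levi_civita <- function(i, j, k) {
  p <- c(i, j, k)
  if (identical(p, c(1L, 2L, 3L)) || identical(p, c(2L, 3L, 1L)) ||
      identical(p, c(3L, 1L, 2L))) 1 else -1
}

#' Compose a rotation matrix from Cardan angles
#'
#' Multiplies the three elementary rotations of the sequence convention:
#' `R = R_a1(theta1) %*% R_a2(theta2) %*% R_a3(theta3)`, angles in degrees.
#'
#' @param angles numeric length-3 vector `(flexion, abduction, rotation)`
#'   in degrees.
#' @param convention a [cardan_convention()].
#' @return 3x3 orthonormal rotation matrix (determinant +1).
#' @examples
#' R <- cardan_to_matrix(c(30, 10, -5))
#' max(abs(crossprod(R) - diag(3)))  # orthonormal
#' @export
cardan_to_matrix <- function(angles, convention = cardan_convention()) {
  convention <- as_convention(convention)
  angles <- as.numeric(angles)
  if (length(angles) != 3L || !all(is.finite(angles)))
    stop("`angles` must be three finite values (degrees)")
  th <- angles * convention$signs * pi / 180
  i <- convention$idx
  elementary_rotation(i[1], th[1]) %*%
    elementary_rotation(i[2], th[2]) %*%
    elementary_rotation(i[3], th[3])
}

#' Decompose a rotation matrix into Cardan angles
#'
#' Inverse of [cardan_to_matrix()] for the same sequence convention. The
#' decomposition is unique on the gimbal-safe band (middle angle away from
#' +/-90 degrees); at gimbal lock the first and third axes coincide and an
#' error is raised.
#'
#' @param R 3x3 orthonormal rotation matrix.
#' @param convention a [cardan_convention()].
#' @param tol_gimbal distance (radians) from +/-pi/2 below which the middle
#'   angle is treated as gimbal-locked.
#' @return named numeric length-3 vector of angles in degrees.
#' @examples
#' matrix_to_cardan(cardan_to_matrix(c(30, 10, -5)))
#' @export
matrix_to_cardan <- function(R, convention = cardan_convention(),
                             tol_gimbal = 1e-6) {
  convention <- as_convention(convention)
  R <- as.matrix(R)
  if (!all(dim(R) == c(3L, 3L)) || !all(is.finite(R)))
    stop("`R` must be a finite 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("`R` is not orthonormal")
  i <- convention$idx[1]; j <- convention$idx[2]; k <- convention$idx[3]
  eps <- levi_civita(i, j, k)
  s2 <- max(-1, min(1, eps * R[i, k]))
  th2 <- asin(s2)
  if (pi / 2 - abs(th2) < tol_gimbal)
    stop("gimbal lock: middle Cardan angle at +/-90 degrees, ",
         "decomposition is degenerate")
  th1 <- atan2(-eps * R[j, k], R[k, k])
  th3 <- atan2(-eps * R[i, j], R[i, i])
  ang <- c(th1, th2, th3) * 180 / pi * convention$signs
  names(ang) <- convention$labels
  ang
}

#' Build a coordinate-system misalignment rotation
#'
#' Rotation matrix describing a malpositioned joint coordinate system,
#' e.g. from marker placement error. Anatomical axis names refer to the
#' femoral frame of the default convention: `"longitudinal"` (z, toward the
#' hip -- the classic malrotation that tilts the flexion axis in the
#' transverse plane and converts flexion into spurious varus/valgus),
#' `"anterior"` (x) and `"mediolateral"` (y, the flexion axis itself).
#'
#' @param angle misalignment magnitude in degrees (|angle| < 45).
#' @param axis axis name or numeric length-3 axis vector (need not be unit).
#' @return 3x3 rotation matrix.
#' @examples
#' misalignment_matrix(10)  # 10 degrees about the longitudinal axis
#' @export
misalignment_matrix <- function(angle, axis = "longitudinal") {
  if (!is.finite(angle) || abs(angle) >= 45)
    stop("|angle| must be finite and below 45 degrees")
  if (is.character(axis)) {
    axis <- switch(match.arg(axis, c("longitudinal", "anterior", "mediolateral")),
                   longitudinal = c(0, 0, 1),
                   anterior = c(1, 0, 0),
                   mediolateral = c(0, 1, 0))
  }
  u <- as.numeric(axis)
  n <- sqrt(sum(u^2))
  if (length(u) != 3L || !all(is.finite(u)) || n == 0)
    stop("`axis` must be a named axis or a nonzero length-3 vector")
  u <- u / n
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a coordinate-system misalignment to Cardan angles
#'
#' Simulates the effect of a malpositioned joint coordinate system on
#' measured angles. With `frame = "proximal"` the observed joint rotation is
#' `mis %*% R(angles)` (only the proximal/femoral frame is reoriented);
#' `"distal"` post-multiplies; `"shared"` conjugates,
#' `mis %*% R(angles) %*% t(mis)`, modelling an error that reorients both
#' segment frames identically (as when the shared knee marker that defines
#' the flexion axis of thigh and shank is misplaced). With the identity
#' misalignment the angles are returned unchanged for every frame model.
#'
#' @param angles length-3 vector or n x 3 matrix of Cardan angles (degrees).
#' @param mis 3x3 misalignment rotation, see [misalignment_matrix()].
#' @param convention a [cardan_convention()].
#' @param frame which segment frame(s) the misalignment affects.
#' @return object of the same shape as `angles`.
#' @examples
#' mis <- misalignment_matrix(10, "longitudinal")
#' apply_misalignment(c(60, 0, 0), mis)  # spurious abduction appears
#' @export
apply_misalignment <- function(angles, mis, convention = cardan_convention(),
                               frame = c("proximal", "shared", "distal")) {
  frame <- match.arg(frame)
  convention <- as_convention(convention)
  mis <- as.matrix(mis)
  if (max(abs(crossprod(mis) - diag(3))) > 1e-8)
    stop("`mis` must be orthonormal")
  one <- function(a) {
    R <- cardan_to_matrix(a, convention)
    Robs <- switch(frame,
                   proximal = mis %*% R,
                   distal = R %*% mis,
                   shared = mis %*% R %*% t(mis))
    matrix_to_cardan(Robs, convention)
  }
  if (is.matrix(angles)) {
    out <- t(apply(angles, 1, one))
    dimnames(out) <- list(rownames(angles), as_convention(convention)$labels)
    out
  } else {
    one(angles)
  }
}
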