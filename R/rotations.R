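#' Elementary rotation matrices
#'
#' Right-handed rotations about the lab/segment axes, used to build and
#' decompose inter-segment orientations. Angles are in degrees throughout
#' the package; radians appear only inside these helpers.
#'
#' @param angle rotation angle in degrees.
#' @return a 3x3 orthonormal rotation matrix.
#' @keywords internal
#' @name elementary-rotations
NULL

#' @rdname elementary-rotations
rot_x <- function(angle) {
  a <- angle * pi / 180
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}

#' @rdname elementary-rotations
rot_y <- function(angle) {
  a <- angle * pi / 180
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' @rdname elementary-rotations
rot_z <- function(angle) {
  a <- angle * pi / 180
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' Compose a rotation from Cardan x-y-z angles
#'
#' Builds `R = Rx(sagittal) %*% Ry(frontal) %*% Rz(transverse)`. In the
#' joint convention used here x is the mediolateral axis (positive sagittal
#' angle = dorsiflexion), y the anteroposterior axis (positive frontal
#' angle = inversion, so eversion prints negative) and z the vertical axis
#' (transverse rotation).
#'
#' @param sagittal,frontal,transverse angles in degrees.
#' @return a 3x3 rotation matrix.
#' @seealso [cardan_xyz()] for the inverse.
#' @export
#' @examples
#' cardan_xyz(cardan_compose(10, -20, 15))
cardan_compose <- function(sagittal, frontal, transverse) {
  rot_x(sagittal) %*% rot_y(frontal) %*% rot_z(transverse)
}

#' Decompose a rotation into Cardan x-y-z angles
#'
#' Inverse of [cardan_compose()]: recovers `(sagittal, frontal, transverse)`
#' in degrees from an orthonormal rotation matrix. When the frontal angle is
#' within the gimbal guard of +/-90 degrees the sagittal/transverse split is
#' undefined; a classed warning is raised and the fallback convention
#' `transverse = 0` is applied (never silently).
#'
#' @param R a 3x3 orthonormal rotation matrix (determinant +1).
#' @param gimbal_guard proximity to +/-90 degrees frontal (in radians of the
#'   middle angle's cosine) below which the decomposition is flagged.
#' @return named numeric vector `c(sagittal, frontal, transverse)` degrees.
#' @export
cardan_xyz <- function(R, gimbal_guard = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || !all(is.finite(R))) {
    fk_stop("`R` must be a finite 3x3 matrix", "footkin_contract_error")
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0) {
    fk_stop("`R` is not an orthonormal rotation (det +1)",
            "footkin_contract_error")
  }
  sb <- max(-1, min(1, R[1, 3]))
  beta <- asin(sb)
  if (abs(cos(beta)) <= gimbal_guard) {
    fk_warn("frontal angle at gimbal lock; using fallback transverse = 0",
            "footkin_gimbal_warning")
    alpha <- atan2(R[3, 2], R[2, 2])
    gamma <- 0
  } else {
    alpha <- atan2(-R[2, 3], R[3, 3])
    gamma <- atan2(-R[1, 2], R[1, 1])
  }
  c(sagittal = alpha, frontal = beta, transverse = gamma) * 180 / pi
}
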