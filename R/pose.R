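#' Leg local coordinate system from anatomical markers
#'
#' The vertical (z) axis joins the malleolar midpoint to the knee-margin
#' midpoint; the anteroposterior (y) axis is the unit normal of the
#' least-squares frontal plane (the plane containing the z direction that
#' minimizes the summed squared out-of-plane distance of the four
#' anatomical points; a 1-DOF problem solved in closed form), oriented
#' anteriorly; x completes the right-handed frame (mediolateral).
#'
#' @param points 4x3 matrix of anatomical marker positions (mm), rows
#'   medial/lateral malleolus then medial/lateral knee margin. Rows may be
#'   named `med_malleolus`, `lat_malleolus`, `med_knee`, `lat_knee`; when
#'   named, rows are matched by name.
#' @param anterior lab-frame direction used to fix the sign of y
#'   (direction of progression).
#' @return list with `rotation` (3x3, columns = x, y, z axes of the LCS in
#'   lab coordinates, i.e. LCS -> lab) and `origin` (malleolar midpoint).
#' @export
#' @examples
#' pts <- rbind(c(40, 0, 0), c(-40, 0, 0), c(50, 0, 400), c(-50, 0, 400))
#' build_leg_lcs(pts)$rotation
build_leg_lcs <- function(points, anterior = c(0, 1, 0)) {
  nm <- c("med_malleolus", "lat_malleolus", "med_knee", "lat_knee")
  if (!is.matrix(points) || nrow(points) != 4L || ncol(points) != 3L ||
      !all(is.finite(points))) {
    fk_stop("`points` must be a finite 4x3 matrix", "footkin_contract_error")
  }
  if (!is.null(rownames(points)) && all(nm %in% rownames(points))) {
    points <- points[nm, , drop = FALSE]
  }
  ctr <- sweep(points, 2, colMeans(points))
  if (svd(ctr)$d[2] < 1e-8) {
    fk_stop("anatomical points are collinear or coincident",
            "footkin_geometry_error")
  }
  mall_mid <- (points[1, ] + points[2, ]) / 2
  knee_mid <- (points[3, ] + points[4, ]) / 2
  zv <- knee_mid - mall_mid
  if (sqrt(sum(zv^2)) < 1e-8) {
    fk_stop("malleolar and knee midpoints coincide", "footkin_geometry_error")
  }
  z <- zv / sqrt(sum(zv^2))
  # orthonormal basis of the plane normal space: candidates perpendicular to z
  ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- ref - sum(ref * z) * z
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(z[2] * u1[3] - z[3] * u1[2],
          z[3] * u1[1] - z[1] * u1[3],
          z[1] * u1[2] - z[2] * u1[1])
  a <- drop(ctr %*% u1)
  b <- drop(ctr %*% u2)
  M <- matrix(c(sum(a * a), sum(a * b), sum(a * b), sum(b * b)), 2, 2)
  ev <- eigen(M, symmetric = TRUE)
  n2 <- ev$vectors[, 2]  # eigenvector of the smaller eigenvalue
  y <- n2[1] * u1 + n2[2] * u2
  if (sum(y * anterior) < 0) y <- -y
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  x <- x / sqrt(sum(x^2))
  R <- cbind(x, y, z)
  dimnames(R) <- NULL
  list(rotation = R, origin = mall_mid)
}

#' Least-squares rigid pose from paired marker clusters
#'
#' SVD-based Procrustes fit of the rigid transform (rotation + translation,
#' no scaling) mapping a reference cluster onto an observed cluster,
#' minimizing the summed squared point residuals. Rows are paired by
#' rowname when both matrices are labelled (mismatched labels are a schema
#' error); rows containing `NA` in either cluster are dropped.
#'
#' @param reference,frame n x 3 matrices of paired points (n >= 3,
#'   non-collinear).
#' @return list with `rotation` (3x3, reference -> frame, det +1),
#'   `translation` (length 3) and `rms` residual in mm.
#' @export
#' @examples
#' ref <- rbind(c(0, 0, 0), c(50, 0, 0), c(0, 50, 0))
#' fit_rigid_pose(ref, ref + rep(c(10, 0, 0), each = 3))
fit_rigid_pose <- function(reference, frame) {
  if (!is.null(rownames(reference)) && !is.null(rownames(frame))) {
    if (!setequal(rownames(reference), rownames(frame))) {
      fk_stop("cluster labels do not match between reference and frame",
              "footkin_schema_error")
    }
    frame <- frame[rownames(reference), , drop = FALSE]
  } else if (nrow(reference) != nrow(frame)) {
    fk_stop("clusters must contain the same points", "footkin_schema_error")
  }
  ok <- stats::complete.cases(reference) & stats::complete.cases(frame)
  reference <- reference[ok, , drop = FALSE]
  frame <- frame[ok, , drop = FALSE]
  if (nrow(reference) < 3L) {
    fk_stop("need >= 3 complete paired points", "footkin_geometry_error")
  }
  cr <- colMeans(reference)
  cf <- colMeans(frame)
  A <- sweep(reference, 2, cr)
  B <- sweep(frame, 2, cf)
  if (svd(A)$d[2] < 1e-8) {
    fk_stop("reference cluster is collinear", "footkin_geometry_error")
  }
  H <- crossprod(A, B)  # sum over points of a_i b_i^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cf - drop(R %*% cr)
  res <- B - A %*% t(R)
  list(rotation = R, translation = tr,
       rms = sqrt(mean(rowSums(res^2))))
}
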