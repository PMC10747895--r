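#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation plus a translation, applied as
#' `x' = R x + t` (coordinates in Angstrom). It is the currency of
#' superposition, grafting, ring stacking and map fitting.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation numeric length-3 translation (Angstrom).
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' tf <- rigid_transform(rotation_about_axis(c(0, 0, 1), pi / 2), c(1, 2, 3))
#' apply_transform(tf, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthogonal (R'R != I within 1e-8)")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation is not proper (det != +1): reflections are not rigid transforms")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(sprintf("%.4f", x$translation), collapse = " "), "\n")
  invisible(x)
}

#' Identity transform
#' @return A `rigid_transform` that leaves coordinates unchanged.
#' @export
identity_transform <- function() rigid_transform()

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` radians about the (normalized) `axis`.
#'
#' @param axis numeric length-3 direction (need not be unit length).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- as.numeric(axis)
  n <- sqrt(sum(u^2))
  if (n < 1e-12) stop("axis direction has zero length")
  u <- u / n
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Apply a rigid transform to coordinates
#'
#' @param tf a `rigid_transform`.
#' @param x numeric length-3 vector or an N x 3 coordinate matrix.
#' @return Transformed coordinates with the same shape as `x`.
#' @export
apply_transform <- function(tf, x) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (is.null(dim(x))) {
    as.numeric(tf$rotation %*% as.numeric(x) + tf$translation)
  } else {
    sweep(as.matrix(x) %*% t(tf$rotation), 2, tf$translation, "+")
  }
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` first, then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  Rt <- t(tf$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% tf$translation))
}

#' Rotation angle and axis of a transform
#'
#' Extracts the screw parameters of a rigid transform: rotation angle
#' (radians), unit rotation axis, and the translation component along that
#' axis (the helical rise when the transform is a ring-to-ring generator).
#'
#' @param tf a `rigid_transform`.
#' @return list with `angle` (radians), `axis` (unit 3-vector) and
#'   `rise` (Angstrom, translation projected on the axis).
#' @export
transform_screw <- function(tf) {
  R <- tf$rotation
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-9) {
    tn <- sqrt(sum(tf$translation^2))
    axis <- if (tn > 1e-12) tf$translation / tn else c(0, 0, 1)
    return(list(angle = 0, axis = axis, rise = sum(tf$translation * axis)))
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(v^2)) < 1e-9) {
    # angle ~ pi: axis from R + I columns
    M <- R + diag(3)
    j <- which.max(colSums(M^2))
    v <- M[, j]
  }
  axis <- v / sqrt(sum(v^2))
  list(angle = ang, axis = axis, rise = sum(tf$translation * axis))
}

#' Draw a random rigid transform
#'
#' Uniform random rotation (via normalized quaternion) plus a translation
#' with components uniform in `[-max_shift, max_shift]`. Uses R's global
#' random stream, so it respects `set.seed()`.
#'
#' @param max_shift maximum absolute translation per component (Angstrom).
#' @return A `rigid_transform`.
#' @export
random_rigid_transform <- function(max_shift = 20) {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)), 3, 3,
    byrow = TRUE)
  rigid_transform(R, stats::runif(3, -max_shift, max_shift))
}
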