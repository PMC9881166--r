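## Rigid-body geometry: least-squares superposition (Kabsch), axis-angle and
## screw decompositions. Angles are reported in degrees throughout the package;
## radians are used internally.

DEG <- 180 / pi

unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Rotation matrix from axis and angle
#'
#' Builds the proper rotation matrix for a right-handed rotation of
#' \code{angle} degrees about the (automatically normalized) \code{axis},
#' via the Rodrigues formula.
#'
#' @param axis numeric 3-vector, rotation axis (need not be unit length).
#' @param angle rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @export
rot_axis_angle <- function(axis, angle) {
  u <- unitv(axis)
  a <- angle / DEG
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Rigid transform (proper rotation + translation)
#'
#' Constructs a validated rigid transform \code{x -> R x + t}. The rotation
#' must be orthonormal with determinant +1 to within \code{tol}.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric 3-vector (Angstrom).
#' @param tol orthonormality tolerance (default 1e-9).
#' @return an object of class \code{rad_transform} with elements \code{R}, \code{t}.
#' @export
rad_transform <- function(rotation, translation = c(0, 0, 0), tol = 1e-9) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > tol) stop("rotation is not orthonormal (max deviation ", format(err), ")")
  if (det(rotation) < 0) stop("improper rotation (det < 0)")
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rad_transform")
}

#' @export
print.rad_transform <- function(x, ...) {
  aa <- axis_angle(x)
  cat("rad_transform: rotation", format(aa$angle, digits = 6), "deg,",
      "|t| =", format(sqrt(sum(x$t^2)), digits = 6), "A\n")
  invisible(x)
}

as_rotation <- function(x) {
  if (inherits(x, "rad_transform")) x$R else as.matrix(x)
}

#' Compose and invert rigid transforms
#'
#' \code{compose_transform(a, b)} is the transform "apply b, then a";
#' \code{invert_transform(a)} is the inverse transform.
#'
#' @param a,b \code{rad_transform} objects.
#' @return a \code{rad_transform}.
#' @export
compose_transform <- function(a, b) {
  rad_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(a) {
  Rt <- t(a$R)
  rad_transform(Rt, as.numeric(-Rt %*% a$t))
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a \code{rad_transform}.
#' @param xyz N x 3 coordinate matrix (or length-3 vector).
#' @return transformed coordinates, same shape as input.
#' @export
apply_transform <- function(transform, xyz) {
  if (is.null(dim(xyz))) {
    as.numeric(transform$R %*% xyz) + transform$t
  } else {
    out <- t(transform$R %*% t(xyz)) +
      matrix(transform$t, nrow(xyz), 3, byrow = TRUE)
    dimnames(out) <- dimnames(xyz)
    out
  }
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation mapping \code{model_points} onto
#' \code{ref_points} with minimal (weighted) least-squares deviation. A
#' reflection guard enforces det(R) = +1, so mirror-image inputs yield the
#' best proper rotation with a non-zero residual.
#'
#' @param ref_points,model_points N x 3 matrices, N >= 3, matched row-wise.
#' @param weights optional non-negative weights of length N.
#' @return list with \code{transform} (a \code{rad_transform} such that
#'   \code{apply_transform(transform, model_points)} best fits
#'   \code{ref_points}) and \code{rmsd} (weighted RMSD, Angstrom).
#' @export
superpose <- function(ref_points, model_points, weights = NULL) {
  ref_points <- as.matrix(ref_points)
  model_points <- as.matrix(model_points)
  n <- nrow(ref_points)
  if (n < 3 || nrow(model_points) != n)
    stop("superpose requires two matched sets of at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  w <- weights / sum(weights)

  rbar <- colSums(ref_points * w)
  mbar <- colSums(model_points * w)
  rc <- sweep(ref_points, 2, rbar)
  mc <- sweep(model_points, 2, mbar)

  ## collinearity guard: the second principal extent must be non-degenerate
  sv <- svd(rc * sqrt(w))$d
  if (sv[2] < 1e-8 * max(sv[1], 1e-8))
    stop("degenerate (collinear) point set; rotation is underdetermined")

  H <- t(mc * w) %*% rc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  Rm <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- rad_transform(Rm, rbar - as.numeric(Rm %*% mbar), tol = 1e-6)
  ## re-orthonormalize to full precision (guards accumulated roundoff)
  tr <- rad_transform(project_so3(tr$R), tr$t)
  dev <- apply_transform(tr, model_points) - ref_points
  rmsd <- sqrt(sum(w * rowSums(dev^2)))
  list(transform = tr, rmsd = rmsd)
}

## nearest proper-orthogonal matrix (polar projection via SVD)
project_so3 <- function(R) {
  s <- svd(R)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Axis-angle decomposition of a rotation
#'
#' Returns the rotation angle in [0, 180] degrees and the unit axis for a
#' right-handed rotation by +angle. Near-zero rotations are flagged
#' degenerate and carry a NULL axis.
#'
#' @param transform a \code{rad_transform} or 3x3 rotation matrix.
#' @param tol angle (degrees) below which the axis is considered undefined.
#' @return list(axis, angle, degenerate).
#' @export
axis_angle <- function(transform, tol = 1e-7) {
  R <- as_rotation(transform)
  ang <- rotation_angle_deg(R)
  if (ang < tol)
    return(list(axis = NULL, angle = ang, degenerate = TRUE))
  if (ang < 180 - 1e-4) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    ax <- unitv(ax)
  } else {
    ## near 180 deg: axis from the dominant column of (R + I)/2
    B <- (R + diag(3)) / 2
    j <- which.max(diag(B))
    ax <- unitv(B[, j])
    ## fix sign from the (tiny) skew part if any, else leave as-is (axis ~ -axis)
    sk <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    if (sum(sk * ax) < 0) ax <- -ax
  }
  list(axis = ax, angle = ang, degenerate = FALSE)
}

## rotation angle in degrees via atan2(sin, cos): well-conditioned at both
## ends of [0, 180], unlike the bare arccos of (trace - 1)/2
rotation_angle_deg <- function(R) {
  s <- 0.5 * sqrt((R[3, 2] - R[2, 3])^2 + (R[1, 3] - R[3, 1])^2 +
                    (R[2, 1] - R[1, 2])^2)
  atan2(s, (sum(diag(R)) - 1) / 2) * DEG
}

## angle (deg) between two unit vectors, atan2 form
vector_angle_deg <- function(u, v) {
  atan2(sqrt(sum(crossp(u, v)^2)), sum(u * v)) * DEG
}

#' Signed angle between two vectors about an axis
#'
#' Angle in (-180, 180] degrees rotating \code{v_from} toward \code{v_to}
#' right-handed about \code{axis}; both vectors are projected onto the plane
#' perpendicular to the axis first.
#'
#' @param axis rotation axis (3-vector).
#' @param v_from,v_to 3-vectors.
#' @return angle in degrees.
#' @export
signed_angle_about <- function(axis, v_from, v_to) {
  a <- unitv(axis)
  p <- v_from - sum(v_from * a) * a
  q <- v_to - sum(v_to * a) * a
  atan2(sum(crossp(p, q) * a), sum(p * q)) * DEG
}

#' Screw-axis decomposition of a rigid transform
#'
#' Every rigid transform with non-degenerate rotation is a rotation about a
#' unique line (the screw axis) plus a slide along it. Points on that line
#' have the minimal displacement magnitude (= |slide|).
#'
#' @param transform a \code{rad_transform}.
#' @param anchor the returned \code{point} is the point on the axis closest
#'   to this anchor (default origin).
#' @param tol rotation angle (degrees) below which the decomposition is
#'   degenerate; the caller must then treat the transform as a pure
#'   translation.
#' @return list(direction, point, angle, slide, degenerate).
#' @export
screw_axis <- function(transform, anchor = c(0, 0, 0), tol = 0.25) {
  aa <- axis_angle(transform)
  if (aa$degenerate || aa$angle < tol)
    return(list(direction = NULL, point = NULL, angle = aa$angle,
                slide = NA_real_, degenerate = TRUE))
  u <- aa$axis
  ## orthonormal basis of the plane perpendicular to u
  seed <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(crossp(u, seed))
  e2 <- crossp(u, e1)
  R <- transform$R
  t <- transform$t
  ## solve (I - R) c = t_perp within the plane
  A <- matrix(c(1 - sum(e1 * R %*% e1), -sum(e1 * R %*% e2),
                -sum(e2 * R %*% e1), 1 - sum(e2 * R %*% e2)),
              2, 2, byrow = TRUE)
  b <- c(sum(e1 * t), sum(e2 * t))
  c2 <- solve(A, b)
  p0 <- c2[1] * e1 + c2[2] * e2
  point <- p0 + sum((anchor - p0) * u) * u
  list(direction = u, point = point, angle = aa$angle,
       slide = sum(t * u), degenerate = FALSE)
}
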