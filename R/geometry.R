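# Small 3-vector helpers. Coordinates are plain numeric length-3 vectors in
# Angstroms throughout; rotations are 3x3 matrices acting on column vectors.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector", call. = FALSE)
  a / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into the interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into `(-180, 180]`; `-180` maps to `+180`.
#' @export
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Signed torsion angle of four points
#'
#' Computes the dihedral about the p2-p3 axis under the IUPAC sign
#' convention: looking from p2 towards p3, a positive angle is a clockwise
#' rotation carrying the p1 side onto the p4 side. Used for all side-chain
#' chi angles (chi1 N-CA-CB-SG, chi2 CA-CB-SG-SG', chi3 CB-SG-SG'-CB').
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates (Angstrom).
#' @return angle in degrees in `(-180, 180]`.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b2) < 1e-9) stop("degenerate geometry: p2 == p3", call. = FALSE)
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("degenerate geometry: colinear bonded triplet", call. = FALSE)
  y <- sum(vcross(n1, n2) * vunit(b2))
  wrap_angle(rad2deg(atan2(y, sum(n1 * n2))))
}

#' Planar angle at p2 formed by p1-p2-p3, in degrees
#' @param p1,p2,p3 numeric length-3 coordinates.
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- vunit(p1 - p2)
  v <- vunit(p3 - p2)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# Place atom D given three predecessors A-B-C and internal coordinates:
# |C-D| = bond, angle(B,C,D) = angle (deg), torsion(A,B,C,D) = tors (deg).
# Standard internal-coordinate (NeRF-style) construction; the sign is fixed
# so that torsion_angle(A, B, C, D) returns `tors`.
place_internal <- function(a, b, c, bond, angle, tors) {
  bc <- vunit(c - b)
  ab <- b - a
  nref <- vcross(ab, bc)
  if (vnorm(nref) < 1e-9)
    stop("degenerate geometry: reference triplet colinear", call. = FALSE)
  n <- vunit(nref)
  m <- vcross(n, bc)
  th <- deg2rad(angle)
  ph <- deg2rad(tors)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Elementary rotation matrices (degrees, right-handed, column-vector acting).
rot_x <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}
rot_y <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}
rot_z <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

#' Rigid transform
#'
#' Bundles a rotation and translation; applied as `R x + t`.
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation, Angstrom.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

apply_transform <- function(tf, xyz) {
  # xyz: length-3 vector or n x 3 matrix
  if (is.matrix(xyz)) {
    sweep(xyz %*% t(tf$R), 2, tf$t, "+")
  } else {
    as.numeric(tf$R %*% xyz + tf$t)
  }
}

# Random rotation from seeded quaternion draws (generator use).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}
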