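# Small 3D vector helpers shared by every geometric rule. All angles are
# unsigned degrees; ring-plane angles are folded into [0, 90].

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

dist3 <- function(a, b) vnorm(a - b)

#' Angle at vertex b of the path a-b-c, in degrees
#' @noRd
angle3 <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

# Angle between two direction vectors, degrees in [0, 180]
vec_angle <- function(u, v) {
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Angle between two planes given by normals, folded into [0, 90]
plane_angle <- function(n1, n2) {
  a <- vec_angle(n1, n2)
  min(a, 180 - a)
}

# Best-fit plane of a point matrix (rows = points): returns centroid, unit
# normal (sign arbitrary) and RMSD of points from the plane.
fit_plane <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  sv <- svd(x)
  normal <- sv$v[, 3]
  rmsd <- sqrt(mean((x %*% normal)^2))
  list(centroid = ctr, normal = unit(normal), rmsd = rmsd)
}

# Lateral offset of point p from the axis through centroid along normal:
# length of the projection of (p - centroid) onto the plane.
plane_offset <- function(p, centroid, normal) {
  d <- p - centroid
  vnorm(d - sum(d * normal) * normal)
}

# Any unit vector perpendicular to v (deterministic choice)
perp_unit <- function(v) {
  v <- unit(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(pracma_cross(ref, v))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotate point set (rows) by angle (degrees) about unit axis through origin
rotate_about <- function(pts, axis, angle_deg) {
  axis <- unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  pts %*% t(R)
}

# All-pairs Euclidean distances between two coordinate matrices (rows = atoms)
cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0
  sqrt(d2)
}
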