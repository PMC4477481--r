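# Internal vector geometry used by the builder, DSSP core and superposition.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Measure a bond angle
#'
#' Angle at `b` formed by points `a`-`b`-`c`, in degrees.
#' @param a,b,c numeric 3-vectors (Angstrom).
#' @return angle in degrees, in `[0, 180]`.
#' @keywords internal
#' @noRd
bond_angle <- function(a, b, c) {
  u <- unit_vec(a - b)
  v <- unit_vec(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Measure a torsion angle
#'
#' Dihedral defined by points p1-p2-p3-p4 with the standard atan2 convention,
#' in degrees in (-180, 180].
#' @keywords internal
#' @noRd
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit_vec(b2))
  ang <- rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang <= -180) ang + 360 else ang
}

# Natural-extension reference frame (NeRF) placement: position atom D given
# placed atoms A, B, C, the bond length |C-D|, the bond angle B-C-D (deg) and
# the torsion A-B-C-D (deg).
place_dihedral <- function(a, b, c, length, angle, torsion) {
  theta <- deg2rad(angle)
  chi <- deg2rad(torsion)
  bc <- unit_vec(c - b)
  n <- unit_vec(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-length * cos(theta),
          length * sin(theta) * cos(chi),
          -length * sin(theta) * sin(chi))
  c + bc * d2[1L] + m * d2[2L] + n * d2[3L]
}

# Proper rotation matrix about an arbitrary axis (Rodrigues), angle in degrees.
rotation_about_axis <- function(axis, angle) {
  u <- unit_vec(axis)
  th <- deg2rad(angle)
  ct <- cos(th)
  st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    ct + ux^2 * (1 - ct),       ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),       uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3L, byrow = TRUE)
}

# Squared Euclidean distance matrix between the rows of two n x 3 matrices.
cross_dist2 <- function(x, y) {
  outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
}

cross_dist <- function(x, y) {
  d2 <- cross_dist2(x, y)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
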