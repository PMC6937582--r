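# Low-level 3D geometry shared by the builders, the dihedral analysis and the
# trajectory fitting. Coordinates are plain numeric length-3 vectors or
# n x 3 matrices, always in Angstrom; angles cross the API in degrees.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion angle defined by four points
#'
#' Returns the dihedral angle about the b--c axis using the IUPAC sign
#' convention (clockwise positive when viewed from b towards c), in degrees
#' in (-180, 180].
#'
#' @param a,b,c,d Numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees, or `NA` if any three consecutive points are
#'   collinear.
#' @export
#' @examples
#' torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0))
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) return(NA_real_)
  m1 <- vcross(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Bond angle a-b-c in degrees.
bond_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  rad2deg(acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v))))))
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three previously placed atoms `a`, `b`, `c`, positions a new atom
#' bonded to `c` at distance `bond`, with bond angle `angle` (b-c-new) and
#' torsion `torsion` (a-b-c-new), both in degrees. This is the natural
#' extension reference frame used by internal-coordinate chain builders.
#'
#' @param a,b,c Numeric length-3 coordinates of the three reference atoms.
#' @param bond Bond length c--new in Angstrom.
#' @param angle Bond angle b-c-new in degrees.
#' @param torsion Torsion a-b-c-new in degrees.
#' @return Length-3 coordinate of the new atom.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  theta <- deg2rad(angle)
  tau <- deg2rad(torsion)
  d2 <- c(-bond * cos(theta),
          bond * sin(theta) * cos(tau),
          bond * sin(theta) * sin(tau))
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- vcross(ab, bc)
  n <- n / vnorm(n)
  m <- cbind(bc, vcross(n, bc), n)
  as.numeric(m %*% d2 + c)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two paired coordinate sets, and reports the RMSD of
#' `mobile` onto `reference` after the fit.
#'
#' @param mobile,reference n x 3 coordinate matrices with matched rows.
#' @param weights Optional per-row non-negative weights (e.g. atomic masses
#'   for a mass-weighted fit). Default: uniform.
#' @return List with `rotation` (3 x 3), `translation` (length 3, applied
#'   after rotation), `rmsd` (unweighted, Angstrom), `rmsd_weighted`, and
#'   `n` (number of paired points). Transform a coordinate matrix `X` with
#'   `X %*% rotation + translation` (row-wise).
#' @export
kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 paired points, got ", n)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    stop("'weights' must be ", n, " non-negative values with positive sum")
  }
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  xm <- sweep(mobile, 2, cm)
  xr <- sweep(reference, 2, cr)
  h <- t(xm * w) %*% xr
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- cr - as.numeric(cm %*% rot)
  fitted <- mobile %*% rot
  fitted <- sweep(fitted, 2, trans, "+")
  dev2 <- rowSums((fitted - reference)^2)
  list(rotation = rot,
       translation = trans,
       rmsd = sqrt(mean(dev2)),
       rmsd_weighted = sqrt(sum(w * dev2)),
       n = n)
}

# Apply a kabsch() transform to an n x 3 matrix.
apply_transform <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% fit$rotation, 2, fit$translation, "+")
}

# Minimal circular distance between angles in degrees, in [0, 180].
circular_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# Cross-set squared distances between an n x 3 and an m x 3 matrix (n x m).
cross_dist2 <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  outer(rowSums(x^2), rep(1, nrow(y))) +
    outer(rep(1, nrow(x)), rowSums(y^2)) - 2 * x %*% t(y)
}
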