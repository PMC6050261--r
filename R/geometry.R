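# Internal 3-D geometry helpers shared by the builder, pose metrics, STD
# prediction and grafting. All angles are in degrees, all lengths in Angstrom.

.xprod <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

#' Signed torsion angle of four points
#'
#' Returns the dihedral a-b-c-d in degrees, in (-180, 180].
#'
#' @param a,b,c,d numeric length-3 coordinate vectors (Angstrom).
#' @return numeric scalar, degrees.
#' @export
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- .xprod(b1, b2)
  n2 <- .xprod(b2, b3)
  m1 <- .xprod(n1, .unit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Rodrigues rotation matrix for a unit axis and angle in degrees.
.rotation_matrix <- function(axis, angle_deg) {
  u <- .unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotate rows of an n x 3 matrix about an axis through `origin`.
.rotate_about <- function(xyz, origin, axis, angle_deg) {
  R <- .rotation_matrix(axis, angle_deg)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
}

# Natural-extension placement: position of atom d bonded to c with bond
# length |cd|, angle b-c-d and dihedral a-b-c-d.
.nerf_place <- function(a, b, c, bond, angle_deg, torsion_deg) {
  bc <- .unit(c - b)
  n <- .unit(.xprod(b - a, bc))
  m <- .xprod(n, bc)
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Kabsch best-fit superposition: returns the rigid map taking `mobile`
# onto `fixed` (both n x 3, matched rows) in least-squares sense.
.kabsch <- function(mobile, fixed) {
  mc <- colMeans(mobile)
  fc <- colMeans(fixed)
  H <- t(sweep(mobile, 2, mc)) %*% sweep(fixed, 2, fc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, mc = mc, fc = fc)
}

.apply_kabsch <- function(xyz, fit) {
  sweep(sweep(xyz, 2, fit$mc) %*% t(fit$R), 2, fit$fc, `+`)
}

# Plain coordinate RMSD over matched rows of two n x 3 matrices.
.rmsd_xyz <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}

# Deterministic "random" rotation matrix drawn from the current RNG stream.
.random_rotation <- function() {
  axis <- stats::rnorm(3)
  .rotation_matrix(axis, stats::runif(1, 0, 360))
}
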