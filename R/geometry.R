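# Internal 3D geometry helpers shared by the descriptor code and the
# synthetic backbone builder.  All coordinates are numeric length-3 vectors
# in Angstroms.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' Returns the torsion angle a-b-c-d in degrees using the IUPAC sign
#' convention, in (-180, 180].  Degenerate (collinear) geometries return
#' `NA` with a warning.
#'
#' @param a,b,c,d numeric length-3 coordinate vectors (Angstrom).
#' @return numeric angle in degrees, or `NA_real_` if undefined.
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    warning("dihedral undefined for (near-)collinear atoms")
    return(NA_real_)
  }
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

bond_angle <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Natural extension of reference frame (NeRF): place atom D given the three
# previous atoms A-B-C, the C-D bond length, the B-C-D angle and the
# A-B-C-D torsion (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(bond * cos(pi - ang),
          bond * cos(tor) * sin(pi - ang),
          -bond * sin(tor) * sin(pi - ang))
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(m %*% d2 + c)
}

# Virtual C-beta position from backbone N, CA, C (standard tetrahedral
# reconstruction; used for Gly and for building fixtures).
virtual_cbeta <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- cross3(b, cc)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

# Deterministic near-uniform points on the unit sphere (golden-section
# spiral), used for the solvent-accessibility quadrature.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Random rigid motion (rotation + translation) for invariance tests.
random_rigid_motion <- function(xyz, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
  shift <- stats::runif(3, -20, 20)
  sweep(xyz %*% t(rot), 2, shift, `+`)
}
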