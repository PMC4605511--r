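# Small 3D geometry kernel: vector helpers, bond/torsion measurement and
# internal-coordinate atom placement. All coordinates are in Angstrom,
# angles in degrees at the interfaces (radians internally).

#' @noRd
vnorm <- function(v) sqrt(sum(v * v))

#' @noRd
vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

#' @noRd
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at b formed by points a-b-c, in degrees
#' @noRd
bond_angle <- function(a, b, c) {
  u <- vunit(a - b); v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Dihedral angle a-b-c-d in degrees, IUPAC sign convention
#' @param a,b,c,d numeric 3-vectors (Angstrom)
#' @return angle in degrees in (-180, 180]
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Positions a new atom `d` at distance `bond` from `c`, with angle
#' b-c-d equal to `angle` and dihedral a-b-c-d equal to `dihedral`.
#'
#' @param a,b,c numeric 3-vectors: the three reference atoms
#' @param bond bond length c-d in Angstrom
#' @param angle bond angle b-c-d in degrees
#' @param dihedral torsion a-b-c-d in degrees
#' @return numeric 3-vector: coordinates of the new atom
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               -bond * sin(ang) * sin(tor))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Deterministic quasi-uniform points on the unit sphere (golden-spiral
# lattice); row i is one unit vector. Determinism given n is relied on by
# the SASA routine.
#' @noRd
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z * z))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}
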