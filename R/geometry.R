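# Small 3-vector helpers. Everything here works in bohr.

.norm3 <- function(v) sqrt(sum(v * v))

.unit3 <- function(v) {
  n <- .norm3(v)
  if (n < 1e-14) abort("zero-length vector", class = "chemion_geometry_error")
  v / n
}

.cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# rotation matrix about unit axis by angle (Rodrigues)
.rotation_matrix <- function(axis, angle) {
  u <- .unit3(axis)
  cth <- cos(angle)
  sth <- sin(angle)
  ux <- matrix(c(
    0, -u[3], u[2],
    u[3], 0, -u[1],
    -u[2], u[1], 0
  ), 3, 3, byrow = TRUE)
  diag(3) * cth + sth * ux + (1 - cth) * (u %o% u)
}

# signed dihedral p1-p2-p3-p4, reduced to [0, 2*pi)
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .unit3(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x)
  ang %% (2 * pi)
}

# canonical tetrahedral directions (unit), listed in a fixed order
.tetra_dirs <- function() {
  rbind(
    c(1, 1, 1),
    c(1, -1, -1),
    c(-1, 1, -1),
    c(-1, -1, 1)
  ) / sqrt(3)
}

# the two remaining tetrahedral directions at a centre whose two known
# neighbour directions are the unit vectors u1, u2 (assumed at acos(-1/3))
.tetra_complete2 <- function(u1, u2) {
  t <- .unit3(.cross3(u1, u2))
  base <- -(u1 + u2) / 2
  s <- sqrt(max(0, 1 - sum(base * base)))
  list(base + s * t, base - s * t)
}

# place a point D with |D - C| = bond, angle(B, C, D) = angle and
# dihedral(A, B, C, D) = dihedral (standard internal-coordinate placement)
.place_internal <- function(A, B, C, bond, angle, dihedral) {
  bc <- .unit3(C - B)
  ab <- B - A
  n <- .unit3(.cross3(ab, bc))
  m <- .cross3(n, bc)
  d2 <- c(
    -bond * cos(angle),
    bond * sin(angle) * cos(dihedral),
    bond * sin(angle) * sin(dihedral)
  )
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}
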