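# Vectorized geometry kernels: angles, dihedrals and their Cartesian
# derivatives. All functions operate row-wise on n x 3 matrices so the energy
# code can evaluate whole interaction lists at once.

row_dot <- function(a, b) a[, 1] * b[, 1] + a[, 2] * b[, 2] + a[, 3] * b[, 3]

row_norm <- function(a) sqrt(row_dot(a, a))

row_cross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

# theta between u and v (both pointing away from the vertex), with
# d(theta)/du and d(theta)/dv. Near-linear arrangements are clamped so the
# derivative stays finite.
angle_kernel <- function(u, v) {
  nu <- row_norm(u)
  nv <- row_norm(v)
  ct <- row_dot(u, v) / (nu * nv)
  ct <- pmin(1 - 1e-12, pmax(-1 + 1e-12, ct))
  st <- sqrt(1 - ct^2)
  st <- pmax(st, 1e-8)
  theta <- acos(ct)
  # d(cos theta)/du = v/(|u||v|) - cos(theta) u/|u|^2
  dcu <- v / (nu * nv) - ct * u / nu^2
  dcv <- u / (nu * nv) - ct * v / nv^2
  list(
    theta = theta,
    dtheta_du = -dcu / st,
    dtheta_dv = -dcv / st
  )
}

# Signed dihedral from three consecutive bond vectors b1 = rj - ri,
# b2 = rk - rj, b3 = rl - rk, plus derivatives with respect to the four
# atomic positions.
dihedral_kernel <- function(b1, b2, b3) {
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  nb2 <- row_norm(b2)
  m1 <- row_cross(n1, b2 / nb2)
  x <- row_dot(n1, n2)
  y <- row_dot(m1, n2)
  omega <- atan2(y, x)

  n1sq <- pmax(row_dot(n1, n1), 1e-16)
  n2sq <- pmax(row_dot(n2, n2), 1e-16)
  dwi <- (nb2 / n1sq) * n1
  dwl <- -(nb2 / n2sq) * n2
  c1 <- row_dot(b1, b2) / nb2^2
  c3 <- row_dot(b3, b2) / nb2^2
  dwj <- -(1 + c1) * dwi + c3 * dwl
  dwk <- c1 * dwi - (1 + c3) * dwl
  list(omega = omega, d_i = dwi, d_j = dwj, d_k = dwk, d_l = dwl)
}

# Rodrigues rotation of points (n x 3) about a unit axis through the origin.
rotate_about_axis <- function(points, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  ct <- cos(angle)
  st <- sin(angle)
  K <- matrix(c(
    0, -axis[3], axis[2],
    axis[3], 0, -axis[1],
    -axis[2], axis[1], 0
  ), 3, 3, byrow = TRUE)
  R <- diag(3) + st * K + (1 - ct) * (K %*% K)
  points %*% t(R)
}

#' Measure an internal coordinate of a structure
#'
#' Computes a bond length (Angstrom), valence angle or torsion angle
#' (degrees) from atomic indices.
#'
#' @param s A [reax_structure].
#' @param indices Integer vector of 2 (bond), 3 (angle) or 4 (torsion)
#'   atom indices.
#' @return Numeric scalar: Angstrom for bonds, degrees for angles/torsions.
#' @export
#' @examples
#' w <- water_molecule()
#' measure_coordinate(w, c(1, 2))    # O-H bond length
#' measure_coordinate(w, c(2, 1, 3)) # H-O-H angle
measure_coordinate <- function(s, indices) {
  x <- s$coords
  if (length(indices) == 2L) {
    return(sqrt(sum((x[indices[1], ] - x[indices[2], ])^2)))
  }
  if (length(indices) == 3L) {
    u <- rbind(x[indices[1], ] - x[indices[2], ])
    v <- rbind(x[indices[3], ] - x[indices[2], ])
    return(angle_kernel(u, v)$theta * RAD2DEG)
  }
  if (length(indices) == 4L) {
    b1 <- rbind(x[indices[2], ] - x[indices[1], ])
    b2 <- rbind(x[indices[3], ] - x[indices[2], ])
    b3 <- rbind(x[indices[4], ] - x[indices[3], ])
    return(dihedral_kernel(b1, b2, b3)$omega * RAD2DEG)
  }
  stop("`indices` must have length 2, 3 or 4", call. = FALSE)
}
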