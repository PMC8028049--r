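# Internal-coordinate scan generation: rigid displacement of a molecular
# fragment along a bond, about an angle/torsion axis, or of an intact water
# molecule along the cluster-atom -> oxygen axis.

# Covalent radii (Angstrom) for the connectivity heuristic used to pick the
# default moving fragment.
COV_RADII <- c(H = 0.31, O = 0.66, Fe = 1.32, S = 1.05)

# Adjacency from a simple covalent-distance criterion (isolated structures).
connectivity <- function(s, scale = 1.25, slack = 0.3) {
  n <- n_atoms(s)
  rad <- COV_RADII[s$symbols]
  adj <- vector("list", n)
  if (n == 1) {
    return(adj)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rc <- scale * (rad[i] + rad[j]) + slack
      if (sqrt(sum((s$coords[i, ] - s$coords[j, ])^2)) <= rc) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  adj
}

# connected component containing `from` with edges to `banned` removed
fragment_from <- function(adj, from, banned) {
  seen <- c(from)
  queue <- from
  while (length(queue) > 0) {
    a <- queue[1]
    queue <- queue[-1]
    for (nb in adj[[a]]) {
      if (nb %in% banned || nb %in% seen) next
      seen <- c(seen, nb)
      queue <- c(queue, nb)
    }
  }
  sort(seen)
}

#' Specify an internal-coordinate scan
#'
#' @param coordinate One of `"bond"`, `"angle"`, `"torsion"`,
#'   `"cluster_water_distance"`.
#' @param indices Atom indices defining the coordinate: 2 for bonds and
#'   cluster-water distances (cluster atom, water oxygen), 3 for angles, 4
#'   for torsions.
#' @param increment Step size: Angstrom for distances, degrees for angles
#'   and torsions (`> 0`).
#' @param range Length-2 displacement range relative to the equilibrium
#'   value (same units as `increment`); offsets are
#'   `seq(range[1], range[2], by = increment)` with the zero offset dropped.
#' @param moving_set Optional integer vector of atoms displaced rigidly; by
#'   default the connected fragment on the far side of the scanned
#'   coordinate.
#' @return A list of class `reax_scanspec`.
#' @export
scan_spec <- function(coordinate, indices, increment, range,
                      moving_set = NULL) {
  coordinate <- match.arg(
    coordinate,
    c("bond", "angle", "torsion", "cluster_water_distance")
  )
  if (increment <= 0) stop("`increment` must be positive", call. = FALSE)
  if (length(range) != 2 || range[1] >= range[2]) {
    stop("`range` must be (min, max) with min < max", call. = FALSE)
  }
  need <- switch(coordinate,
    bond = 2L, cluster_water_distance = 2L, angle = 3L, torsion = 4L
  )
  if (length(indices) != need) {
    stop("`", coordinate, "` scans need ", need, " atom indices", call. = FALSE)
  }
  structure(
    list(
      coordinate = coordinate, indices = as.integer(indices),
      increment = increment, range = range, moving_set = moving_set
    ),
    class = "reax_scanspec"
  )
}

scan_offsets <- function(spec) {
  off <- seq(spec$range[1], spec$range[2], by = spec$increment)
  off[abs(off) > 1e-12]
}

default_moving_set <- function(s, spec) {
  adj <- connectivity(s)
  idx <- spec$indices
  switch(spec$coordinate,
    bond = fragment_from(adj, idx[2], banned = idx[1]),
    angle = fragment_from(adj, idx[3], banned = idx[2]),
    torsion = fragment_from(adj, idx[4], banned = idx[3]),
    cluster_water_distance = {
      o <- idx[2]
      hs <- adj[[o]][s$symbols[adj[[o]]] == "H"]
      sort(c(o, hs))
    }
  )
}

#' Generate nonequilibrium structures by scanning one internal coordinate
#'
#' Each output differs from the equilibrium only in the scanned coordinate,
#' displaced by `k * increment` for every nonzero offset in the range. The
#' moving set is displaced rigidly: along the bond axis for bonds, by
#' rotation about the normal through the pivot for angles, about the central
#' bond for torsions, and as an intact rigid water along the cluster-atom ->
#' oxygen axis for cluster-water distances.
#'
#' @param equilibrium Equilibrium [reax_structure].
#' @param spec A [scan_spec()].
#' @return List of displaced [reax_structure]s (attribute `offsets` records
#'   the applied displacements).
#' @export
generate_scan <- function(equilibrium, spec) {
  s <- equilibrium
  idx <- spec$indices
  mov <- spec$moving_set
  if (is.null(mov)) mov <- default_moving_set(s, spec)
  pivots <- switch(spec$coordinate,
    bond = idx[1],
    angle = idx[1:2],
    torsion = idx[1:3],
    cluster_water_distance = idx[1]
  )
  if (any(pivots %in% mov)) {
    stop("moving set must not contain pivot atoms", call. = FALSE)
  }
  offs <- scan_offsets(spec)
  x <- s$coords
  out <- vector("list", length(offs))

  for (kk in seq_along(offs)) {
    off <- offs[kk]
    xs <- x
    if (spec$coordinate %in% c("bond", "cluster_water_distance")) {
      axis <- x[idx[2], ] - x[idx[1], ]
      axis <- axis / sqrt(sum(axis^2))
      xs[mov, ] <- xs[mov, , drop = FALSE] +
        matrix(axis * off, length(mov), 3, byrow = TRUE)
    } else if (spec$coordinate == "angle") {
      u <- x[idx[1], ] - x[idx[2], ]
      v <- x[idx[3], ] - x[idx[2], ]
      axis <- c(
        u[2] * v[3] - u[3] * v[2],
        u[3] * v[1] - u[1] * v[3],
        u[1] * v[2] - u[2] * v[1]
      )
      if (sqrt(sum(axis^2)) < 1e-8) {
        stop("collinear atoms: angle rotation axis is undefined", call. = FALSE)
      }
      # positive offset opens the angle i-j-k
      shifted <- sweep(xs[mov, , drop = FALSE], 2, x[idx[2], ])
      xs[mov, ] <- sweep(
        rotate_about_axis(shifted, axis, off * DEG2RAD), 2,
        -x[idx[2], ]
      )
    } else { # torsion
      axis <- x[idx[3], ] - x[idx[2], ]
      if (sqrt(sum(axis^2)) < 1e-8) {
        stop("coincident torsion pivot atoms", call. = FALSE)
      }
      shifted <- sweep(xs[mov, , drop = FALSE], 2, x[idx[3], ])
      xs[mov, ] <- sweep(
        rotate_about_axis(shifted, axis, -off * DEG2RAD), 2,
        -x[idx[3], ]
      )
    }
    sn <- s
    sn$coords <- xs
    sn$charges <- NULL
    sn$comment <- sprintf("%s scan offset %+.4f", spec$coordinate, off)
    out[[kk]] <- sn
  }
  attr(out, "offsets") <- offs
  out
}
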