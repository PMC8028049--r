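# Pair-list construction. Isolated systems use a plain O(N^2) scan; periodic
# (orthorhombic) systems enumerate explicit lattice images within the cutoff
# sphere, which remains correct when a cell edge is shorter than twice the
# cutoff (the solvated-cluster boxes of interest are in that regime).

#' Build nonbonded and bonded-candidate pair lists
#'
#' Collects all atom pairs within the nonbonded (taper) cutoff and flags the
#' subset within the bond-order cutoff radius as bonded candidates. Periodic
#' systems include every lattice image within the cutoff, so the same atom
#' pair may appear once per relevant image; each unordered pair/image is
#' represented once.
#'
#' @param s A [reax_structure].
#' @param ff A [reax_forcefield]; the nonbonded cutoff is the taper radius
#'   (general parameter `swb`).
#' @param bond_cutoff Bonded-candidate cutoff radius, Angstrom.
#' @return A list of class `reax_neighborlist` with integer vectors `i`, `j`,
#'   displacement matrix `d` (rows `x_j - x_i + shift`), distances `r`, and a
#'   logical `bonded` marking pairs within `bond_cutoff`.
#' @export
build_neighbor_list <- function(s, ff, bond_cutoff = 5.0) {
  validate_structure(s)
  r_cut <- ff$general[["swb"]]
  x <- s$coords
  n <- nrow(x)

  if (is.null(s$cell)) {
    if (n == 1L) {
      pi_ <- integer(0)
      pj <- integer(0)
      d <- matrix(0, 0, 3)
    } else {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      pi_ <- idx[, 1]
      pj <- idx[, 2]
      d <- x[pj, , drop = FALSE] - x[pi_, , drop = FALSE]
    }
  } else {
    L <- s$cell
    m <- ceiling(r_cut / L)
    shifts <- as.matrix(expand.grid(
      sx = -m[1]:m[1], sy = -m[2]:m[2], sz = -m[3]:m[3]
    ))
    # keep the zero shift and one representative of each +/- shift pair
    keep <- (shifts[, 1] > 0) |
      (shifts[, 1] == 0 & shifts[, 2] > 0) |
      (shifts[, 1] == 0 & shifts[, 2] == 0 & shifts[, 3] >= 0)
    shifts <- shifts[keep, , drop = FALSE]
    pi_list <- list()
    pj_list <- list()
    d_list <- list()
    all_i <- rep(seq_len(n), times = n)
    all_j <- rep(seq_len(n), each = n)
    ut <- all_i < all_j
    for (k in seq_len(nrow(shifts))) {
      sh <- shifts[k, ] * L
      zero_shift <- all(shifts[k, ] == 0)
      ii <- if (zero_shift) all_i[ut] else all_i
      jj <- if (zero_shift) all_j[ut] else all_j
      dd <- x[jj, , drop = FALSE] - x[ii, , drop = FALSE]
      dd[, 1] <- dd[, 1] + sh[1]
      dd[, 2] <- dd[, 2] + sh[2]
      dd[, 3] <- dd[, 3] + sh[3]
      rr <- sqrt(rowSums(dd^2))
      keep_p <- rr <= r_cut & !(ii == jj & zero_shift)
      pi_list[[k]] <- ii[keep_p]
      pj_list[[k]] <- jj[keep_p]
      d_list[[k]] <- dd[keep_p, , drop = FALSE]
    }
    pi_ <- unlist(pi_list)
    pj <- unlist(pj_list)
    d <- do.call(rbind, d_list)
  }

  r <- if (length(pi_) > 0) sqrt(rowSums(d^2)) else numeric(0)
  if (is.null(s$cell)) {
    keep <- r <= r_cut
    pi_ <- pi_[keep]
    pj <- pj[keep]
    d <- d[keep, , drop = FALSE]
    r <- r[keep]
  }
  if (any(r < 1e-6)) {
    bad <- which(r < 1e-6)[1]
    stop("overlapping atoms ", pi_[bad], " and ", pj[bad],
      " (r < 1e-6 Angstrom)",
      call. = FALSE
    )
  }
  structure(
    list(
      i = pi_, j = pj, d = d, r = r,
      bonded = r <= bond_cutoff,
      r_cut = r_cut, bond_cutoff = bond_cutoff
    ),
    class = "reax_neighborlist"
  )
}

#' @export
print.reax_neighborlist <- function(x, ...) {
  cat(
    "<reax_neighborlist> ", length(x$i), " pairs within ", x$r_cut,
    " A (", sum(x$bonded), " bonded candidates within ", x$bond_cutoff,
    " A)\n",
    sep = ""
  )
  invisible(x)
}
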