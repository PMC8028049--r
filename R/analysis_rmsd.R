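# Permutation-inversion RMSD: minimum RMSD over rigid translation, proper
# rotation, permutations within element classes, and overall inversion.
# Alternates optimal assignment (Hungarian, on squared distances within each
# element class) with optimal rotation (Kabsch) until a fixed point, from
# multiple deterministic initial orientations and both parities.

kabsch_rotation <- function(P, Q) {
  # rotation R minimizing || P %*% t(R) - Q ||; proper rotation enforced
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  sv$v %*% D %*% t(sv$u)
}

center_coords <- function(x) sweep(x, 2, colMeans(x))

rmsd_of <- function(P, Q) sqrt(mean(rowSums((P - Q)^2)))

best_assignment <- function(P, Q, classes) {
  # per element class, columns of Q assigned to rows of P minimizing total
  # squared distance
  perm <- integer(nrow(P))
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    if (length(idx) == 1) {
      perm[idx] <- idx
      next
    }
    cost <- outer(seq_along(idx), seq_along(idx), Vectorize(function(a, b) {
      sum((P[idx[a], ] - Q[idx[b], ])^2)
    }))
    asg <- hungarian_solve(cost)
    perm[idx] <- idx[asg]
  }
  perm
}

# deterministic set of rotations: identity plus a fixed pseudo-random batch
orientation_set <- function(n_extra = 30) {
  rots <- list(diag(3))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(20201202)
  for (k in seq_len(n_extra)) {
    # random rotation via QR of a Gaussian matrix
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    rots[[k + 1]] <- R
  }
  rots
}

#' Minimum RMSD over translation, rotation, permutation and inversion
#'
#' @param a,b [reax_structure]s with identical element multisets.
#' @param n_orientations Number of initial orientations tried per parity.
#' @return Minimum RMSD (Angstrom). Attributes `permutation` (mapping of
#'   `b`'s atoms onto `a`'s) and `inverted` report the optimal match.
#' @export
#' @examples
#' w <- water_molecule()
#' aligned_rmsd(w, w) # 0
aligned_rmsd <- function(a, b, n_orientations = 30) {
  if (!identical(sort(a$symbols), sort(b$symbols))) {
    stop("structures have different element multisets", call. = FALSE)
  }
  # group-preserving relabel: match element lists positionally
  bsym <- b$symbols
  map <- integer(length(bsym))
  used <- rep(FALSE, length(bsym))
  for (k in seq_along(a$symbols)) {
    cand <- which(bsym == a$symbols[k] & !used)
    map[k] <- cand[1]
    used[cand[1]] <- TRUE
  }
  P <- center_coords(a$coords)
  Q0 <- center_coords(b$coords[map, , drop = FALSE])
  classes <- a$symbols

  best <- Inf
  best_perm <- seq_len(nrow(P))
  best_inv <- FALSE
  rots <- orientation_set(n_orientations)
  for (parity in c(1, -1)) {
    Qp <- parity * Q0
    for (R0 in rots) {
      Q <- Qp %*% t(R0)
      prev_perm <- NULL
      for (iter in 1:60) {
        perm <- best_assignment(P, Q, classes)
        Rk <- kabsch_rotation(Q[perm, , drop = FALSE], P)
        Q <- Q %*% t(Rk)
        if (!is.null(prev_perm) && identical(perm, prev_perm)) break
        prev_perm <- perm
      }
      val <- rmsd_of(P, Q[perm, , drop = FALSE])
      if (val < best) {
        best <- val
        best_perm <- map[perm]
        best_inv <- parity < 0
      }
    }
  }
  structure(best, permutation = best_perm, inverted = best_inv)
}
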