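# Independent oracles used by the unit and acceptance tests. These
# deliberately re-derive results from first principles (exhaustive
# enumeration, brute-force loops) rather than calling the implementation
# paths they check.

brute_force_rmsd <- function(a, b) {
  # exhaustive minimum over permutations within element classes and both
  # parities, Kabsch rotation per candidate
  P <- a$coords
  P <- sweep(P, 2, colMeans(P))
  Q0 <- b$coords
  Q0 <- sweep(Q0, 2, colMeans(Q0))
  classes <- unique(a$symbols)
  perms_of <- function(v) {
    if (length(v) == 1) {
      return(list(v))
    }
    out <- list()
    for (k in seq_along(v)) {
      for (rest in perms_of(v[-k])) out[[length(out) + 1]] <- c(v[k], rest)
    }
    out
  }
  slot_lists <- lapply(classes, function(cl) which(a$symbols == cl))
  cand_lists <- lapply(classes, function(cl) perms_of(which(b$symbols == cl)))
  combine <- function(k, acc) {
    if (k > length(classes)) {
      return(list(acc))
    }
    out <- list()
    for (p in cand_lists[[k]]) {
      acc2 <- acc
      acc2[slot_lists[[k]]] <- p
      out <- c(out, combine(k + 1, acc2))
    }
    out
  }
  all_perms <- combine(1, integer(n_atoms(a)))
  kabsch <- function(P, Q) {
    # rotation matrix minimizing ||Q R^T - P||, proper rotation enforced
    H <- t(Q) %*% P
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  best <- Inf
  for (parity in c(1, -1)) {
    for (pp in all_perms) {
      Q <- parity * Q0[pp, , drop = FALSE]
      R <- kabsch(P, Q)
      val <- sqrt(mean(rowSums((Q %*% t(R) - P)^2)))
      best <- min(best, val)
    }
  }
  best
}

brute_force_hbonds <- function(frame, cluster, dmax = 3.7, amax = 20,
                               h_max_bond = 1.3) {
  x <- frame$coords
  cell <- frame$cell
  mi <- function(v) {
    if (!is.null(cell)) v <- v - cell * round(v / cell)
    v
  }
  hs <- which(frame$symbols == "H")
  da <- which(frame$symbols %in% c("O", "S"))
  in_cl <- rep(FALSE, n_atoms(frame))
  in_cl[cluster] <- TRUE
  count <- 0L
  for (h in hs) {
    best <- Inf
    don <- NA
    for (d in da) {
      r <- sqrt(sum(mi(x[d, ] - x[h, ])^2))
      if (r < best) {
        best <- r
        don <- d
      }
    }
    if (best > h_max_bond) next
    for (acc in da) {
      if (acc == don) next
      v_da <- mi(x[acc, ] - x[don, ])
      if (sqrt(sum(v_da^2)) > dmax) next
      if (length(cluster) > 0 && in_cl[don] == in_cl[acc]) next
      v_dh <- mi(x[h, ] - x[don, ])
      cosang <- sum(v_dh * v_da) / sqrt(sum(v_dh^2) * sum(v_da^2))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (ang <= amax) count <- count + 1L
    }
  }
  count
}
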