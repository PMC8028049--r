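# O(n^3) Hungarian algorithm (potentials + shortest augmenting paths) for
# the optimal-assignment step of the permutational alignment.

# a: square cost matrix; returns integer vector ans with ans[row] = column.
hungarian_solve <- function(a) {
  n <- nrow(a)
  if (n == 0L) {
    return(integer(0))
  }
  if (n == 1L) {
    return(1L)
  }
  u <- numeric(n) # row potentials
  v <- numeric(n + 1) # column potentials; index 1 is the virtual column
  p <- integer(n + 1) # p[j]: row currently assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free_j <- which(!used)
      cur <- a[i0, free_j - 1L] - u[i0] - v[free_j]
      upd <- which(cur < minv[free_j])
      minv[free_j[upd]] <- cur[upd]
      way[free_j[upd]] <- j0
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      u[p[used]] <- u[p[used]] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2:(n + 1)) ans[p[j]] <- j - 1L
  ans
}
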