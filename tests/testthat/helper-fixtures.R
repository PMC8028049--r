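# Shared fixtures: small force fields and reference geometries built in code.

ff_ho <- make_toy_forcefield(c("H", "O"))
ff_full <- make_toy_forcefield()

water_dimer <- function(offset = c(-2.9, 0.4, 0.2)) {
  w <- water_molecule()
  reax_structure(
    rep(c("O", "H", "H"), 2),
    rbind(w$coords, sweep(w$coords, 2, -offset))
  )
}

random_mixed_structure <- function(seed, n = 6, spread = 4) {
  set.seed(seed)
  syms <- sample(c("H", "O", "S", "Fe"), n, replace = TRUE, prob = c(4, 3, 2, 1))
  repeat {
    x <- matrix(stats::runif(3 * n, 0, spread), ncol = 3)
    if (min(stats::dist(x)) > 0.8) break
  }
  reax_structure(syms, x)
}

random_rotation <- function(seed) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# random box of n water molecules (no solute), isolated or periodic
random_water_frame <- function(seed, n_waters = 20, cell = c(12, 12, 12),
                               periodic = TRUE) {
  bx <- build_solvated_box(box_spec(cell, n_waters,
    solute = NULL,
    min_separation = 2.2, seed = seed
  ))
  if (!periodic) bx$cell <- NULL
  bx
}
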