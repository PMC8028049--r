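test_that("aligned RMSD is zero on transformed self-copies", {
  set.seed(5)
  a <- random_mixed_structure(5, n = 6)
  expect_equal(as.numeric(aligned_rmsd(a, a)), 0, tolerance = 1e-10)
  R <- random_rotation(6)
  perm <- c(2, 1, 3, 5, 4, 6)
  # only permute within element classes
  cl <- a$symbols
  perm <- seq_len(6)
  for (el in unique(cl)) {
    idx <- which(cl == el)
    if (length(idx) > 1) perm[idx] <- idx[c(2:length(idx), 1)]
  }
  b <- a
  b$symbols <- a$symbols[perm]
  b$coords <- -(a$coords[perm, ] %*% R) + matrix(c(1, -2, 0.5), 6, 3, byrow = TRUE)
  expect_equal(as.numeric(aligned_rmsd(a, b)), 0, tolerance = 1e-8)
})

test_that("aligned RMSD matches the exhaustive-permutation oracle", {
  for (seed in c(11, 12, 13)) {
    a <- random_mixed_structure(seed, n = 6)
    set.seed(seed + 100)
    b <- a
    b$coords <- a$coords + matrix(rnorm(18, sd = 0.25), 6, 3)
    b$coords <- b$coords %*% t(random_rotation(seed + 200))
    got <- as.numeric(aligned_rmsd(a, b))
    want <- brute_force_rmsd(a, b)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("aligned RMSD is symmetric and rejects mismatched compositions", {
  a <- random_mixed_structure(21, n = 5)
  b <- a
  set.seed(22)
  b$coords <- a$coords + matrix(rnorm(15, sd = 0.3), 5, 3)
  expect_equal(as.numeric(aligned_rmsd(a, b)), as.numeric(aligned_rmsd(b, a)),
    tolerance = 1e-8
  )
  wrong <- water_molecule()
  expect_error(aligned_rmsd(a, wrong), "multiset")
})

test_that("hydrogen-bond counting matches constructed cases", {
  lin <- reax_structure(
    c("O", "H", "O"),
    rbind(c(0, 0, 0), c(0.96, 0.03, 0), c(2.9, 0.2, 0))
  )
  expect_identical(count_hbonds(lin), 1L)
  far <- lin
  far$coords[3, 1] <- 4.0
  expect_identical(count_hbonds(far), 0L)
  bent <- lin
  bent$coords[3, ] <- c(2.0, 2.3, 0) # large deviation angle
  expect_identical(count_hbonds(bent), 0L)
  # empty selection warns and returns zero
  expect_warning(
    out <- count_hbonds(reax_structure("Fe", rbind(c(0, 0, 0)))),
    "empty"
  )
  expect_identical(out, 0L)
})

test_that("hydrogen-bond counter matches the brute-force triple loop", {
  for (seed in c(31, 32)) {
    fr <- random_water_frame(seed, n_waters = 20)
    expect_identical(
      count_hbonds(fr),
      brute_force_hbonds(fr, integer(0))
    )
    # with a cluster restriction (first water as the "cluster")
    expect_identical(
      count_hbonds(fr, cluster = 1:3),
      brute_force_hbonds(fr, 1:3)
    )
  }
})

test_that("hydrogen-bond counting is invariant under rigid motion", {
  fr <- random_water_frame(33, n_waters = 12, periodic = FALSE)
  n0 <- count_hbonds(fr)
  fr2 <- fr
  fr2$coords <- fr$coords %*% t(random_rotation(34)) +
    matrix(c(5, -3, 2), n_atoms(fr), 3, byrow = TRUE)
  expect_identical(count_hbonds(fr2), n0)
})

test_that("trajectory statistics reproduce hand-computed values", {
  s <- fe2s2_cluster(0)
  x1 <- s$coords
  x2 <- x1
  x2[4, 3] <- x2[4, 3] + 0.5
  fr <- function(t, x) {
    list(
      time = t, positions = x, velocities = x * 0, temperature = 300,
      energy = NULL
    )
  }
  traj <- reax_trajectory(s$symbols, list(fr(0, x1), fr(10, x2)))
  # frozen trajectory: SD zero
  frozen <- reax_trajectory(s$symbols, list(fr(0, x1), fr(10, x1)))
  stf <- trajectory_statistics(frozen, distances = list(FeFe = list(c(1, 2))))
  expect_equal(stf$mean, measure_coordinate(s, c(1, 2)))
  expect_identical(stf$sd, 0)
  # two-frame dihedral 0 and 10 degrees -> mean 5, population SD 5
  d1 <- abs(measure_coordinate(reax_structure(s$symbols, x1), c(1, 3, 2, 4)))
  expect_equal(d1, 0, tolerance = 1e-8) # planar ring
  st <- trajectory_statistics(traj, dihedrals = list(theta = c(1, 3, 2, 4)))
  d2 <- abs(measure_coordinate(reax_structure(s$symbols, x2), c(1, 3, 2, 4)))
  expect_equal(st$mean, (d1 + d2) / 2, tolerance = 1e-10)
  expect_equal(st$sd, (d2 - d1) / 2, tolerance = 1e-10)
  # windows and bad indices are validated
  expect_error(trajectory_statistics(traj, window = c(100, 200)), "empty")
  expect_error(
    trajectory_statistics(traj, distances = list(x = list(c(1, 99)))),
    "out of range"
  )
})

test_that("deviation reports count symmetry-unique coordinates once", {
  w <- water_molecule()
  ident <- geometry_deviation_report(list(w = w), list(w = w))
  expect_true(all(ident$coords$deviation == 0))
  # the two equivalent O-H bonds appear as a single unique bond
  expect_identical(sum(ident$coords$type == "bond"), 1L)
  # stretch one bond by 0.1: bond deviation 0.1, angle/torsion untouched
  b <- w
  dirv <- (b$coords[2, ] - b$coords[1, ])
  b$coords[2, ] <- b$coords[1, ] + dirv * (1 + 0.1 / sqrt(sum(dirv^2)))
  rep2 <- geometry_deviation_report(list(w = b), list(w = w))
  bond_dev <- rep2$aggregate[rep2$aggregate$type == "bond", ]
  ang_dev <- rep2$aggregate[rep2$aggregate$type == "angle", ]
  expect_equal(bond_dev$mean, 0.1, tolerance = 1e-6)
  expect_equal(ang_dev$mean, 0, tolerance = 1e-8)
  expect_error(
    geometry_deviation_report(list(w = w), list(v = w)),
    "cluster names"
  )
})

test_that("correlation reports recover known linear relations", {
  ts <- make_synthetic_trainset(
    ff_ho, list(water = water_molecule()),
    list(water = list(scan_spec("bond", c(1, 2), 0.1, c(-0.2, 0.4))))
  )
  rep1 <- prediction_correlation_report(ts, ff_ho)
  expect_equal(rep1$summary$slope, 1, tolerance = 1e-8)
  expect_equal(rep1$summary$r_squared, 1, tolerance = 1e-8)
  expect_equal(rep1$summary$rmse, 0, tolerance = 1e-8)
  # references scaled by 2 -> predicted = 0.5 * reference
  ts2 <- ts
  ts2$entries$reference <- ts2$entries$reference * 2
  rep2 <- prediction_correlation_report(ts2, ff_ho)
  expect_equal(rep2$summary$slope, 0.5, tolerance = 1e-8)
  # single entry: slope reported absent, pair still listed
  ts3 <- ts
  ts3$entries <- ts3$entries[1, ]
  rep3 <- prediction_correlation_report(ts3, ff_ho)
  expect_identical(nrow(rep3$pairs), 1L)
  expect_true(is.na(rep3$summary$slope))
})

test_that("charge reports flag agreement and disagreement correctly", {
  w <- water_molecule()
  qe <- equilibrate_charges(w, ff_ho)
  rep1 <- charge_report(list(w = w), ff_ho, list(w = qe))
  expect_true(all(abs(rep1$atoms$error) < 1e-12))
  # neutral homonuclear diatomic: EEM gives zero, error equals |reference|
  o2 <- reax_structure(c("O", "O"), rbind(c(0, 0, 0), c(0, 0, 1.21)))
  rep2 <- charge_report(list(o2 = o2), ff_ho, list(o2 = c(0.3, -0.3)))
  expect_equal(abs(rep2$atoms$error), c(0.3, 0.3), tolerance = 1e-10)
  expect_error(
    charge_report(list(w = w), ff_ho, list(w = c(0, 0))),
    "mismatch"
  )
})

test_that("coordination states classify Fe sites by water-oxygen count", {
  s <- fe2s2_cluster(4)
  fr <- list(
    time = 0, positions = s$coords, velocities = s$coords * 0,
    temperature = 300, energy = NULL
  )
  fr2 <- fr
  fr2$time <- 1
  traj <- reax_trajectory(s$symbols, list(fr, fr2))
  cs <- coordination_states(traj, fe_indices = c(1, 2), cutoff = 2.8)
  expect_identical(nrow(cs), 4L)
  expect_true(all(cs$n_coordinated == 2))
  expect_true(all(cs$state == "undercoordinated"))
})
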