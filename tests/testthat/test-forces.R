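test_that("analytic forces match central-difference gradients", {
  suppressWarnings({
    for (s in list(
      water_molecule(), water_dimer(),
      reax_structure(
        c("H", "S", "S", "H"),
        rbind(
          c(0.2, 0.9, 0.3), c(0, 0, 1.34),
          c(2.06, 0, 1.2), c(2.4, 1.1, 1.9)
        )
      )
    )) {
      fa <- compute_forces(s, ff_full, "analytic")
      fn <- compute_forces(s, ff_full, "numerical")
      expect_lt(max(abs(fa - fn)), 1e-4)
    }
  })
})

test_that("diatomic forces are equal and opposite along the bond axis", {
  s <- reax_structure(c("O", "O"), rbind(c(0, 0, 0), c(0, 0, 1.25)))
  f <- compute_forces(s, ff_ho, "analytic")
  expect_equal(f[1, ], -f[2, ], tolerance = 1e-10)
  expect_lt(max(abs(f[, 1:2])), 1e-10) # force purely axial
})

test_that("net force and net torque vanish for isolated clusters", {
  suppressWarnings({
    s <- fe2s2_cluster(4)
    f <- compute_forces(s, ff_full, "analytic")
  })
  expect_lt(max(abs(colSums(f))), 1e-6)
  torque <- colSums(cbind(
    s$coords[, 2] * f[, 3] - s$coords[, 3] * f[, 2],
    s$coords[, 3] * f[, 1] - s$coords[, 1] * f[, 3],
    s$coords[, 1] * f[, 2] - s$coords[, 2] * f[, 1]
  ))
  expect_lt(max(abs(torque)), 1e-6)
})

test_that("forces stay consistent under periodic boundary conditions", {
  suppressWarnings({
    bx <- build_solvated_box(
      box_spec(c(8.5, 8.5, 8.5), 5, solute = fe2s2_cluster(0), seed = 3)
    )
    fa <- compute_forces(bx, ff_full, "analytic")
    fn <- compute_forces(bx, ff_full, "numerical")
  })
  expect_lt(max(abs(fa - fn)), 1e-4)
})
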