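test_that("the toy force field is complete, valid and overridable", {
  expect_identical(ff_full$atoms$element, c("H", "O", "Fe", "S"))
  expect_silent(validate_forcefield(ff_full))
  f <- withr::local_tempfile()
  write_ffield(make_toy_forcefield(c("H", "O")), f)
  expect_s3_class(read_ffield(f), "reax_forcefield")
  ff2 <- make_toy_forcefield(overrides = list(
    list(section = "bonds", key = "Fe-S", param = "De_s", value = 123.4567)
  ))
  expect_equal(ff_get_param(ff2, "bonds", "Fe-S", "De_s"), 123.4567)
  # a written override survives the fixed-format round trip
  f2 <- withr::local_tempfile()
  write_ffield(ff2, f2)
  expect_equal(ff_get_param(read_ffield(f2), "bonds", "Fe-S", "De_s"),
    123.4567,
    tolerance = 1e-10
  )
  expect_error(
    make_toy_forcefield(overrides = list(
      list(section = "bonds", key = "Fe-S", param = "nope", value = 1)
    )),
    "unknown bond parameter"
  )
})

test_that("zeroed vdW depth kills the vdW term", {
  ff <- make_toy_forcefield(c("H", "O"))
  ff$atoms$epsilon <- rep(0, 2)
  ff$offdiag$epsilon <- 0
  suppressWarnings({
    e <- compute_energy(water_dimer(), ff)
  })
  expect_identical(e$E_vdW, 0)
})

test_that("solvated boxes are deterministic and respect composition", {
  spec <- box_spec(c(11, 11, 11), 12, solute = fe2s2_cluster(0), seed = 5)
  b1 <- build_solvated_box(spec)
  b2 <- build_solvated_box(spec)
  expect_identical(b1$coords, b2$coords)
  expect_identical(n_atoms(b1), 4L + 12L * 3L)
  expect_equal(b1$cell, c(11, 11, 11))
  # solute centered
  expect_equal(colMeans(b1$coords[1:4, ]), c(11, 11, 11) / 2, tolerance = 1e-8)
  # minimum heavy-atom separation honoured (O and solute heavy atoms)
  heavy <- which(b1$symbols != "H")
  dmin <- Inf
  for (i in heavy) {
    for (j in heavy) {
      if (j <= i) next
      # skip intra-solute pairs
      if (i <= 4 && j <= 4) next
      d <- b1$coords[j, ] - b1$coords[i, ]
      d <- d - b1$cell * round(d / b1$cell)
      dmin <- min(dmin, sqrt(sum(d^2)))
    }
  }
  expect_gte(dmin, 2.0)
  # density reported
  expect_gt(attr(b1, "density"), 0)
})

test_that("a box without waters is just the centered solute", {
  b <- build_solvated_box(
    box_spec(c(10, 10, 10), 0, solute = fe2s2_cluster(0), seed = 1)
  )
  expect_identical(n_atoms(b), 4L)
  expect_equal(colMeans(b$coords), c(5, 5, 5), tolerance = 1e-10)
})

test_that("the reference simulation box composition is reproduced", {
  b <- build_solvated_box(
    box_spec(c(13.0, 16.4, 15.24), 78,
      solute = fe2s2_cluster(0),
      min_separation = 2.0, seed = 7
    )
  )
  expect_identical(n_atoms(b), 2L + 2L + 78L * 3L)
  # density = water mass over box volume, computed independently
  rho <- 78 * 18.01528 / 6.02214076e23 / (prod(c(13.0, 16.4, 15.24)) * 1e-24)
  expect_equal(attr(b, "density"), rho, tolerance = 1e-6)
})

test_that("packing failure raises an error", {
  expect_error(
    build_solvated_box(box_spec(c(5, 5, 5), 60, min_separation = 2.5, seed = 1)),
    "packing failure"
  )
})

test_that("synthetic trainsets are reproducible and label partitions", {
  geoms <- list(
    water = water_molecule(),
    fe2s2_w2 = fe2s2_cluster(2)
  )
  scans <- list(
    water = list(scan_spec("bond", c(1, 2), 0.2, c(0.2, 0.4))),
    fe2s2_w2 = list(scan_spec("cluster_water_distance", c(1, 5), 0.5, c(0.5, 1.0)))
  )
  suppressWarnings({
    ts1 <- make_synthetic_trainset(ff_full, geoms, scans,
      noise_sd = 0.5, seed = 9,
      validation_clusters = "fe2s2_w2"
    )
    ts2 <- make_synthetic_trainset(ff_full, geoms, scans,
      noise_sd = 0.5, seed = 9,
      validation_clusters = "fe2s2_w2"
    )
  })
  expect_identical(ts1$entries$reference, ts2$entries$reference)
  expect_true(all(
    ts1$entries$partition[grepl("fe2s2", ts1$entries$id)] == "validation"
  ))
  expect_true(all(
    ts1$entries$partition[grepl("water", ts1$entries$id)] == "train"
  ))
  # with noise the references differ from the noise-free ones
  suppressWarnings({
    ts0 <- make_synthetic_trainset(ff_full, geoms, scans, noise_sd = 0)
  })
  expect_false(all(ts0$entries$reference == ts1$entries$reference))
})
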