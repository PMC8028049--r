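test_that("bond scans hit the requested offsets exactly", {
  w <- water_molecule()
  sc <- generate_scan(w, scan_spec("bond", c(1, 2), 0.2, c(0.2, 0.6)))
  expect_length(sc, 3)
  r0 <- measure_coordinate(w, c(1, 2))
  got <- vapply(sc, measure_coordinate, 0, indices = c(1, 2)) - r0
  expect_equal(got, c(0.2, 0.4, 0.6), tolerance = 1e-8)
  # the untouched O-H bond is unchanged
  other <- vapply(sc, measure_coordinate, 0, indices = c(1, 3))
  expect_equal(other, rep(measure_coordinate(w, c(1, 3)), 3), tolerance = 1e-10)
})

test_that("angle scans change only the scanned angle", {
  w <- water_molecule()
  sc <- generate_scan(w, scan_spec("angle", c(2, 1, 3), 10, c(-20, 20)))
  a0 <- measure_coordinate(w, c(2, 1, 3))
  got <- vapply(sc, measure_coordinate, 0, indices = c(2, 1, 3)) - a0
  expect_equal(got, c(-20, -10, 10, 20), tolerance = 1e-8)
  for (s in sc) {
    expect_equal(measure_coordinate(s, c(1, 2)), measure_coordinate(w, c(1, 2)),
      tolerance = 1e-8
    )
    expect_equal(measure_coordinate(s, c(1, 3)), measure_coordinate(w, c(1, 3)),
      tolerance = 1e-8
    )
  }
})

test_that("torsion scans rotate the far fragment by the requested angle", {
  s <- reax_structure(
    c("H", "S", "S", "H"),
    rbind(c(0.2, 0.9, 0.3), c(0, 0, 1.34), c(2.06, 0, 1.2), c(2.4, 1.1, 1.9))
  )
  sc <- generate_scan(s, scan_spec("torsion", c(1, 2, 3, 4), 15, c(-30, 30)))
  w0 <- measure_coordinate(s, c(1, 2, 3, 4))
  got <- vapply(sc, measure_coordinate, 0, indices = c(1, 2, 3, 4)) - w0
  expect_equal(got, c(-30, -15, 15, 30), tolerance = 1e-8)
  # bond lengths untouched
  for (p in list(c(1, 2), c(2, 3), c(3, 4))) {
    expect_equal(
      vapply(sc, measure_coordinate, 0, indices = p),
      rep(measure_coordinate(s, p), 4),
      tolerance = 1e-8
    )
  }
})

test_that("cluster-water scans translate an intact rigid water", {
  s <- fe2s2_cluster(2)
  sc <- generate_scan(
    s, scan_spec("cluster_water_distance", c(1, 5), 0.3, c(0.3, 0.9))
  )
  r0 <- measure_coordinate(s, c(1, 5))
  got <- vapply(sc, measure_coordinate, 0, indices = c(1, 5)) - r0
  expect_equal(got, c(0.3, 0.6, 0.9), tolerance = 1e-8)
  for (d in sc) {
    expect_equal(measure_coordinate(d, c(5, 6)), measure_coordinate(s, c(5, 6)),
      tolerance = 1e-8
    )
    expect_equal(measure_coordinate(d, c(5, 7)), measure_coordinate(s, c(5, 7)),
      tolerance = 1e-8
    )
    expect_equal(
      measure_coordinate(d, c(6, 5, 7)), measure_coordinate(s, c(6, 5, 7)),
      tolerance = 1e-8
    )
  }
})

test_that("scan specification errors are caught", {
  w <- water_molecule()
  expect_error(scan_spec("bond", c(1, 2), -0.1, c(0.1, 0.3)), "positive")
  expect_error(scan_spec("bond", c(1, 2), 0.1, c(0.5, 0.1)), "min < max")
  expect_error(scan_spec("angle", c(1, 2), 10, c(-10, 10)), "3 atom indices")
  # collinear atoms leave the rotation axis undefined
  lin <- reax_structure(
    c("O", "H", "O"),
    rbind(c(-1, 0, 0), c(0, 0, 0), c(1.3, 0, 0))
  )
  expect_error(
    generate_scan(lin, scan_spec("angle", c(1, 2, 3), 10, c(-10, 10))),
    "collinear"
  )
  # pivot atoms may not move
  expect_error(
    generate_scan(w, scan_spec("bond", c(1, 2), 0.1, c(0.1, 0.2),
      moving_set = c(1, 2)
    )),
    "pivot"
  )
})
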