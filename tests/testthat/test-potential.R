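test_that("taper satisfies its boundary conditions", {
  expect_identical(taper_value(0, 10), 1)
  expect_identical(taper_value(10, 10), 0)
  expect_identical(taper_value(12, 10), 0)
  expect_error(taper_value(1, -1), "positive")
  # derivative vanishes at the cutoff
  h <- 1e-5
  expect_lt(abs(taper_value(10 + h, 10) - taper_value(10 - h, 10)) / (2 * h), 1e-6)
  # interior derivative matches the closed form
  rr <- 4.321
  num <- (taper_value(rr + 1e-6, 10) - taper_value(rr - 1e-6, 10)) / 2e-6
  expect_equal(reaxkit:::taper_deriv(rr, 10), num, tolerance = 1e-6)
})

test_that("neighbor lists are complete within the cutoff", {
  s <- reax_structure(c("H", "H"), rbind(c(0, 0, 0), c(5, 0, 0)))
  nl <- build_neighbor_list(s, ff_ho)
  expect_length(nl$i, 1)
  s2 <- reax_structure(c("H", "H"), rbind(c(0, 0, 0), c(15, 0, 0)))
  expect_length(build_neighbor_list(s2, ff_ho)$i, 0)
  expect_error(
    build_neighbor_list(
      reax_structure(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1e-8))), ff_ho
    ),
    "overlapping"
  )
})

test_that("periodic neighbor list matches a brute-force image scan", {
  set.seed(42)
  cell <- c(7, 8, 9)
  n <- 20
  x <- cbind(runif(n, 0, 7), runif(n, 0, 8), runif(n, 0, 9))
  s <- reax_structure(rep("O", n), x, cell = cell)
  nl <- build_neighbor_list(s, ff_ho)
  r_cut <- ff_ho$general[["swb"]]
  # O(N^2 * images) oracle over unordered pair/image combinations
  count <- 0L
  for (i in 1:n) {
    for (j in i:n) {
      for (sx in -2:2) {
        for (sy in -2:2) {
          for (sz in -2:2) {
            if (i == j) {
              # one representative per +/- shift pair, skip the zero shift
              if (!(sx > 0 || (sx == 0 && sy > 0) ||
                (sx == 0 && sy == 0 && sz > 0))) {
                next
              }
            } else if (sx == 0 && sy == 0 && sz == 0) {
              # zero-shift i<j pair counted below like any other shift
            }
            d <- x[j, ] + c(sx, sy, sz) * cell - x[i, ]
            if (sqrt(sum(d^2)) <= r_cut) count <- count + 1L
          }
        }
      }
    }
  }
  expect_identical(length(nl$i), count)
})

test_that("bond orders vanish beyond the cutoff and respect symmetry", {
  far <- reax_structure(c("O", "H"), rbind(c(0, 0, 0), c(8, 0, 0)))
  bo <- compute_bond_orders(far, ff_ho)
  expect_identical(nrow(bo$pairs), 0L)
  expect_equal(bo$delta, -c(2, 1)) # bare valencies
  single <- reax_structure("O", rbind(c(0, 0, 0)))
  bo1 <- compute_bond_orders(single, ff_ho)
  expect_identical(nrow(bo1$pairs), 0L)
  # symmetric O-H-O: equal bond orders on both legs
  sym <- reax_structure(
    c("O", "H", "O"),
    rbind(c(-1.2, 0, 0), c(0, 0, 0), c(1.2, 0, 0))
  )
  bos <- compute_bond_orders(sym, ff_ho)$pairs
  oh <- bos[bos$i != 1 | bos$j != 3, ]
  oh <- oh[(oh$i == 2 | oh$j == 2), ]
  expect_equal(oh$bo[1], oh$bo[2], tolerance = 1e-12)
  # corrections damp bond orders of overcoordinated atoms: an H with two
  # close neighbours keeps a total bond order near its valency of one
  h3 <- reax_structure(
    c("H", "H", "H"),
    rbind(c(-0.75, 0, 0), c(0, 0, 0), c(0.75, 0, 0))
  )
  bo3 <- compute_bond_orders(h3, ff_ho)
  at2 <- bo3$pairs$i == 2 | bo3$pairs$j == 2
  raw2 <- sum((bo3$pairs$bo_sigma_raw + bo3$pairs$bo_pi_raw +
    bo3$pairs$bo_pipi_raw)[at2])
  expect_lt(bo3$total_bo[2], 0.9 * raw2) # central H damped toward valency
  # all corrected bond orders stay finite and non-negative
  suppressWarnings({
    s <- random_mixed_structure(1, n = 8)
    pr <- compute_bond_orders(s, ff_full)$pairs
  })
  expect_true(all(pr$bo >= 0 & is.finite(pr$bo)))
})

test_that("missing bond parameters for a close pair raise a named error", {
  ff <- ff_full
  ff$bonds <- ff$bonds[!(ff$bonds$el1 == "Fe" & ff$bonds$el2 == "S") &
    !(ff$bonds$el1 == "S" & ff$bonds$el2 == "Fe"), ]
  s <- reax_structure(c("Fe", "S"), rbind(c(0, 0, 0), c(0, 0, 2.2)))
  expect_error(compute_bond_orders(s, ff), "Fe-S")
})

test_that("EEM charges obey symmetry and the total-charge constraint", {
  s0 <- reax_structure(c("O", "O"), rbind(c(0, 0, 0), c(0, 0, 1.3)))
  expect_equal(equilibrate_charges(s0, ff_ho), c(0, 0), tolerance = 1e-12)
  s1 <- s0
  s1$total_charge <- -1
  expect_equal(equilibrate_charges(s1, ff_ho), c(-0.5, -0.5), tolerance = 1e-12)
  suppressWarnings({
    w <- water_dimer()
    q <- equilibrate_charges(w, ff_ho)
  })
  expect_lt(abs(sum(q)), 1e-10)
})

test_that("EEM solution equalizes effective electronegativities", {
  suppressWarnings({
    s <- fe2s2_cluster(2)
    q <- equilibrate_charges(s, ff_full)
    nl <- build_neighbor_list(s, ff_full)
  })
  # rebuild the EEM matrix independently of the solver path
  els <- s$symbols
  chi <- vapply(els, function(e) ff_get_param(ff_full, "atoms", e, "chi"), 0) * 23.0609
  eta <- vapply(els, function(e) ff_get_param(ff_full, "atoms", e, "eta"), 0) * 23.0609
  gam <- vapply(els, function(e) ff_get_param(ff_full, "atoms", e, "gamma"), 0)
  n <- n_atoms(s)
  K <- matrix(0, n, n)
  for (k in seq_along(nl$i)) {
    i <- nl$i[k]
    j <- nl$j[k]
    gij <- sqrt(gam[i] * gam[j])
    kv <- 332.0637 * taper_value(nl$r[k], 10) / (nl$r[k]^3 + gij^-3)^(1 / 3)
    K[i, j] <- K[i, j] + kv
    K[j, i] <- K[j, i] + kv
  }
  mu <- chi + 2 * eta * q + as.numeric(K %*% q)
  expect_lt(max(mu) - min(mu), 1e-6)
})

test_that("energy breakdown is internally consistent", {
  suppressWarnings({
    e <- compute_energy(fe2s2_cluster(2), ff_full)
  })
  terms <- setdiff(names(e), c("total", "charges"))
  expect_equal(sum(unlist(e[terms])), e$total, tolerance = 1e-8)
  # single atom: only the self/polarization term can be nonzero
  h <- reax_structure("H", rbind(c(0, 0, 0)))
  eh <- compute_energy(h, ff_ho)
  expect_identical(eh$E_bond, 0)
  expect_identical(eh$E_vdW, 0)
  expect_equal(eh$total, eh$E_charge)
  # two identical atoms beyond every cutoff: zero energy, zero charges
  far <- reax_structure(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 15)))
  ef <- compute_energy(far, ff_ho)
  expect_equal(ef$total, 0, tolerance = 1e-12)
  expect_equal(ef$charges, c(0, 0), tolerance = 1e-12)
})

test_that("energy is invariant under rigid motion and atom permutation", {
  suppressWarnings({
    s <- fe2s2_cluster(2)
    e0 <- compute_energy(s, ff_full)$total
    # translation
    st <- s
    st$coords <- sweep(st$coords, 2, -c(3.7, -1.2, 0.4))
    expect_lt(abs(compute_energy(st, ff_full)$total - e0), 1e-6)
    # rotation
    sr <- s
    sr$coords <- s$coords %*% t(random_rotation(99))
    expect_lt(abs(compute_energy(sr, ff_full)$total - e0), 1e-6)
    # permutation of identical atoms (swap the two Fe and the two S)
    sp <- s
    perm <- c(2, 1, 4, 3, 5:n_atoms(s))
    sp$symbols <- s$symbols[perm]
    sp$coords <- s$coords[perm, ]
    expect_equal(compute_energy(sp, ff_full)$total, e0, tolerance = 1e-12)
  })
})

test_that("energy terms switch off smoothly at the nonbonded cutoff", {
  r_cut <- ff_ho$general[["swb"]]
  e_at <- function(r) {
    compute_energy(
      reax_structure(c("O", "H"), rbind(c(0, 0, 0), c(r, 0, 0))), ff_ho
    )$total
  }
  below <- e_at(r_cut - 1e-3)
  above <- e_at(r_cut + 1e-3)
  expect_lt(abs(above - below), 1e-6)
})
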