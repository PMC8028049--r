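test_that("minimization is idempotent at a minimum and monotone in energy", {
  suppressWarnings({
    w <- minimize_structure(water_molecule(), ff_ho, rmsg_tol = 1e-4)
    w2 <- minimize_structure(w, ff_ho, rmsg_tol = 1e-4)
  })
  expect_equal(w2$coords, w$coords, tolerance = 1e-6)
  expect_lte(attr(w, "energy"), compute_energy(water_molecule(), ff_ho)$total)
  expect_lte(attr(w, "rmsg"), 1e-4)
  trace <- attr(w, "energy_trace")
  expect_true(all(diff(trace) <= 1e-8))
})

test_that("a stretched diatomic relaxes to the 1-D scan minimum", {
  # golden-section oracle over the dimer bond length
  dimer_at <- function(r) {
    reax_structure(c("O", "H"), rbind(c(0, 0, 0), c(r, 0, 0)))
  }
  e_of <- function(r) compute_energy(dimer_at(r), ff_ho)$total
  gold <- optimize(e_of, interval = c(0.7, 1.6), tol = 1e-8)
  s0 <- dimer_at(gold$minimum + 0.1)
  relaxed <- minimize_structure(s0, ff_ho, rmsg_tol = 1e-5)
  expect_equal(measure_coordinate(relaxed, c(1, 2)), gold$minimum,
    tolerance = 1e-3
  )
})

test_that("md_config validates its invariants", {
  expect_error(md_config(timestep = 0), "positive")
  expect_error(md_config(temperature = -5), "positive")
  expect_error(md_config(timestep = 1, berendsen_tau = 0.5), "timestep")
})

test_that("Berendsen rescale with tau = dt pins the kinetic temperature", {
  suppressWarnings({
    cfg <- md_config(
      timestep = 0.1, temperature = 250, berendsen_tau = 0.1,
      n_steps = 1, seed = 2
    )
    st <- md_init(water_dimer(), ff_ho, cfg)
    st$velocities <- st$velocities * 1.7 # knock T off target
    st2 <- md_step(st, ff_ho, cfg)
  })
  expect_equal(st2$temperature, 250, tolerance = 1e-8)
})

test_that("free particles move uniformly when the thermostat is off", {
  # two atoms far beyond every cutoff: zero forces
  s <- reax_structure(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 30)))
  cfg <- md_config(
    timestep = 0.5, temperature = 300, berendsen_tau = Inf,
    n_steps = 4, seed = 3, record_every = 1
  )
  tab <- reaxkit:::ff_tables(ff_ho)
  st <- md_init(s, ff_ho, cfg, tab)
  v0 <- st$velocities
  expect_lt(max(abs(st$forces)), 1e-12)
  for (k in 1:4) st <- md_step(st, ff_ho, cfg, tab)
  expect_equal(st$velocities, v0, tolerance = 1e-12)
  expect_equal(st$structure$coords, s$coords + v0 * 4 * 0.5, tolerance = 1e-10)
})

test_that("MD is deterministic for a fixed seed and n_steps = 0 yields one frame", {
  suppressWarnings({
    d <- water_dimer()
    cfg <- md_config(
      timestep = 0.2, temperature = 200, berendsen_tau = 25,
      n_steps = 40, seed = 7, record_every = 10
    )
    t1 <- run_md(d, ff_ho, cfg)
    t2 <- run_md(d, ff_ho, cfg)
  })
  expect_identical(
    t1$frames[[length(t1$frames)]]$positions,
    t2$frames[[length(t2$frames)]]$positions
  )
  suppressWarnings({
    t0 <- run_md(d, ff_ho, md_config(n_steps = 0, seed = 1))
  })
  expect_length(t0$frames, 1)
})

test_that("center-of-mass momentum is removed and conserved", {
  suppressWarnings({
    d <- water_dimer()
    cfg <- md_config(
      timestep = 0.1, temperature = 300, berendsen_tau = Inf,
      n_steps = 50, seed = 9, record_every = 50
    )
    tab <- reaxkit:::ff_tables(ff_ho)
    st <- md_init(d, ff_ho, cfg, tab)
    m <- reaxkit:::masses_for(d, tab)
    p0 <- colSums(st$velocities * m)
    expect_lt(max(abs(p0)), 1e-10)
    for (k in 1:50) st <- md_step(st, ff_ho, cfg, tab)
  })
  expect_lt(max(abs(colSums(st$velocities * m))), 1e-8)
})

test_that("MD detects blow-ups", {
  st <- list(
    structure = water_molecule(),
    velocities = matrix(NaN, 3, 3),
    forces = matrix(0, 3, 3), time = 0
  )
  cfg <- md_config(timestep = 0.1, n_steps = 1, seed = 1)
  expect_error(suppressWarnings(md_step(st, ff_ho, cfg)), "non-finite")
})
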