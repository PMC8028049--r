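dummy_trainset <- function(pred_offsets, weights,
                           partition = rep("train", length(pred_offsets))) {
  # entries whose reference is offset from the model's own prediction so the
  # residuals are known exactly
  w <- water_molecule()
  eq <- w
  d <- w
  d$coords[2, 1] <- d$coords[2, 1] + 0.2
  e_diff <- compute_energy(d, ff_ho)$total - compute_energy(eq, ff_ho)$total
  entries <- tibble::tibble(
    id = paste0("e", seq_along(pred_offsets)), kind = "energy_difference",
    structure_ids = "d,eq", detail = "",
    reference = e_diff - pred_offsets, weight = weights, partition = partition
  )
  reax_trainset(entries, list(d = d, eq = eq))
}

test_that("the cost is the weighted sum of squared residuals", {
  mask <- parameter_mask(
    tibble::tibble(
      section = "bonds", key = "H-O", param = "De_s",
      lower = 100, upper = 220
    ),
    ff_ho
  )
  p0 <- mask_values(ff_ho, mask)
  # residuals 1 and 2, weights 1 and 0.5 -> 1*1 + 0.5*4 = 3
  ts <- dummy_trainset(c(1, 2), c(1, 0.5))
  expect_equal(evaluate_cost(p0, ts, ff_ho, mask), 3.0, tolerance = 1e-8)
  # reciprocal-variance convention: (1/1)^2 + (2/0.5)^2 = 17
  expect_equal(
    evaluate_cost(p0, ts, ff_ho, mask, weight_convention = "divide"),
    17,
    tolerance = 1e-8
  )
  # validation entries never contribute
  ts2 <- dummy_trainset(c(1, 2), c(1, 0.5), partition = c("train", "validation"))
  expect_equal(evaluate_cost(p0, ts2, ff_ho, mask), 1.0, tolerance = 1e-8)
  # empty training set
  ts3 <- dummy_trainset(1, 1, partition = "validation")
  expect_identical(evaluate_cost(p0, ts3, ff_ho, mask), 0)
})

test_that("a synthetic trainset costs zero at the generating parameters", {
  ts <- make_synthetic_trainset(
    ff_ho, list(water = water_molecule()),
    list(water = list(scan_spec("bond", c(1, 2), 0.2, c(-0.2, 0.4)))),
    include_charges = TRUE
  )
  mask <- parameter_mask(
    tibble::tibble(
      section = c("bonds", "atoms"), key = c("H-O", "O"),
      param = c("De_s", "chi"), lower = c(100, 6), upper = c(220, 10)
    ),
    ff_ho
  )
  truth <- mask_values(ff_ho, mask)
  expect_equal(evaluate_cost(truth, ts, ff_ho, mask), 0, tolerance = 1e-12)
  expect_equal(evaluate_cost(truth, ts, ff_ho, mask, stage = "charges_only"), 0,
    tolerance = 1e-12
  )
  # perturbed parameters cost more
  expect_gt(evaluate_cost(truth * c(1.1, 1.0), ts, ff_ho, mask), 0)
  # charges_only stage ignores the energy entries
  expect_gt(evaluate_cost(truth * c(1.1, 1.0), ts, ff_ho, mask),
    evaluate_cost(truth * c(1.1, 1.0), ts, ff_ho, mask, stage = "charges_only"))
})

test_that("staged charge-only training recovers a known electronegativity", {
  ts <- make_synthetic_trainset(
    ff_ho, list(water = water_molecule()),
    list(water = list(scan_spec("bond", c(1, 2), 0.2, c(0.2, 0.4)))),
    include_charges = TRUE
  )
  mask <- parameter_mask(
    tibble::tibble(
      section = "atoms", key = "O", param = "chi",
      lower = 6, upper = 10
    ),
    ff_ho
  )
  cost1 <- function(p) {
    evaluate_cost(p, ts, ff_ho, mask, stage = "charges_only")
  }
  opt <- optimize(function(p) cost1(p), c(6, 10), tol = 1e-10)
  expect_equal(opt$minimum, ff_get_param(ff_ho, "atoms", "O", "chi"),
    tolerance = 1e-4
  )
  expect_lt(opt$objective, 1e-10)
})

test_that("canonical gbest PSO recovers a known sphere optimum", {
  cfg <- swarm_config(
    n_agents = 20, max_iters = 200, seed = 7,
    respawn_fraction = 0, polish_every = 0
  )
  target <- c(0.3, -1.2)
  res <- pso_optimize(
    function(p) sum((p - target)^2), c(-5, -5), c(5, 5), cfg
  )
  expect_equal(res$par, target, tolerance = 1e-3)
  expect_true(all(diff(res$history$best_cost) <= 1e-12))
})

test_that("Gaussian respawn and polishing never worsen the global best", {
  cfg <- swarm_config(
    n_agents = 10, max_iters = 60, seed = 3,
    respawn_fraction = 0.3, polish_every = 15
  )
  rosen <- function(p) (1 - p[1])^2 + 100 * (p[2] - p[1]^2)^2
  res <- pso_optimize(rosen, c(-2, -2), c(2, 2), cfg)
  expect_true(all(diff(res$history$best_cost) <= 1e-12))
  expect_lt(res$value, rosen(c(0, 0)))
})

test_that("Nelder-Mead polishing respects bounds and never regresses", {
  quad <- function(p) (p[1] - 0.5)^2
  pol <- polish_nelder_mead(quad, 0.9, lower = 0, upper = 1)
  expect_equal(pol$par, 0.5, tolerance = 1e-4)
  expect_lt(pol$value, 1e-6)
  # start at a boundary optimum outside which it may not move
  pol2 <- polish_nelder_mead(function(p) -p[1], 1, lower = 0, upper = 1)
  expect_lte(pol2$par, 1)
  expect_lte(pol2$value, -1 + 1e-12)
  # a pathological cost falls back to the start
  pol3 <- polish_nelder_mead(function(p) stop("boom"), 0.5,
    lower = 0, upper = 1
  )
  expect_identical(pol3$par, 0.5)
})

test_that("failed evaluations hit the penalty ceiling instead of crashing", {
  ts <- dummy_trainset(1, 1)
  # an absurd parameter that breaks the energy evaluation path
  mask <- parameter_mask(
    tibble::tibble(
      section = "general", key = "swb", param = "swb",
      lower = -20, upper = 20
    ),
    ff_ho
  )
  val <- evaluate_cost(-5, ts, ff_ho, mask)
  expect_identical(val, 1e8)
})
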