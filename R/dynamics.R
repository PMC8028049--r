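# Geometry optimization to a root-mean-square-gradient criterion and NVT
# molecular dynamics (velocity Verlet + Berendsen weak-coupling thermostat).

masses_for <- function(s, tab) {
  t <- match(s$symbols, tab$els)
  m <- tab$mass[t]
  if (anyNA(m)) m[is.na(m)] <- REAX_MASSES[s$symbols[is.na(m)]]
  m
}

#' Root-mean-square gradient of a structure
#'
#' @param s A [reax_structure].
#' @param ff A [reax_forcefield].
#' @return RMS over all 3N Cartesian gradient components
#'   (kcal/mol/Angstrom).
#' @export
rmsg <- function(s, ff) {
  f <- reax_eval(s, ff, want_forces = TRUE)$forces
  sqrt(mean(f^2))
}

#' Minimize a structure to an RMSG criterion
#'
#' Quasi-Newton (L-BFGS-B) minimization of the total energy with the
#' analytic gradient, iterated until the root-mean-square gradient over all
#' 3N components falls below `rmsg_tol`.
#'
#' @param s A [reax_structure].
#' @param ff A [reax_forcefield].
#' @param rmsg_tol Convergence criterion, kcal/mol/Angstrom.
#' @param max_rounds Maximum optimizer restarts (each up to `maxit`
#'   iterations).
#' @param maxit L-BFGS-B iteration cap per round.
#' @return The relaxed [reax_structure]; attributes `energy` (kcal/mol),
#'   `rmsg` and `energy_trace` (per-round energies). On non-convergence an
#'   error of class `reaxkit_minimize_error` carries the best-so-far
#'   structure in its `best` field.
#' @export
minimize_structure <- function(s, ff, rmsg_tol = 1e-3, max_rounds = 40,
                               maxit = 200) {
  if (rmsg_tol <= 0) stop("`rmsg_tol` must be positive", call. = FALSE)
  validate_structure(s)
  tab <- ff_tables(ff)
  cur <- s
  x0 <- as.numeric(s$coords)
  fn <- function(x) {
    cur$coords <- matrix(x, ncol = 3)
    reax_eval(cur, ff, tables = tab, want_forces = FALSE)$total
  }
  gr <- function(x) {
    cur$coords <- matrix(x, ncol = 3)
    -as.numeric(reax_eval(cur, ff, tables = tab, want_forces = TRUE)$forces)
  }
  trace <- numeric(0)
  x <- x0
  for (round in seq_len(max_rounds)) {
    g <- gr(x)
    cur_rmsg <- sqrt(mean(g^2))
    trace <- c(trace, fn(x))
    if (cur_rmsg <= rmsg_tol) {
      out <- s
      out$coords <- matrix(x, ncol = 3)
      attr(out, "energy") <- fn(x)
      attr(out, "rmsg") <- cur_rmsg
      attr(out, "energy_trace") <- trace
      return(out)
    }
    opt <- stats::optim(x, fn, gr,
      method = "L-BFGS-B",
      control = list(maxit = maxit, factr = 10, pgtol = rmsg_tol * 1e-2)
    )
    x <- opt$par
  }
  best <- s
  best$coords <- matrix(x, ncol = 3)
  stop(errorCondition(
    sprintf(
      "minimization did not reach RMSG %.3g (best %.3g)", rmsg_tol,
      sqrt(mean(gr(x)^2))
    ),
    class = c("reaxkit_minimize_error", "error"),
    best = best
  ))
}

#' Molecular-dynamics configuration
#'
#' @param timestep Integration time step, fs.
#' @param temperature Thermostat target, K.
#' @param berendsen_tau Berendsen coupling constant, fs; `Inf` disables the
#'   thermostat (NVE).
#' @param n_steps Number of integration steps.
#' @param seed Integer seed for the Maxwell-Boltzmann initialization.
#' @param record_every Record a frame every this many steps.
#' @return A list of class `reax_mdconfig`.
#' @export
md_config <- function(timestep = 0.1, temperature = 300,
                      berendsen_tau = 25, n_steps = 1000, seed = 1,
                      record_every = 10) {
  if (timestep <= 0) stop("`timestep` must be positive", call. = FALSE)
  if (temperature <= 0) stop("`temperature` must be positive", call. = FALSE)
  if (is.finite(berendsen_tau) && berendsen_tau < timestep) {
    stop("`berendsen_tau` must be at least one timestep", call. = FALSE)
  }
  structure(
    list(
      timestep = timestep, temperature = temperature,
      berendsen_tau = berendsen_tau, n_steps = n_steps, seed = seed,
      record_every = record_every
    ),
    class = "reax_mdconfig"
  )
}

kinetic_energy <- function(v, m) {
  0.5 * sum(m * rowSums(v^2)) * MASS_VEL2_TO_KCAL
}

instantaneous_temperature <- function(v, m, dof) {
  2 * kinetic_energy(v, m) / (dof * KB_KCAL)
}

md_dof <- function(s) if (is.null(s$cell)) 3L * n_atoms(s) - 3L else 3L * n_atoms(s)

#' Advance an MD state by one step
#'
#' One velocity-Verlet step followed (when the thermostat is active) by a
#' Berendsen velocity rescale
#' `lambda = sqrt(1 + (dt/tau) * (T0/T_inst - 1))`.
#'
#' @param state List with `structure` (a [reax_structure]), `velocities`
#'   (N x 3, Angstrom/fs), `forces` (N x 3) and `time` (fs), e.g. from
#'   [md_init()].
#' @param ff A [reax_forcefield].
#' @param cfg A [md_config()].
#' @param tables Internal precompiled parameter tables (optional).
#' @return Updated state list (with refreshed `forces`, `time`,
#'   `temperature` and `energy`).
#' @export
md_step <- function(state, ff, cfg, tables = NULL) {
  if (is.null(tables)) tables <- ff_tables(ff)
  s <- state$structure
  m <- masses_for(s, tables)
  dt <- cfg$timestep
  inv2m <- dt / (2 * m * MASS_VEL2_TO_KCAL)
  v <- state$velocities + state$forces * inv2m
  s$coords <- s$coords + v * dt
  if (any(!is.finite(s$coords))) {
    stop("MD blow-up: non-finite coordinates", call. = FALSE)
  }
  ev <- reax_eval(s, ff, tables = tables, want_forces = TRUE)
  v <- v + ev$forces * inv2m
  dof <- md_dof(s)
  t_inst <- instantaneous_temperature(v, m, dof)
  if (is.finite(cfg$berendsen_tau) && t_inst > 0) {
    lambda <- sqrt(1 + (dt / cfg$berendsen_tau) *
      (cfg$temperature / t_inst - 1))
    v <- v * lambda
    t_inst <- instantaneous_temperature(v, m, dof)
  }
  list(
    structure = s, velocities = v, forces = ev$forces,
    time = state$time + dt, temperature = t_inst,
    energy = c(ev$breakdown, list(total = ev$total)),
    kinetic = kinetic_energy(v, m)
  )
}

#' Initialize an MD state with Maxwell-Boltzmann velocities
#'
#' Velocities are drawn from the Maxwell-Boltzmann distribution at the
#' target temperature (seeded), the center-of-mass motion is removed, and
#' the result is rescaled so the instantaneous temperature equals the target
#' exactly.
#'
#' @inheritParams md_step
#' @param s A [reax_structure].
#' @return An MD state list (see [md_step()]).
#' @export
md_init <- function(s, ff, cfg, tables = NULL) {
  if (is.null(tables)) tables <- ff_tables(ff)
  m <- masses_for(s, tables)
  n <- n_atoms(s)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(cfg$seed)
  sd_v <- sqrt(KB_KCAL * cfg$temperature / (m * MASS_VEL2_TO_KCAL))
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd_v
  # remove center-of-mass motion
  vcom <- colSums(v * m) / sum(m)
  v <- sweep(v, 2, vcom)
  dof <- md_dof(s)
  t_now <- instantaneous_temperature(v, m, dof)
  if (t_now > 0) v <- v * sqrt(cfg$temperature / t_now)
  ev <- reax_eval(s, ff, tables = tables, want_forces = TRUE)
  list(
    structure = s, velocities = v, forces = ev$forces, time = 0,
    temperature = instantaneous_temperature(v, m, dof),
    energy = c(ev$breakdown, list(total = ev$total)),
    kinetic = kinetic_energy(v, m)
  )
}

#' Run constant-temperature molecular dynamics
#'
#' Velocity-Verlet NVT with a Berendsen thermostat. Deterministic for a
#' fixed `cfg$seed`.
#'
#' @param s Initial [reax_structure].
#' @param ff A [reax_forcefield].
#' @param cfg A [md_config()].
#' @param progress Print a log line every `progress` steps (0 = silent).
#' @return A [reax_trajectory] whose frames carry positions, velocities,
#'   instantaneous temperature and the energy breakdown.
#' @export
run_md <- function(s, ff, cfg, progress = 0) {
  validate_structure(s)
  tables <- ff_tables(ff)
  state <- md_init(s, ff, cfg, tables)
  grab <- function(st) {
    list(
      time = st$time, positions = st$structure$coords,
      velocities = st$velocities, temperature = st$temperature,
      energy = st$energy, kinetic = st$kinetic
    )
  }
  frames <- list(grab(state))
  if (cfg$n_steps > 0) {
    for (step in seq_len(cfg$n_steps)) {
      state <- md_step(state, ff, cfg, tables)
      if (step %% cfg$record_every == 0 || step == cfg$n_steps) {
        frames[[length(frames) + 1L]] <- grab(state)
      }
      if (progress > 0 && step %% progress == 0) {
        message(sprintf(
          "step %d  t=%.2f fs  T=%.1f K  E=%.4f kcal/mol",
          step, state$time, state$temperature, state$energy$total
        ))
      }
    }
  }
  # de-duplicate a possibly repeated final frame
  times <- vapply(frames, function(f) f$time, 0)
  frames <- frames[!duplicated(times)]
  reax_trajectory(s$symbols, frames, cell = s$cell)
}
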