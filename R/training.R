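# Force-field training: parameter masks, the weighted least-squares cost,
# bound-constrained particle-swarm optimization with Gaussian-mutation
# respawn, and Nelder-Mead polishing.

#' Define trainable parameters and their bounds
#'
#' @param entries Data frame/tibble with columns `section`, `key`, `param`,
#'   `lower`, `upper` (see [ff_get_param()] for the addressing scheme).
#' @param template A [reax_forcefield] used to check that every selected
#'   parameter exists.
#' @return A tibble of class `reax_parameter_mask`.
#' @export
parameter_mask <- function(entries, template) {
  m <- tibble::as_tibble(entries)
  needed <- c("section", "key", "param", "lower", "upper")
  if (!all(needed %in% names(m))) {
    stop("mask needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(m$lower)) || any(!is.finite(m$upper)) ||
    any(m$lower >= m$upper)) {
    stop("mask bounds must be finite with lower < upper", call. = FALSE)
  }
  for (k in seq_len(nrow(m))) {
    ff_get_param(template, m$section[k], m$key[k], m$param[k]) # errors if absent
  }
  class(m) <- c("reax_parameter_mask", class(m))
  m
}

#' Extract masked parameter values from a force field
#'
#' @param ff A [reax_forcefield].
#' @param mask A [parameter_mask()].
#' @return Numeric vector in mask order.
#' @export
mask_values <- function(ff, mask) {
  vapply(
    seq_len(nrow(mask)),
    function(k) ff_get_param(ff, mask$section[k], mask$key[k], mask$param[k]),
    0
  )
}

#' Apply masked parameter values to a force field
#'
#' @param ff A [reax_forcefield].
#' @param mask A [parameter_mask()].
#' @param values Numeric vector in mask order.
#' @return The modified force field.
#' @export
mask_apply <- function(ff, mask, values) {
  for (k in seq_len(nrow(mask))) {
    ff <- ff_set_param(ff, mask$section[k], mask$key[k], mask$param[k], values[k])
  }
  ff
}

#' Assemble a training set from scans and reference data
#'
#' Builds weighted energy-difference entries (distorted minus equilibrium)
#' from internal-coordinate scans and optional per-atom charge entries for
#' the equilibrium geometries. Clusters named in `validation_clusters` are
#' tagged `validation` and excluded from the training cost.
#'
#' @param scan_results List; each element is a list with fields `cluster`
#'   (id string), `equilibrium` (a [reax_structure]), `distorted` (list of
#'   structures) and `reference` (numeric reference energy differences,
#'   kcal/mol, one per distorted structure).
#' @param reference_charges Optional named list (cluster id -> per-atom
#'   reference charges, e) adding charge entries for the equilibrium
#'   geometry.
#' @param weights List with elements `energy` and `charge` giving the w_m
#'   applied to each entry kind.
#' @param validation_clusters Character vector of cluster ids forming the
#'   validation partition.
#' @return A [reax_trainset].
#' @export
assemble_training_set <- function(scan_results, reference_charges = NULL,
                                  weights = list(energy = 1, charge = 1),
                                  validation_clusters = character()) {
  structures <- list()
  rows <- list()
  for (sc in scan_results) {
    if (length(sc$distorted) != length(sc$reference)) {
      stop("cluster '", sc$cluster,
        "': one reference value is required per distorted structure",
        call. = FALSE
      )
    }
    eq_id <- paste0(sc$cluster, "_eq")
    structures[[eq_id]] <- sc$equilibrium
    part <- if (sc$cluster %in% validation_clusters) "validation" else "train"
    for (k in seq_along(sc$distorted)) {
      sid <- sprintf("%s_scan%03d", sc$cluster, k)
      structures[[sid]] <- sc$distorted[[k]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = sprintf("%s_e%03d", sc$cluster, k), kind = "energy_difference",
        structure_ids = paste(sid, eq_id, sep = ","), detail = "",
        reference = sc$reference[k], weight = weights$energy, partition = part
      )
    }
  }
  if (!is.null(reference_charges)) {
    for (cl in names(reference_charges)) {
      eq_id <- paste0(cl, "_eq")
      if (is.null(structures[[eq_id]])) {
        stop("reference charges for unknown cluster '", cl, "'", call. = FALSE)
      }
      part <- if (cl %in% validation_clusters) "validation" else "train"
      qs <- reference_charges[[cl]]
      for (a in seq_along(qs)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          id = sprintf("%s_q%03d", cl, a), kind = "charge",
          structure_ids = eq_id, detail = as.character(a),
          reference = qs[a], weight = weights$charge, partition = part
        )
      }
    }
  }
  reax_trainset(dplyr::bind_rows(rows), structures)
}

# Predicted values for every entry of a trainset under a force field.
# Returns a numeric vector aligned with ts$entries rows (NA for geometry
# items, which do not enter the cost).
predict_trainset <- function(ts, ff) {
  tab <- ff_tables(ff)
  e_cache <- new.env(parent = emptyenv())
  q_cache <- new.env(parent = emptyenv())
  energy_of <- function(id) {
    if (is.null(e_cache[[id]])) {
      e_cache[[id]] <- reax_eval(ts$structures[[id]], NULL,
        tables = tab,
        want_forces = FALSE
      )$total
    }
    e_cache[[id]]
  }
  charges_of <- function(id) {
    if (is.null(q_cache[[id]])) {
      s <- ts$structures[[id]]
      nl <- build_neighbor_list(s, list(general = c(swb = tab$r_taper)))
      q_cache[[id]] <- eem_solve(s, tab, nl, atom_types(s, tab))$q
    }
    q_cache[[id]]
  }
  out <- rep(NA_real_, nrow(ts$entries))
  for (k in seq_len(nrow(ts$entries))) {
    kind <- ts$entries$kind[k]
    ids <- entry_structure_ids(ts$entries$structure_ids[k])
    if (kind == "energy_difference") {
      out[k] <- energy_of(ids[1]) - energy_of(ids[2])
    } else if (kind == "charge") {
      out[k] <- charges_of(ids[1])[as.integer(ts$entries$detail[k])]
    }
  }
  out
}

#' Weighted least-squares training cost
#'
#' Sums `w_m * (y_m_ReaxFF - y_m_ref)^2` over the training-partition entries
#' matching the stage: charge entries only in stage `"charges_only"`, energy
#' and charge entries in stage `"all"`. Validation entries never contribute.
#' A failed energy evaluation yields the penalty ceiling rather than an
#' error.
#'
#' @param params Masked parameter vector (within bounds).
#' @param trainset A [reax_trainset].
#' @param ff_template A [reax_forcefield] whose masked entries are replaced
#'   by `params`.
#' @param mask A [parameter_mask()].
#' @param stage `"all"` or `"charges_only"`.
#' @param weight_convention `"multiply"` (w_m multiplies the squared
#'   residual, the default) or `"divide"` (reciprocal convention,
#'   `(residual / w_m)^2`).
#' @param penalty Cost returned when evaluation fails.
#' @return Non-negative scalar cost.
#' @export
evaluate_cost <- function(params, trainset, ff_template, mask,
                          stage = c("all", "charges_only"),
                          weight_convention = c("multiply", "divide"),
                          penalty = 1e8) {
  stage <- match.arg(stage)
  weight_convention <- match.arg(weight_convention)
  ff <- mask_apply(ff_template, mask, params)
  keep_kinds <- if (stage == "charges_only") "charge" else c("energy_difference", "charge")
  e <- trainset$entries
  sel <- which(e$partition == "train" & e$kind %in% keep_kinds)
  if (length(sel) == 0) {
    return(0)
  }
  pred <- tryCatch(predict_trainset(trainset, ff), error = function(err) NULL)
  if (is.null(pred) || anyNA(pred[sel]) || any(!is.finite(pred[sel]))) {
    return(penalty)
  }
  resid <- pred[sel] - e$reference[sel]
  if (weight_convention == "multiply") {
    sum(e$weight[sel] * resid^2)
  } else {
    sum((resid / e$weight[sel])^2)
  }
}

#' Swarm-optimizer configuration
#'
#' Defaults follow standard practice for swarm-based force-field fitting:
#' cognitive/social coefficients 2.0, inertia decaying linearly 0.9 -> 0.4,
#' Gaussian respawn of the worst-performing fifth of the swarm with scale
#' 0.1 of the bound range, and periodic Nelder-Mead polishing.
#'
#' @param n_agents Number of swarm members (>= 2).
#' @param c1,c2 Cognitive (personal-best) and social (global-best)
#'   acceleration coefficients.
#' @param omega_start,omega_end Initial and final inertia factors.
#' @param gamma Gaussian mutation scale (fraction of each bound range).
#' @param respawn_fraction Fraction of worst agents respawned each
#'   iteration (in `[0, 1)`).
#' @param polish_every Nelder-Mead polish cadence in iterations (0 never).
#' @param max_iters Iteration budget.
#' @param seed Integer RNG seed.
#' @return A list of class `reax_swarmconfig`.
#' @export
swarm_config <- function(n_agents = 20, c1 = 2.0, c2 = 2.0,
                         omega_start = 0.9, omega_end = 0.4, gamma = 0.1,
                         respawn_fraction = 0.2, polish_every = 20,
                         max_iters = 200, seed = 1) {
  if (n_agents < 2) stop("`n_agents` must be at least 2", call. = FALSE)
  if (!(omega_end > 0 && omega_end <= omega_start)) {
    stop("need 0 < omega_end <= omega_start", call. = FALSE)
  }
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (respawn_fraction < 0 || respawn_fraction >= 1) {
    stop("`respawn_fraction` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      n_agents = n_agents, c1 = c1, c2 = c2, omega_start = omega_start,
      omega_end = omega_end, gamma = gamma,
      respawn_fraction = respawn_fraction, polish_every = polish_every,
      max_iters = max_iters, seed = seed
    ),
    class = "reax_swarmconfig"
  )
}

clip_to <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Nelder-Mead polish of a parameter vector
#'
#' Local simplex minimization from `start`; bounds are respected by
#' clipping candidate points before evaluation. Never returns a point worse
#' than the start.
#'
#' @param cost_fn Function of a parameter vector returning a scalar cost.
#' @param start Start vector (within bounds).
#' @param lower,upper Bound vectors.
#' @param maxit Simplex iteration cap.
#' @return List with `par` and `value`.
#' @export
polish_nelder_mead <- function(cost_fn, start, lower, upper, maxit = 200) {
  f0 <- tryCatch(cost_fn(start), error = function(e) NULL)
  if (is.null(f0)) {
    return(list(par = start, value = Inf))
  }
  wrapped <- function(x) cost_fn(clip_to(x, lower, upper))
  res <- tryCatch(
    suppressWarnings(stats::optim(start, wrapped,
      method = "Nelder-Mead",
      control = list(maxit = maxit)
    )),
    error = function(e) NULL
  )
  if (is.null(res)) {
    return(list(par = start, value = f0))
  }
  par <- clip_to(res$par, lower, upper)
  val <- cost_fn(par)
  if (val <= f0) list(par = par, value = val) else list(par = start, value = f0)
}

#' Bound-constrained particle-swarm minimization
#'
#' Inertia-weighted global-best PSO with cognitive/social terms, linear
#' inertia decay, velocity clamping at half the bound range, Gaussian
#' respawn of the worst-performing agents around the global best
#' (per-dimension sigma `gamma * (upper - lower)`), and periodic
#' Nelder-Mead polishing of every agent. With `respawn_fraction = 0` and
#' `polish_every = 0` this reduces to canonical gbest PSO.
#'
#' @param cost_fn Function of a parameter vector returning a scalar cost.
#' @param lower,upper Numeric bound vectors.
#' @param cfg A [swarm_config()].
#' @return List with `par`, `value`, and `history` (tibble with columns
#'   `iteration`, `best_cost`).
#' @export
pso_optimize <- function(cost_fn, lower, upper, cfg = swarm_config()) {
  nd <- length(lower)
  stopifnot(length(upper) == nd, all(lower < upper))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  na <- cfg$n_agents
  rng <- upper - lower
  vmax <- 0.5 * rng
  X <- matrix(stats::runif(na * nd), na, nd) * rep(rng, each = na) +
    rep(lower, each = na)
  V <- matrix(0, na, nd)
  cost <- apply(X, 1, cost_fn)
  pbest_x <- X
  pbest_c <- cost
  gi <- which.min(cost)
  gbest_x <- X[gi, ]
  gbest_c <- cost[gi]
  hist_cost <- numeric(cfg$max_iters)

  n_respawn <- floor(cfg$respawn_fraction * na)
  for (it in seq_len(cfg$max_iters)) {
    w <- if (cfg$max_iters > 1) {
      cfg$omega_start + (cfg$omega_end - cfg$omega_start) * (it - 1) /
        (cfg$max_iters - 1)
    } else {
      cfg$omega_start
    }
    r1 <- matrix(stats::runif(na * nd), na, nd)
    r2 <- matrix(stats::runif(na * nd), na, nd)
    V <- w * V + cfg$c1 * r1 * (pbest_x - X) +
      cfg$c2 * r2 * (matrix(gbest_x, na, nd, byrow = TRUE) - X)
    V <- pmin(pmax(V, matrix(-vmax, na, nd, byrow = TRUE)),
      matrix(vmax, na, nd, byrow = TRUE)
    )
    X <- X + V
    X <- pmin(pmax(X, matrix(lower, na, nd, byrow = TRUE)),
      matrix(upper, na, nd, byrow = TRUE)
    )
    cost <- apply(X, 1, cost_fn)

    improved <- cost < pbest_c
    pbest_x[improved, ] <- X[improved, , drop = FALSE]
    pbest_c[improved] <- cost[improved]
    bi <- which.min(pbest_c)
    if (pbest_c[bi] < gbest_c) {
      gbest_c <- pbest_c[bi]
      gbest_x <- pbest_x[bi, ]
    }

    if (n_respawn > 0) {
      ord <- order(cost, decreasing = TRUE)
      worst <- setdiff(ord, which.min(cost))[seq_len(n_respawn)]
      for (a in worst) {
        X[a, ] <- clip_to(
          gbest_x + stats::rnorm(nd, sd = cfg$gamma * rng),
          lower, upper
        )
        V[a, ] <- 0
        cost[a] <- cost_fn(X[a, ])
        if (cost[a] < pbest_c[a]) {
          pbest_c[a] <- cost[a]
          pbest_x[a, ] <- X[a, ]
          if (cost[a] < gbest_c) {
            gbest_c <- cost[a]
            gbest_x <- X[a, ]
          }
        }
      }
    }

    if (cfg$polish_every > 0 && it %% cfg$polish_every == 0) {
      for (a in seq_len(na)) {
        pol <- polish_nelder_mead(cost_fn, X[a, ], lower, upper)
        X[a, ] <- pol$par
        cost[a] <- pol$value
        if (cost[a] < pbest_c[a]) {
          pbest_c[a] <- cost[a]
          pbest_x[a, ] <- X[a, ]
          if (cost[a] < gbest_c) {
            gbest_c <- cost[a]
            gbest_x <- X[a, ]
          }
        }
      }
    }
    hist_cost[it] <- gbest_c
  }
  list(
    par = gbest_x, value = gbest_c,
    history = tibble::tibble(
      iteration = seq_len(cfg$max_iters),
      best_cost = hist_cost
    )
  )
}

#' Train force-field parameters with the swarm optimizer
#'
#' Minimizes [evaluate_cost()] over the masked parameters.
#'
#' @param ff_template A [reax_forcefield] providing all unmasked parameters.
#' @param mask A [parameter_mask()].
#' @param trainset A [reax_trainset].
#' @param cfg A [swarm_config()].
#' @param stage Training stage passed to [evaluate_cost()].
#' @param weight_convention Weight convention passed to [evaluate_cost()].
#' @return Object of class `reax_swarm_fit`: fitted `forcefield`, `par`,
#'   `value` (final cost), `history`, plus the mask and config.
#' @export
train_swarm <- function(ff_template, mask, trainset, cfg = swarm_config(),
                        stage = "all", weight_convention = "multiply") {
  cost_fn <- function(p) {
    evaluate_cost(p, trainset, ff_template, mask,
      stage = stage,
      weight_convention = weight_convention
    )
  }
  res <- pso_optimize(cost_fn, mask$lower, mask$upper, cfg)
  structure(
    list(
      forcefield = mask_apply(ff_template, mask, res$par),
      par = res$par, value = res$value, history = res$history,
      mask = mask, config = cfg, stage = stage
    ),
    class = "reax_swarm_fit"
  )
}

#' @export
print.reax_swarm_fit <- function(x, ...) {
  cat(
    "<reax_swarm_fit> ", nrow(x$mask), " parameters, final cost ",
    format(x$value, digits = 6), " after ",
    nrow(x$history), " iterations\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a swarm fit: fitted parameters
#'
#' @param x A `reax_swarm_fit`.
#' @param ... Unused.
#' @return Tibble with one row per trained parameter (section, key, param,
#'   bounds, fitted estimate).
#' @export
tidy.reax_swarm_fit <- function(x, ...) {
  tibble::tibble(
    section = x$mask$section, key = x$mask$key, param = x$mask$param,
    lower = x$mask$lower, upper = x$mask$upper, estimate = x$par
  )
}

#' Glance at a swarm fit
#'
#' @param x A `reax_swarm_fit`.
#' @param ... Unused.
#' @return One-row tibble with the final cost and run summary.
#' @export
glance.reax_swarm_fit <- function(x, ...) {
  tibble::tibble(
    final_cost = x$value, iterations = nrow(x$history),
    n_agents = x$config$n_agents, n_parameters = nrow(x$mask),
    stage = x$stage
  )
}
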