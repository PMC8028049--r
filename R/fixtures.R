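# Deterministic synthetic inputs: a hand-designed plausible H/O/Fe/S force
# field, reference molecular geometries, solvated boxes and synthetic
# training sets. Everything here is synthetic - parameter magnitudes are
# physically plausible for aqueous iron-sulfur chemistry but are not fitted
# to any quantum-mechanical data.

toy_general <- function() {
  g <- c(
    p_boc1 = 50.0000, p_boc2 = 9.5469, p_coa2 = 26.5405, p_trip4 = 1.7224,
    p_trip3 = 6.8702, k_c2 = 60.4850, p_ovun6 = 1.0588, p_trip2 = 4.6000,
    p_ovun7 = 12.1176, p_ovun8 = 13.3056, p_trip1 = -70.5044, swa = 0.0000,
    swb = 10.0000, nu14 = 2.8793, p_val6 = 33.8667, p_lp1 = 6.0891,
    p_val9 = 1.0563, p_val10 = 2.0384, nu19 = 6.1431, p_pen2 = 6.9290,
    p_pen3 = 0.3989, p_pen4 = 3.9954, nu23 = -2.4837, p_tor2 = 5.7796,
    p_tor3 = 10.0000, p_tor4 = 1.9487, nu27 = -1.2327, p_cot2 = 2.1645,
    p_vdw1 = 1.5591, bo_cutoff_x100 = 0.1000, p_coa4 = 2.1365,
    p_ovun4 = 0.6991, p_ovun3 = 50.0000, p_val8 = 1.8512, nu35 = 0.5003,
    nu36 = 20.0000, nu37 = 5.0000, nu38 = 0.0000, p_coa3 = 2.6962
  )
  g
}

toy_atom_rows <- function() {
  # columns follow ATOM_PARAM_NAMES
  rows <- list(
    H = c(
      0.8930, 1, 1.0080, 1.3550, 0.0930, 0.8203, -0.1000, 1,
      8.2230, 33.2894, 1, 0.0000, 0, 3.7248, 9.6093, 1,
      -0.1000, 0.0000, 121.1250, 3.0408, 2.4197, 0.0003, 1.0698, 0,
      -19.4571, 4.2733, 1.0338, 1, 2.8793, 0, 0, 0
    ),
    O = c(
      1.2450, 2, 15.9990, 2.3890, 0.1000, 1.0898, 1.0548, 6,
      9.7300, 13.8449, 4, 37.5000, 0, 8.5000, 8.3122, 2,
      0.9049, 0.4056, 59.0626, 3.5027, 0.7640, 0.0021, 0.9745, 0,
      -3.5500, 2.9000, 1.0493, 4, 2.9225, 0, 0, 0
    ),
    Fe = c(
      1.9506, 3, 55.8450, 2.0990, 0.1181, 0.4744, -1.0000, 3,
      10.1260, 2.6084, 3, 0.0000, 0, 1.7785, 8.6281, 0,
      -1.0000, 0.0000, 66.4838, 2.6500, 0.1780, 0.0860, 1.0000, 0,
      -16.0573, 2.6997, 1.0000, 3, 2.5791, 0, 0, 0
    ),
    S = c(
      1.8328, 2, 32.0600, 2.0677, 0.2099, 0.7530, 1.6468, 6,
      9.9575, 4.9055, 2.2000, 30.0000, 0, 6.5745, 8.2545, 2,
      -1.0000, 3.4994, 71.1843, 8.5146, 22.1978, 0.0003, 1.0000, 0,
      -10.0773, 2.7000, 1.0000, 6.2998, 2.8802, 0, 0, 0
    )
  )
  rows
}

toy_bond_rows <- function() {
  # columns follow BOND_PARAM_NAMES:
  # De_s De_p De_pp p_be1 p_bo5 v13corr p_bo6 p_ovun1
  # p_be2 p_bo3 p_bo4 nu12 p_bo1 p_bo2 ovc nu16
  list(
    "H-H" = c(
      153.3934, 0, 0, -0.4600, 0, 1, 6.0000, 0.7300,
      6.2500, 1.0000, 1.0000, 0, -0.0790, 6.0552, 1, 0
    ),
    "H-O" = c(
      160.0000, 0, 0, -0.5725, 0, 1, 6.0000, 0.5626,
      1.1150, 1.0000, 1.0000, 0, -0.0920, 4.2790, 1, 0
    ),
    "O-O" = c(
      142.2858, 145.0000, 50.8293, 0.2506, -0.1000, 1, 29.7503, 0.6051,
      0.3451, -0.1055, 9.0000, 0, -0.1225, 5.5000, 1, 0
    ),
    "H-S" = c(
      90.0000, 0, 0, -0.5000, 0, 1, 6.0000, 0.5000,
      1.5000, 1.0000, 1.0000, 0, -0.0800, 5.0000, 1, 0
    ),
    "O-S" = c(
      100.0000, 80.0000, 0, -0.3000, 0, 1, 6.0000, 0.4000,
      0.6000, -0.1200, 8.0000, 0, -0.1100, 5.2000, 1, 0
    ),
    "S-S" = c(
      86.8868, 70.0000, 0, -0.5000, 0, 1, 6.0000, 0.2800,
      0.2799, -0.1805, 7.0893, 0, -0.0950, 6.4598, 1, 0
    ),
    "Fe-Fe" = c(
      41.4611, 0, 0, 0.2931, 0, 1, 6.0000, 0.2682,
      1.0000, 1.0000, 1.0000, 0, -0.0512, 6.8013, 1, 0
    ),
    "Fe-O" = c(
      80.0000, 0, 0, -0.3000, 0, 1, 6.0000, 0.3000,
      0.8000, 1.0000, 1.0000, 0, -0.4100, 2.8100, 1, 0
    ),
    "Fe-S" = c(
      80.0000, 0, 0, -0.2500, 0, 1, 6.0000, 0.3500,
      0.5000, 1.0000, 1.0000, 0, -0.0850, 5.5000, 1, 0
    ),
    "Fe-H" = c(
      45.0000, 0, 0, -0.3000, 0, 1, 6.0000, 0.3000,
      1.0000, 1.0000, 1.0000, 0, -0.0700, 5.5000, 1, 0
    )
  )
}

toy_offdiag_rows <- function() {
  # epsilon r_vdw alpha r_s r_p r_pp  (r_vdw stored as radius; pair value 2x)
  list(
    "H-O" = c(0.0283, 1.2885, 10.9190, 0.9215, -1.0000, -1.0000),
    "Fe-O" = c(0.0800, 1.7500, 9.5000, 1.4000, -1.0000, -1.0000)
  )
}

toy_angle_rows <- function() {
  # theta00 p_val1 p_val2 p_coa1 p_val7 p_pen1 p_val4
  list(
    "H-O-H" = c(85.8000, 9.8453, 2.2720, 0, 2.8635, 0, 1.5800),
    "H-O-O" = c(80.7324, 14.0000, 1.0000, 0, 1.0000, 0, 1.1000),
    "O-O-O" = c(80.0000, 15.0000, 2.0000, 0, 1.0000, 0, 1.5000),
    "Fe-O-H" = c(65.0000, 12.0000, 1.5000, 0, 1.0000, 0, 1.2000),
    "Fe-O-Fe" = c(60.0000, 10.0000, 1.8000, 0, 1.0000, 0, 1.5000),
    "Fe-O-O" = c(70.0000, 10.0000, 1.5000, 0, 1.0000, 0, 1.2000),
    "S-Fe-S" = c(75.0000, 15.0000, 1.5000, 0, 1.0000, 0, 1.3000),
    "O-Fe-S" = c(72.0000, 12.0000, 1.6000, 0, 1.0000, 0, 1.3000),
    "O-Fe-O" = c(70.0000, 12.0000, 1.8000, 0, 1.0000, 0, 1.3000),
    "H-Fe-O" = c(70.0000, 6.0000, 1.5000, 0, 1.0000, 0, 1.2000),
    "H-Fe-S" = c(70.0000, 6.0000, 1.5000, 0, 1.0000, 0, 1.2000),
    "Fe-Fe-S" = c(60.0000, 5.0000, 1.5000, 0, 1.0000, 0, 1.2000),
    "Fe-Fe-O" = c(60.0000, 5.0000, 1.5000, 0, 1.0000, 0, 1.2000),
    "Fe-S-Fe" = c(70.0000, 16.0000, 1.5000, 0, 1.0000, 0, 1.2000),
    "Fe-S-H" = c(75.0000, 10.0000, 1.8000, 0, 1.0000, 0, 1.2000),
    "Fe-S-S" = c(72.0000, 10.0000, 1.6000, 0, 1.0000, 0, 1.2000),
    "H-S-H" = c(85.0000, 12.0000, 2.0000, 0, 1.0000, 0, 1.5000),
    "H-S-S" = c(78.0000, 10.0000, 1.8000, 0, 1.0000, 0, 1.5000),
    "S-S-S" = c(75.0000, 12.0000, 1.6000, 0, 1.0000, 0, 1.4000),
    "H-O-S" = c(78.0000, 12.0000, 1.6000, 0, 1.0000, 0, 1.3000),
    "O-S-O" = c(78.0000, 12.0000, 1.6000, 0, 1.0000, 0, 1.3000)
  )
}

toy_torsion_rows <- function() {
  # V1 V2 V3 p_tor1 p_cot1
  list(
    "X-O-O-X" = c(0.0000, 10.0000, 0.0000, -2.0000, 0.0000, 0, 0),
    "X-Fe-S-X" = c(0.0000, 5.0000, 0.0000, -2.0000, 0.0000, 0, 0),
    "X-Fe-O-X" = c(0.0000, 2.0000, 0.0000, -2.0000, 0.0000, 0, 0),
    "X-S-S-X" = c(0.0000, 5.0000, 0.0000, -2.0000, 0.0000, 0, 0),
    "X-O-S-X" = c(0.0000, 4.0000, 0.0000, -2.0000, 0.0000, 0, 0),
    "X-Fe-Fe-X" = c(0.0000, 2.0000, 0.0000, -2.0000, 0.0000, 0, 0)
  )
}

toy_hbond_rows <- function() {
  # r_hb p_hb1 p_hb2 p_hb3  (donor, hydrogen, acceptor)
  list(
    "O-H-O" = c(2.1200, -3.5800, 1.4500, 19.5000),
    "O-H-S" = c(2.5000, -2.0000, 1.4500, 19.5000),
    "S-H-O" = c(2.5000, -2.0000, 1.4500, 19.5000),
    "S-H-S" = c(2.8000, -1.5000, 1.4500, 19.5000)
  )
}

#' Construct the synthetic toy force field
#'
#' A complete, physically plausible H/O/Fe/S parameter set intended for
#' testing and synthetic-data generation (it is not fitted to reference
#' data). All blocks of the fixed-format layout are populated; `overrides`
#' can replace any single parameter.
#'
#' @param elements Subset of `c("H", "O", "Fe", "S")`.
#' @param overrides Optional list of overrides, each a list with fields
#'   `section`, `key`, `param`, `value` (see [ff_set_param()]).
#' @return A [reax_forcefield].
#' @export
#' @examples
#' ff <- make_toy_forcefield(c("H", "O"))
#' ff_get_param(ff, "bonds", "H-O", "De_s")
make_toy_forcefield <- function(elements = c("H", "O", "Fe", "S"),
                                overrides = NULL) {
  if (!all(elements %in% REAX_ELEMENTS)) {
    stop("elements must be a subset of {H, O, Fe, S}", call. = FALSE)
  }
  elements <- REAX_ELEMENTS[REAX_ELEMENTS %in% elements]
  arows <- toy_atom_rows()[elements]
  atoms <- as.data.frame(do.call(rbind, arows))
  names(atoms) <- ATOM_PARAM_NAMES
  atoms <- cbind(element = elements, atoms)
  rownames(atoms) <- NULL

  keep_key <- function(key, nsym) {
    parts <- strsplit(key, "-", fixed = TRUE)[[1]]
    all(parts %in% c(elements, "X"))
  }
  build_block <- function(rows, cols, symnames) {
    rows <- rows[vapply(names(rows), keep_key, TRUE, nsym = length(symnames))]
    if (length(rows) == 0) {
      df <- as.data.frame(matrix(numeric(0), 0, length(cols)))
      names(df) <- cols
      sdf <- as.data.frame(matrix(character(0), 0, length(symnames)))
      names(sdf) <- symnames
      return(cbind(sdf, df))
    }
    df <- as.data.frame(do.call(rbind, rows))
    names(df) <- cols
    syms <- do.call(rbind, strsplit(names(rows), "-", fixed = TRUE))
    sdf <- as.data.frame(syms, stringsAsFactors = FALSE)
    names(sdf) <- symnames
    out <- cbind(sdf, df)
    rownames(out) <- NULL
    out
  }
  bonds <- build_block(toy_bond_rows(), BOND_PARAM_NAMES, c("el1", "el2"))
  offdiag <- build_block(toy_offdiag_rows(), OFFDIAG_PARAM_NAMES, c("el1", "el2"))
  angles <- build_block(toy_angle_rows(), ANGLE_PARAM_NAMES, c("el1", "el2", "el3"))
  torsions <- build_block(
    toy_torsion_rows(), TORSION_PARAM_NAMES,
    c("el1", "el2", "el3", "el4")
  )
  hbonds <- build_block(
    toy_hbond_rows(), HBOND_PARAM_NAMES,
    c("donor", "hydrogen", "acceptor")
  )
  ff <- reax_forcefield(toy_general(), atoms, bonds, offdiag, angles,
    torsions, hbonds,
    header = "reaxkit synthetic H/O/Fe/S force field (toy fixture)"
  )
  if (!is.null(overrides)) {
    for (ov in overrides) {
      ff <- ff_set_param(ff, ov$section, ov$key, ov$param, ov$value)
    }
  }
  ff
}

#' Rigid water monomer geometry
#'
#' O-H 0.9572 Angstrom, H-O-H 104.52 degrees (gas-phase experimental
#' values), oxygen at the origin.
#'
#' @param center Optional length-3 translation applied to all atoms.
#' @return A [reax_structure].
#' @export
water_molecule <- function(center = c(0, 0, 0)) {
  r <- 0.9572
  half <- 104.52 / 2 * DEG2RAD
  coords <- rbind(
    c(0, 0, 0),
    c(r * sin(half), r * cos(half), 0),
    c(-r * sin(half), r * cos(half), 0)
  )
  coords <- sweep(coords, 2, -center)
  reax_structure(c("O", "H", "H"), coords)
}

#' Idealized Fe2S2 cluster, optionally with coordinated waters
#'
#' A planar Fe2S2 rhombus (Fe-S about 2.24 Angstrom) with `n_waters` water
#' ligands distributed over the two Fe sites at the given Fe-O distance,
#' oriented away from the cluster.
#'
#' @param n_waters 0, 2 or 4 coordinated waters.
#' @param fe_o Fe-O coordination distance, Angstrom.
#' @return A [reax_structure]; Fe atoms first, then S, then waters (O,H,H).
#' @export
fe2s2_cluster <- function(n_waters = 0, fe_o = 2.05) {
  a <- 1.35 # half the Fe-Fe distance
  b <- 1.79 # half the S-S distance
  symbols <- c("Fe", "Fe", "S", "S")
  coords <- rbind(
    c(a, 0, 0), c(-a, 0, 0),
    c(0, b, 0), c(0, -b, 0)
  )
  if (!n_waters %in% c(0, 2, 4)) {
    stop("`n_waters` must be 0, 2 or 4", call. = FALSE)
  }
  if (n_waters > 0) {
    # ligand directions per Fe: tetrahedral-ish, tilted out of plane
    dirs <- list(
      c(1, 0.35, 0.8), c(1, -0.35, -0.8),
      c(-1, 0.35, -0.8), c(-1, -0.35, 0.8)
    )
    fe_of <- c(1, 1, 2, 2)
    take <- if (n_waters == 2) c(1, 3) else 1:4
    for (kk in take) {
      dir <- dirs[[kk]]
      dir <- dir / sqrt(sum(dir^2))
      fe <- coords[fe_of[kk], ]
      opos <- fe + fe_o * dir
      w <- water_molecule()
      # orient the water plane perpendicular-ish to the Fe-O axis: rotate
      # the monomer so its C2 axis (+y) points away from Fe
      ref <- c(0, 1, 0)
      axis <- c(
        ref[2] * dir[3] - ref[3] * dir[2],
        ref[3] * dir[1] - ref[1] * dir[3],
        ref[1] * dir[2] - ref[2] * dir[1]
      )
      ang <- acos(pmin(1, pmax(-1, sum(ref * dir))))
      wc <- w$coords
      if (sqrt(sum(axis^2)) > 1e-8) {
        wc <- rotate_about_axis(wc, axis, ang)
      }
      wc <- sweep(wc, 2, -opos)
      symbols <- c(symbols, w$symbols)
      coords <- rbind(coords, wc)
    }
  }
  reax_structure(symbols, coords)
}

#' Specify a solvated box
#'
#' @param cell Orthorhombic cell edge lengths, Angstrom.
#' @param n_waters Number of water molecules to place.
#' @param solute A [reax_structure] placed at the box center (or `NULL`).
#' @param min_separation Minimum intermolecular heavy-atom distance,
#'   Angstrom.
#' @param seed Integer seed controlling jitter and orientations.
#' @return List of class `reax_boxspec`.
#' @export
box_spec <- function(cell, n_waters, solute = NULL, min_separation = 2.0,
                     seed = 1) {
  if (n_waters < 0) stop("`n_waters` must be non-negative", call. = FALSE)
  if (min_separation <= 0) stop("`min_separation` must be positive", call. = FALSE)
  structure(
    list(
      cell = cell, n_waters = n_waters, solute = solute,
      min_separation = min_separation, seed = seed
    ),
    class = "reax_boxspec"
  )
}

#' Build a solvated orthorhombic box
#'
#' Places the solute at the box center and water molecules on a jittered
#' lattice with random (seeded) orientations, rejecting placements with
#' intermolecular heavy-atom contacts below the minimum separation under
#' the minimum-image convention. Deterministic for a fixed seed.
#'
#' @param spec A [box_spec()].
#' @return A periodic [reax_structure]; attribute `density` reports the
#'   water mass density in g/mL.
#' @export
build_solvated_box <- function(spec) {
  cell <- spec$cell
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  symbols <- character(0)
  coords <- matrix(0, 0, 3)
  heavy <- matrix(0, 0, 3) # heavy-atom positions for contact checks
  if (!is.null(spec$solute)) {
    sol <- spec$solute$coords
    sol <- sweep(sol, 2, colMeans(sol))
    sol <- sweep(sol, 2, -cell / 2)
    symbols <- spec$solute$symbols
    coords <- sol
    heavy <- sol[spec$solute$symbols != "H", , drop = FALSE]
  }
  if (spec$n_waters > 0) {
    # lattice sized to hold the requested count
    ncell <- ceiling(spec$n_waters^(1 / 3) * cell / (prod(cell))^(1 / 3))
    ncell <- pmax(ncell, 1)
    while (prod(ncell) < spec$n_waters * 2) {
      ncell[which.min(ncell)] <- ncell[which.min(ncell)] + 1
    }
    grid <- as.matrix(expand.grid(
      x = (seq_len(ncell[1]) - 0.5) / ncell[1] * cell[1],
      y = (seq_len(ncell[2]) - 0.5) / ncell[2] * cell[2],
      z = (seq_len(ncell[3]) - 0.5) / ncell[3] * cell[3]
    ))
    grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
    placed <- 0
    gi <- 0
    attempts <- 0
    max_attempts <- nrow(grid) * 8
    while (placed < spec$n_waters) {
      attempts <- attempts + 1
      if (attempts > max_attempts) {
        stop("packing failure: could not place ", spec$n_waters,
          " waters at min_separation ", spec$min_separation,
          call. = FALSE
        )
      }
      gi <- gi %% nrow(grid) + 1
      site <- grid[gi, ] + stats::runif(3, -0.35, 0.35)
      # random orientation
      qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
      R <- qr.Q(qr_)
      if (det(R) < 0) R[, 1] <- -R[, 1]
      w <- water_molecule()
      wc <- w$coords %*% t(R)
      wc <- sweep(wc, 2, -site)
      op <- wc[1, , drop = FALSE]
      if (nrow(heavy) > 0) {
        dmin <- min(sqrt(rowSums(min_image_vec(
          sweep(heavy, 2, op[1, ]), cell
        )^2)))
        if (dmin < spec$min_separation) next
      }
      symbols <- c(symbols, w$symbols)
      coords <- rbind(coords, wc)
      heavy <- rbind(heavy, op)
      placed <- placed + 1
    }
  }
  out <- reax_structure(symbols, coords, cell = cell)
  water_mass_g <- spec$n_waters * 18.01528 / 6.02214076e23
  vol_ml <- prod(cell) * 1e-24
  attr(out, "density") <- water_mass_g / vol_ml
  out
}

#' Generate a synthetic training set from a known force field
#'
#' Builds internal-coordinate scans for the supplied geometries, evaluates
#' the reference energies (and equilibrium charges) with `ff_truth`, and
#' assembles a [reax_trainset] whose references are, up to optional Gaussian
#' noise, exactly reproducible by `ff_truth` - enabling parameter-recovery
#' experiments.
#'
#' @param ff_truth The generating [reax_forcefield].
#' @param geometries Named list of equilibrium [reax_structure]s.
#' @param scans Named list (same names) of lists of [scan_spec()]s.
#' @param noise_sd Gaussian noise SD added to reference energies (kcal/mol;
#'   0 for noise-free references).
#' @param seed Integer seed for the noise.
#' @param include_charges Add per-atom charge entries for each equilibrium
#'   geometry.
#' @param validation_clusters Passed to [assemble_training_set()].
#' @return A [reax_trainset].
#' @export
make_synthetic_trainset <- function(ff_truth, geometries, scans,
                                    noise_sd = 0, seed = 1,
                                    include_charges = FALSE,
                                    validation_clusters = character()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  tab <- ff_tables(ff_truth)
  energy_of <- function(s) {
    reax_eval(s, NULL, tables = tab, want_forces = FALSE)$total
  }
  scan_results <- list()
  for (cl in names(geometries)) {
    eq <- geometries[[cl]]
    e_eq <- energy_of(eq)
    distorted <- list()
    for (sp in scans[[cl]]) {
      distorted <- c(distorted, generate_scan(eq, sp))
    }
    reference <- vapply(distorted, function(d) energy_of(d) - e_eq, 0)
    if (noise_sd > 0) {
      reference <- reference + stats::rnorm(length(reference), sd = noise_sd)
    }
    scan_results[[length(scan_results) + 1]] <- list(
      cluster = cl, equilibrium = eq, distorted = distorted,
      reference = reference
    )
  }
  reference_charges <- NULL
  if (include_charges) {
    reference_charges <- lapply(geometries, function(s) {
      equilibrate_charges(s, ff_truth)
    })
  }
  assemble_training_set(scan_results,
    reference_charges = reference_charges,
    validation_clusters = validation_clusters
  )
}
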