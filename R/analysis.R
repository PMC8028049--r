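# Solvation and force-field quality analysis: hydrogen-bond counting,
# trajectory statistics, geometry-deviation reports over symmetry-unique
# internal coordinates, prediction-correlation and partial-charge reports,
# and Fe coordination-state classification.

#' Hydrogen-bond criteria
#'
#' Donor-acceptor cutoff criteria. The angular criterion is applied, by
#' default, to the deviation of the D-H...A arrangement from linearity
#' measured as the angle between the D->H and D->A directions (small =
#' near-linear). `convention = "h_vertex"` instead requires the D-H-A angle
#' at the hydrogen vertex to be at least `180 - angular_max` degrees.
#'
#' @param donor_acceptor_max_distance D...A cutoff, Angstrom.
#' @param angular_max Angular cutoff, degrees (in (0, 180]).
#' @param convention `"deviation"` (default) or `"h_vertex"`.
#' @return List of class `reax_hbond_criteria`.
#' @export
hbond_criteria <- function(donor_acceptor_max_distance = 3.7,
                           angular_max = 20,
                           convention = c("deviation", "h_vertex")) {
  convention <- match.arg(convention)
  if (donor_acceptor_max_distance <= 0) {
    stop("distance cutoff must be positive", call. = FALSE)
  }
  if (angular_max <= 0 || angular_max > 180) {
    stop("`angular_max` must be in (0, 180]", call. = FALSE)
  }
  structure(
    list(
      donor_acceptor_max_distance = donor_acceptor_max_distance,
      angular_max = angular_max, convention = convention
    ),
    class = "reax_hbond_criteria"
  )
}

min_image_vec <- function(d, cell) {
  if (is.null(cell)) {
    return(d)
  }
  for (k in 1:3) d[, k] <- d[, k] - cell[k] * round(d[, k] / cell[k])
  d
}

pair_vectors <- function(x, from, to, cell) {
  d <- x[to, , drop = FALSE] - x[from, , drop = FALSE]
  min_image_vec(d, cell)
}

#' Count hydrogen bonds in a frame
#'
#' Counts D-H...A arrangements with the D...A distance and angular deviation
#' inside the criteria. Covalent D-H assignment uses a distance heuristic
#' (nearest donor-element atom within `h_max_bond`). When `cluster` is
#' non-empty, only bonds with exactly one partner (donor or acceptor) in the
#' cluster are counted; minimum-image distances are used under periodic
#' boundary conditions.
#'
#' @param frame A [reax_structure].
#' @param cluster Integer atom indices of the solute cluster (possibly
#'   empty, in which case all D-H...A bonds are counted).
#' @param criteria A [hbond_criteria()].
#' @param donor_elements Elements acting as donors/acceptors.
#' @param h_max_bond Covalent D-H assignment cutoff, Angstrom.
#' @return Integer hydrogen-bond count.
#' @export
count_hbonds <- function(frame, cluster = integer(),
                         criteria = hbond_criteria(),
                         donor_elements = c("O", "S"), h_max_bond = 1.3) {
  x <- frame$coords
  cell <- frame$cell
  hs <- which(frame$symbols == "H")
  da <- which(frame$symbols %in% donor_elements)
  if (length(hs) == 0 || length(da) == 0) {
    warning("empty donor/acceptor selection; hydrogen-bond count is 0",
      call. = FALSE
    )
    return(0L)
  }
  # assign each H to its nearest donor-element atom within the bond cutoff
  count <- 0L
  in_cluster <- rep(FALSE, n_atoms(frame))
  in_cluster[cluster] <- TRUE
  for (h in hs) {
    dvec <- pair_vectors(x, rep(h, length(da)), da, cell)
    dd <- sqrt(rowSums(dvec^2))
    k <- which.min(dd)
    if (dd[k] > h_max_bond) next
    don <- da[k]
    u_dh <- -dvec[k, ] # donor -> H
    acc <- da[da != don]
    if (length(acc) == 0) next
    davec <- pair_vectors(x, rep(don, length(acc)), acc, cell)
    dda <- sqrt(rowSums(davec^2))
    ok_d <- dda <= criteria$donor_acceptor_max_distance
    if (!any(ok_d)) next
    for (m in which(ok_d)) {
      a <- acc[m]
      if (length(cluster) > 0 && (in_cluster[don] == in_cluster[a])) next
      if (criteria$convention == "deviation") {
        cosang <- sum(u_dh * davec[m, ]) /
          (sqrt(sum(u_dh^2)) * dda[m])
        dev <- acos(pmin(1, pmax(-1, cosang))) * RAD2DEG
        if (dev <= criteria$angular_max) count <- count + 1L
      } else {
        # angle at the hydrogen vertex
        v_hd <- -u_dh
        v_ha <- min_image_vec(rbind(x[a, ] - x[h, ]), cell)[1, ]
        cosang <- sum(v_hd * v_ha) / (sqrt(sum(v_hd^2)) * sqrt(sum(v_ha^2)))
        ang <- acos(pmin(1, pmax(-1, cosang))) * RAD2DEG
        if (ang >= 180 - criteria$angular_max) count <- count + 1L
      }
    }
  }
  count
}

fold_dihedral <- function(deg) abs(((deg + 180) %% 360) - 180)

frame_structure <- function(traj, k) {
  reax_structure(traj$symbols, traj$frames[[k]]$positions, cell = traj$cell)
}

#' Time-averaged structural statistics over a trajectory window
#'
#' Computes per-frame values of named coordinates and the cluster-water
#' hydrogen-bond count, then reports the mean and population standard
#' deviation over the frames inside the window. Distance definitions may
#' pool several symmetry-equivalent atom pairs: the per-frame value is the
#' mean over the pooled pairs. Dihedrals are folded to `[0, 180]` degrees.
#'
#' @param traj A [reax_trajectory].
#' @param window Length-2 time range (fs) analyzed, inclusive.
#' @param distances Named list; each element is a list of atom-index pairs
#'   pooled into one reported distance.
#' @param dihedrals Named list of length-4 atom-index vectors.
#' @param hbonds `NULL`, or a list with elements `cluster` (atom indices)
#'   and optionally `criteria` (a [hbond_criteria()]).
#' @return Tibble of class `reax_trajstats` with columns `quantity`,
#'   `mean`, `sd`, `n_frames`.
#' @export
trajectory_statistics <- function(traj, window = NULL, distances = list(),
                                  dihedrals = list(), hbonds = NULL) {
  times <- trajectory_times(traj)
  if (is.null(window)) window <- range(times)
  sel <- which(times >= window[1] & times <= window[2])
  if (length(sel) == 0) stop("empty analysis window", call. = FALSE)
  n <- length(traj$symbols)
  check_idx <- function(idx) {
    if (any(idx < 1 | idx > n)) stop("named atom index out of range", call. = FALSE)
  }
  rows <- list()
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

  for (nm in names(distances)) {
    pairs <- distances[[nm]]
    vals <- vapply(sel, function(k) {
      x <- traj$frames[[k]]$positions
      mean(vapply(pairs, function(p) {
        check_idx(p)
        sqrt(sum(min_image_vec(rbind(x[p[2], ] - x[p[1], ]), traj$cell)^2))
      }, 0))
    }, 0)
    rows[[length(rows) + 1]] <- tibble::tibble(
      quantity = nm, mean = mean(vals), sd = pop_sd(vals),
      n_frames = length(sel)
    )
  }
  for (nm in names(dihedrals)) {
    idx <- dihedrals[[nm]]
    check_idx(idx)
    vals <- vapply(sel, function(k) {
      s <- frame_structure(traj, k)
      fold_dihedral(measure_coordinate(s, idx))
    }, 0)
    rows[[length(rows) + 1]] <- tibble::tibble(
      quantity = nm, mean = mean(vals), sd = pop_sd(vals),
      n_frames = length(sel)
    )
  }
  if (!is.null(hbonds)) {
    crit <- hbonds$criteria
    if (is.null(crit)) crit <- hbond_criteria()
    vals <- vapply(sel, function(k) {
      as.numeric(count_hbonds(frame_structure(traj, k),
        cluster = hbonds$cluster, criteria = crit
      ))
    }, 0)
    rows[[length(rows) + 1]] <- tibble::tibble(
      quantity = "n_hbonds", mean = mean(vals), sd = pop_sd(vals),
      n_frames = length(sel)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("reax_trajstats", class(out))
  out
}

## ---- symmetry-unique internal coordinates --------------------------------

topology_graph <- function(s) {
  adj <- connectivity(s)
  edges <- list()
  for (i in seq_along(adj)) {
    for (j in adj[[i]]) if (j > i) edges[[length(edges) + 1]] <- c(i, j)
  }
  list(adj = adj, edges = edges)
}

enumerate_internal_coords <- function(adj) {
  n <- length(adj)
  bonds <- list()
  angles <- list()
  torsions <- list()
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      if (j > i) bonds[[length(bonds) + 1]] <- c(i, j)
      for (k in adj[[j]]) {
        if (k == i) next
        if (k > i) angles[[length(angles) + 1]] <- c(i, j, k)
        for (l in adj[[k]]) {
          if (l == j || l == i) next
          key_fwd <- c(i, j, k, l)
          if (i < l || (i == l)) {
            torsions[[length(torsions) + 1]] <- key_fwd
          }
        }
      }
    }
  }
  # deduplicate torsions under reversal
  if (length(torsions) > 0) {
    canon <- vapply(torsions, function(tq) {
      rv <- rev(tq)
      paste(if (paste(tq, collapse = ",") < paste(rv, collapse = ",")) tq else rv,
        collapse = ","
      )
    }, "")
    torsions <- torsions[!duplicated(canon)]
  }
  list(bonds = bonds, angles = angles, torsions = torsions)
}

# orbits of internal coordinates under the automorphism group of the
# element-coloured bond topology graph (coordinates equivalent by symmetry
# are counted once)
symmetry_unique_coords <- function(s) {
  tg <- topology_graph(s)
  coords <- enumerate_internal_coords(tg$adj)
  n <- n_atoms(s)
  if (length(tg$edges) == 0) {
    return(coords)
  }
  el <- unlist(tg$edges)
  gr <- igraph::graph_from_edgelist(matrix(el, ncol = 2, byrow = TRUE),
    directed = FALSE
  )
  gr <- igraph::add_vertices(gr, max(0, n - igraph::vcount(gr)))
  colors <- as.integer(factor(s$symbols))
  gens <- tryCatch(
    igraph::automorphism_group(gr, colors = colors),
    error = function(e) list()
  )
  gens <- lapply(gens, as.integer)
  if (length(gens) == 0) {
    return(coords)
  }
  canon_key <- function(idx) {
    rv <- rev(idx)
    a <- paste(idx, collapse = ",")
    b <- paste(rv, collapse = ",")
    if (a < b) a else b
  }
  orbit_reps <- function(lst) {
    if (length(lst) == 0) {
      return(lst)
    }
    keys <- vapply(lst, canon_key, "")
    assigned <- rep(FALSE, length(lst))
    key_index <- stats::setNames(seq_along(keys), keys)
    reps <- list()
    for (m in seq_along(lst)) {
      if (assigned[m]) next
      # BFS over group generators
      frontier <- list(lst[[m]])
      seen <- canon_key(lst[[m]])
      assigned[m] <- TRUE
      reps[[length(reps) + 1]] <- lst[[m]]
      while (length(frontier) > 0) {
        cur <- frontier[[1]]
        frontier <- frontier[-1]
        for (gp in gens) {
          img <- gp[cur]
          kk <- canon_key(img)
          if (!kk %in% seen) {
            seen <- c(seen, kk)
            frontier[[length(frontier) + 1]] <- img
            hit <- key_index[kk]
            if (!is.na(hit)) assigned[hit] <- TRUE
          }
        }
      }
    }
    reps
  }
  list(
    bonds = orbit_reps(coords$bonds),
    angles = orbit_reps(coords$angles),
    torsions = orbit_reps(coords$torsions)
  )
}

#' Geometry-deviation report over symmetry-unique internal coordinates
#'
#' Compares optimized structures against references: absolute deviations of
#' bond lengths (Angstrom), valence angles and torsion angles (degrees) over
#' the symmetry-unique internal coordinates of the bonded topology
#' (coordinates equivalent under automorphisms of the element-coloured graph
#' are counted once), then per-cluster and aggregate mean and population SD.
#'
#' @param ff_structures Named list of optimized [reax_structure]s.
#' @param qm_structures Named list of reference structures (same names, same
#'   atom ordering).
#' @return List of class `reax_deviation_report` with tibbles `coords`
#'   (every unique coordinate), `by_cluster` and `aggregate`.
#' @export
geometry_deviation_report <- function(ff_structures, qm_structures) {
  if (!setequal(names(ff_structures), names(qm_structures))) {
    stop("structure sets must share cluster names", call. = FALSE)
  }
  rows <- list()
  for (cl in names(ff_structures)) {
    a <- ff_structures[[cl]]
    b <- qm_structures[[cl]]
    if (!identical(a$symbols, b$symbols)) {
      stop("topology mismatch for cluster '", cl, "'", call. = FALSE)
    }
    uniq <- symmetry_unique_coords(b)
    add <- function(lst, type) {
      for (idx in lst) {
        va <- measure_coordinate(a, idx)
        vb <- measure_coordinate(b, idx)
        dev <- if (type == "torsion") {
          # compare folded magnitudes (sign convention-free)
          abs(fold_dihedral(va) - fold_dihedral(vb))
        } else {
          abs(va - vb)
        }
        rows[[length(rows) + 1]] <<- tibble::tibble(
          cluster = cl, type = type,
          indices = paste(idx, collapse = "-"), deviation = dev
        )
      }
    }
    add(uniq$bonds, "bond")
    add(uniq$angles, "angle")
    add(uniq$torsions, "torsion")
  }
  coords <- dplyr::bind_rows(rows)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  by_cluster <- coords |>
    dplyr::group_by(.data$cluster, .data$type) |>
    dplyr::summarise(
      mean = mean(.data$deviation), sd = pop_sd(.data$deviation),
      n = dplyr::n(), .groups = "drop"
    )
  aggregate <- coords |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(
      mean = mean(.data$deviation), sd = pop_sd(.data$deviation),
      n = dplyr::n(), .groups = "drop"
    )
  structure(
    list(coords = coords, by_cluster = by_cluster, aggregate = aggregate),
    class = "reax_deviation_report"
  )
}

#' @export
print.reax_deviation_report <- function(x, ...) {
  cat("<reax_deviation_report>\n")
  print(x$aggregate)
  invisible(x)
}

#' Correlation report of predicted vs reference energies
#'
#' Evaluates every energy entry of a training set under a force field and
#' summarises the correlation per partition (slope, intercept, R squared,
#' signed bias, RMS error). With a single entry in a partition the slope and
#' intercept are reported as `NA`.
#'
#' @param trainset A [reax_trainset].
#' @param ff A [reax_forcefield].
#' @return List of class `reax_correlation_report` with tibbles `pairs`
#'   (`id`, `partition`, `reference`, `predicted`) and `summary`.
#' @export
prediction_correlation_report <- function(trainset, ff) {
  pred <- predict_trainset(trainset, ff)
  e <- trainset$entries
  sel <- which(e$kind == "energy_difference")
  pairs <- tibble::tibble(
    id = e$id[sel], partition = e$partition[sel],
    reference = e$reference[sel], predicted = pred[sel]
  )
  summarise_part <- function(df) {
    if (nrow(df) < 2) {
      return(tibble::tibble(
        slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
        bias = mean(df$predicted - df$reference),
        rmse = sqrt(mean((df$predicted - df$reference)^2)), n = nrow(df)
      ))
    }
    fit <- stats::lm(predicted ~ reference, data = df)
    tibble::tibble(
      slope = stats::coef(fit)[["reference"]],
      intercept = stats::coef(fit)[["(Intercept)"]],
      # a perfect fit is the expected self-consistency outcome here
      r_squared = suppressWarnings(summary(fit)$r.squared),
      bias = mean(df$predicted - df$reference),
      rmse = sqrt(mean((df$predicted - df$reference)^2)), n = nrow(df)
    )
  }
  summary <- pairs |>
    dplyr::group_by(.data$partition) |>
    dplyr::group_modify(~ summarise_part(.x)) |>
    dplyr::ungroup()
  structure(list(pairs = pairs, summary = summary),
    class = "reax_correlation_report"
  )
}

#' @export
print.reax_correlation_report <- function(x, ...) {
  cat("<reax_correlation_report>\n")
  print(x$summary)
  invisible(x)
}

#' Partial-charge comparison report
#'
#' Tabulates EEM charges against per-atom reference charges and summarises
#' the mean absolute error per element.
#'
#' @param structures Named list of [reax_structure]s.
#' @param ff A [reax_forcefield].
#' @param reference_charges Named list (same names) of per-atom reference
#'   charges (e).
#' @return List of class `reax_charge_report` with tibbles `atoms`
#'   (`cluster`, `atom`, `element`, `reference`, `eem`, `error`) and
#'   `by_element` (mean absolute error).
#' @export
charge_report <- function(structures, ff, reference_charges) {
  rows <- list()
  for (cl in names(structures)) {
    s <- structures[[cl]]
    qr <- reference_charges[[cl]]
    if (is.null(qr) || length(qr) != n_atoms(s)) {
      stop("reference charge count mismatch for cluster '", cl, "'",
        call. = FALSE
      )
    }
    qe <- equilibrate_charges(s, ff)
    rows[[length(rows) + 1]] <- tibble::tibble(
      cluster = cl, atom = seq_len(n_atoms(s)), element = s$symbols,
      reference = qr, eem = qe, error = qe - qr
    )
  }
  atoms <- dplyr::bind_rows(rows)
  by_element <- atoms |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(
      mae = mean(abs(.data$error)), n = dplyr::n(),
      .groups = "drop"
    )
  structure(list(atoms = atoms, by_element = by_element),
    class = "reax_charge_report"
  )
}

#' @export
print.reax_charge_report <- function(x, ...) {
  cat("<reax_charge_report>\n")
  print(x$by_element)
  invisible(x)
}

#' Classify Fe coordination states along a trajectory
#'
#' Counts water oxygens within the Fe-O coordination cutoff of each iron
#' site per frame and maps the total to the conventional labels: 3 waters =
#' trigonal, 4 = tetrahedral, 5 = bipyramidal (per Fe site).
#'
#' @param traj A [reax_trajectory].
#' @param fe_indices Indices of the Fe atoms.
#' @param oxygen_indices Indices of candidate coordinating oxygens (default:
#'   all O atoms).
#' @param cutoff Fe-O coordination cutoff, Angstrom.
#' @param window Optional time window (fs).
#' @return Tibble with one row per frame and Fe site: `time`, `fe`,
#'   `n_coordinated`, `state`.
#' @export
coordination_states <- function(traj, fe_indices, oxygen_indices = NULL,
                                cutoff = 2.8, window = NULL) {
  times <- trajectory_times(traj)
  if (is.null(window)) window <- range(times)
  sel <- which(times >= window[1] & times <= window[2])
  if (is.null(oxygen_indices)) {
    oxygen_indices <- which(traj$symbols == "O")
  }
  rows <- list()
  for (k in sel) {
    x <- traj$frames[[k]]$positions
    for (fe in fe_indices) {
      d <- sqrt(rowSums(min_image_vec(
        x[oxygen_indices, , drop = FALSE] -
          matrix(x[fe, ], length(oxygen_indices), 3, byrow = TRUE),
        traj$cell
      )^2))
      nc <- sum(d <= cutoff)
      state <- dplyr::case_when(
        nc <= 2 ~ "undercoordinated",
        nc == 3 ~ "trigonal",
        nc == 4 ~ "tetrahedral",
        nc == 5 ~ "bipyramidal",
        TRUE ~ "overcoordinated"
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        time = times[k], fe = fe, n_coordinated = nc, state = state
      )
    }
  }
  dplyr::bind_rows(rows)
}
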