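# Trajectory container: time-ordered MD frames with positions, velocities,
# instantaneous temperature and an energy breakdown, plus multi-frame
# extended-XYZ persistence.

#' Construct a trajectory object
#'
#' @param symbols Element symbols (constant across frames).
#' @param frames List of frames; each frame is a list with elements `time`
#'   (fs), `positions` (N x 3, Angstrom), `velocities` (N x 3, Angstrom/fs),
#'   `temperature` (K) and `energy` (an energy breakdown as returned by
#'   [compute_energy()], or `NULL`).
#' @param cell Optional orthorhombic cell (Angstrom).
#' @return An object of class `reax_trajectory`.
#' @export
reax_trajectory <- function(symbols, frames, cell = NULL) {
  if (length(frames) < 1) stop("a trajectory needs at least one frame", call. = FALSE)
  times <- vapply(frames, function(f) f$time, 0)
  if (any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  n <- length(symbols)
  ok <- vapply(frames, function(f) nrow(f$positions) == n, TRUE)
  if (!all(ok)) stop("frame atom count is not constant", call. = FALSE)
  structure(list(symbols = symbols, frames = frames, cell = cell),
    class = "reax_trajectory"
  )
}

#' @export
print.reax_trajectory <- function(x, ...) {
  times <- vapply(x$frames, function(f) f$time, 0)
  cat(
    "<reax_trajectory> ", length(x$frames), " frames, ",
    length(x$symbols), " atoms, t = ",
    sprintf("%.3f", times[1]), " .. ", sprintf("%.3f", times[length(times)]),
    " fs\n",
    sep = ""
  )
  invisible(x)
}

#' Times of all trajectory frames
#'
#' @param traj A [reax_trajectory].
#' @return Numeric vector of frame times (fs).
#' @export
trajectory_times <- function(traj) vapply(traj$frames, function(f) f$time, 0)

#' Write a trajectory as multi-frame extended XYZ
#'
#' Each frame's comment line carries `time=` (fs), `temperature=` (K) and
#' `energy=` (total, kcal/mol) annotations; velocities are written as columns
#' 5-7 in Angstrom/fs.
#'
#' @param traj A [reax_trajectory].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  out <- character(0)
  for (f in traj$frames) {
    parts <- character(0)
    if (!is.null(traj$cell)) {
      parts <- c(parts, sprintf(
        'Lattice="%.8f 0.0 0.0 0.0 %.8f 0.0 0.0 0.0 %.8f"',
        traj$cell[1], traj$cell[2], traj$cell[3]
      ))
    }
    etot <- if (!is.null(f$energy)) f$energy$total else NA_real_
    parts <- c(parts, sprintf("time=%.6f", f$time),
      sprintf("temperature=%.6f", f$temperature),
      if (!is.na(etot)) sprintf("energy=%.8f", etot)
    )
    out <- c(out, sprintf("%d", length(traj$symbols)), paste(parts, collapse = " "))
    for (k in seq_along(traj$symbols)) {
      out <- c(out, sprintf(
        "%-2s %16.8f %16.8f %16.8f %14.8f %14.8f %14.8f",
        traj$symbols[k],
        f$positions[k, 1], f$positions[k, 2], f$positions[k, 3],
        f$velocities[k, 1], f$velocities[k, 2], f$velocities[k, 3]
      ))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path Path to a multi-frame extended-XYZ trajectory.
#' @return A [reax_trajectory] (energy breakdowns are reduced to totals).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ln <- 1L
  frames <- list()
  symbols <- NULL
  cell <- NULL
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) {
      ln <- ln + 1L
      next
    }
    n <- as.integer(trimws(lines[ln]))
    ann <- parse_extxyz_comment(lines[ln + 1L])
    if (!is.null(ann$lattice)) cell <- lattice_to_cell(ann$lattice)
    pos <- matrix(0, n, 3)
    vel <- matrix(0, n, 3)
    syms <- character(n)
    for (k in seq_len(n)) {
      toks <- strsplit(trimws(lines[ln + 1L + k]), "\\s+")[[1]]
      syms[k] <- toks[1]
      pos[k, ] <- as.numeric(toks[2:4])
      if (length(toks) >= 7) vel[k, ] <- as.numeric(toks[5:7])
    }
    if (is.null(symbols)) symbols <- syms
    energy <- if (!is.null(ann$energy)) list(total = as.numeric(ann$energy)) else NULL
    frames[[length(frames) + 1L]] <- list(
      time = as.numeric(ann$time),
      positions = pos, velocities = vel,
      temperature = as.numeric(ann$temperature), energy = energy
    )
    ln <- ln + 2L + n
  }
  reax_trajectory(symbols, frames, cell = cell)
}
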