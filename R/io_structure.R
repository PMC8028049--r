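# (Extended) XYZ reading and writing. The extended-XYZ comment line carries
# Lattice="ax 0 0 0 by 0 0 0 cz" for orthorhombic cells and optional
# key=value annotations (total_charge, time, temperature, energy); per-atom
# charges are written as a fourth column when present.

parse_extxyz_comment <- function(comment) {
  out <- list()
  # quoted values first (Lattice="...")
  m <- gregexpr('([A-Za-z_]+)="([^"]*)"', comment)
  for (hit in regmatches(comment, m)[[1]]) {
    key <- sub('^([A-Za-z_]+)=.*$', "\\1", hit)
    val <- sub('^[A-Za-z_]+="([^"]*)"$', "\\1", hit)
    out[[tolower(key)]] <- val
  }
  comment_clean <- gsub('([A-Za-z_]+)="([^"]*)"', "", comment)
  m2 <- gregexpr("([A-Za-z_]+)=([^\\s\"]+)", comment_clean, perl = TRUE)
  for (hit in regmatches(comment_clean, m2)[[1]]) {
    key <- sub("^([A-Za-z_]+)=.*$", "\\1", hit)
    val <- sub("^[A-Za-z_]+=(.*)$", "\\1", hit)
    out[[tolower(key)]] <- val
  }
  out
}

lattice_to_cell <- function(lattice_string) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(lattice_string), "\\s+")[[1]]))
  if (length(v) != 9 || anyNA(v)) {
    stop("malformed Lattice annotation: ", lattice_string, call. = FALSE)
  }
  off <- v[c(2, 3, 4, 6, 7, 8)]
  if (any(abs(off) > 1e-10)) {
    stop("only orthorhombic (diagonal) lattices are supported", call. = FALSE)
  }
  c(v[1], v[5], v[9])
}

#' Read structures from an (extended) XYZ file
#'
#' Supports plain multi-frame XYZ and the extended-XYZ dialect with an
#' orthorhombic `Lattice="ax 0 0 0 by 0 0 0 cz"` annotation and an optional
#' `total_charge=` key in the comment line. A numeric fourth column, when
#' present, is read as per-atom charges.
#'
#' @param path Path to an XYZ/extended-XYZ file.
#' @return List of [reax_structure] objects, one per frame.
#' @seealso [write_structure_file()]
#' @export
read_structure_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) {
      ln <- ln + 1L
      next
    }
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n < 1) {
      stop("XYZ parse error at line ", ln, ": expected an atom count",
        call. = FALSE
      )
    }
    if (ln + 1L + n > length(lines)) {
      stop("XYZ parse error: frame starting at line ", ln,
        " declares ", n, " atoms but the file ends early",
        call. = FALSE
      )
    }
    comment <- lines[ln + 1L]
    ann <- parse_extxyz_comment(comment)
    cell <- if (!is.null(ann$lattice)) lattice_to_cell(ann$lattice) else NULL
    total_charge <- if (!is.null(ann$total_charge)) as.numeric(ann$total_charge) else 0

    syms <- character(n)
    xyz <- matrix(0, n, 3)
    q <- rep(NA_real_, n)
    for (k in seq_len(n)) {
      toks <- strsplit(trimws(lines[ln + 1L + k]), "\\s+")[[1]]
      if (length(toks) < 4) {
        stop("XYZ parse error at line ", ln + 1L + k,
          ": expected 'symbol x y z'",
          call. = FALSE
        )
      }
      syms[k] <- toks[1]
      vals <- suppressWarnings(as.numeric(toks[2:4]))
      if (anyNA(vals)) {
        stop("XYZ parse error at line ", ln + 1L + k, ": non-numeric coordinate",
          call. = FALSE
        )
      }
      xyz[k, ] <- vals
      if (length(toks) >= 5) {
        q[k] <- suppressWarnings(as.numeric(toks[5]))
      }
    }
    charges <- if (!anyNA(q)) q else NULL
    if (!is.null(charges) && is.null(ann$total_charge)) {
      total_charge <- sum(charges)
    }
    frames[[length(frames) + 1L]] <- reax_structure(
      syms, xyz,
      cell = cell, total_charge = total_charge, charges = charges,
      comment = comment
    )
    ln <- ln + 2L + n
  }
  if (length(frames) == 0) stop("no frames found in ", path, call. = FALSE)
  frames
}

structure_comment <- function(s, extra = "") {
  parts <- character(0)
  if (!is.null(s$cell)) {
    parts <- c(parts, sprintf(
      'Lattice="%.8f 0.0 0.0 0.0 %.8f 0.0 0.0 0.0 %.8f"',
      s$cell[1], s$cell[2], s$cell[3]
    ))
  }
  if (abs(s$total_charge) > 0) {
    parts <- c(parts, sprintf("total_charge=%.6f", s$total_charge))
  }
  if (nzchar(extra)) parts <- c(parts, extra)
  paste(parts, collapse = " ")
}

format_xyz_frame <- function(s, comment = NULL) {
  if (is.null(comment)) comment <- structure_comment(s)
  lines <- c(sprintf("%d", n_atoms(s)), comment)
  for (k in seq_len(n_atoms(s))) {
    line <- sprintf(
      "%-2s %16.8f %16.8f %16.8f", s$symbols[k],
      s$coords[k, 1], s$coords[k, 2], s$coords[k, 3]
    )
    if (!is.null(s$charges)) line <- paste0(line, sprintf(" %12.8f", s$charges[k]))
    lines <- c(lines, line)
  }
  lines
}

#' Write structures to an (extended) XYZ file
#'
#' @param structures A [reax_structure] or list of them (multi-frame output).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_file <- function(structures, path) {
  if (inherits(structures, "reax_structure")) structures <- list(structures)
  out <- unlist(lapply(structures, format_xyz_frame))
  writeLines(out, path)
  invisible(path)
}
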