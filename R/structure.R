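# Molecular structure container: element symbols, Cartesian coordinates in
# Angstrom, optional orthorhombic cell, total charge and optional per-atom
# charges.

#' Construct a molecular structure
#'
#' @param symbols Character vector of element symbols.
#' @param coords N x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @param cell Optional numeric length-3 vector of orthorhombic cell edge
#'   lengths (Angstrom); `NULL` for an isolated (non-periodic) system.
#' @param total_charge Total charge in e (default 0).
#' @param charges Optional per-atom charges (e); must sum to `total_charge`.
#' @param comment Optional free-text comment carried through file I/O.
#' @return An object of class `reax_structure`.
#' @export
#' @examples
#' reax_structure(c("O", "H", "H"),
#'   rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
reax_structure <- function(symbols, coords, cell = NULL, total_charge = 0,
                           charges = NULL, comment = "") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  s <- structure(
    list(
      symbols = as.character(symbols), coords = coords, cell = cell,
      total_charge = total_charge, charges = charges, comment = comment
    ),
    class = "reax_structure"
  )
  validate_structure(s)
  s
}

#' Validate a structure object
#'
#' Enforces the container invariants: at least one atom, coordinate matrix of
#' matching shape, strictly positive cell edges when a cell is present, and
#' per-atom charges (when present) summing to the total charge within 1e-8 e.
#'
#' @param s A [reax_structure].
#' @return `s`, invisibly; errors on violation.
#' @export
validate_structure <- function(s) {
  n <- length(s$symbols)
  if (n < 1L) stop("structure must contain at least one atom", call. = FALSE)
  if (!is.matrix(s$coords) || nrow(s$coords) != n || ncol(s$coords) != 3) {
    stop("coords must be an N x 3 matrix matching the symbols", call. = FALSE)
  }
  if (!is.null(s$cell)) {
    if (length(s$cell) != 3 || any(s$cell <= 0)) {
      stop("cell must be three strictly positive edge lengths", call. = FALSE)
    }
  }
  if (!is.null(s$charges)) {
    if (length(s$charges) != n) {
      stop("charges must have one entry per atom", call. = FALSE)
    }
    if (abs(sum(s$charges) - s$total_charge) > 1e-8) {
      stop("per-atom charges do not sum to the total charge", call. = FALSE)
    }
  }
  invisible(s)
}

#' @export
print.reax_structure <- function(x, ...) {
  tab <- table(x$symbols)
  cat(
    "<reax_structure> ", length(x$symbols), " atoms (",
    paste(names(tab), tab, sep = "", collapse = " "), ")",
    if (!is.null(x$cell)) {
      paste0(
        " cell ", paste(sprintf("%.2f", x$cell), collapse = " x "), " A"
      )
    } else {
      " isolated"
    },
    ", charge ", x$total_charge, "\n",
    sep = ""
  )
  invisible(x)
}

#' Number of atoms in a structure
#'
#' @param s A [reax_structure].
#' @return Integer atom count.
#' @export
n_atoms <- function(s) length(s$symbols)

#' Convert a structure to a tibble
#'
#' One row per atom with element, coordinates and (if present) charge.
#'
#' @param x A [reax_structure].
#' @param ... Unused.
#' @return A tibble with columns `atom`, `element`, `x`, `y`, `z` and
#'   optionally `charge`.
#' @export
as_tibble.reax_structure <- function(x, ...) {
  s <- x
  out <- tibble::tibble(
    atom = seq_along(s$symbols), element = s$symbols,
    x = s$coords[, 1], y = s$coords[, 2], z = s$coords[, 3]
  )
  if (!is.null(s$charges)) out$charge <- s$charges
  out
}
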