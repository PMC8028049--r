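# The reax_forcefield S3 container and parameter access helpers.
#
# Layout follows the community fixed-format 'ffield' file: a 39-entry general
# block, 32 parameters per element (4 lines of 8), 16 per bonded pair
# (2 lines of 8), 6 per off-diagonal pair and single-line angle (7), torsion
# (7) and hydrogen-bond (4) records. Slot meanings follow the canonical
# dialect; unused canonical slots are kept so files round-trip exactly.

GENERAL_PARAM_NAMES <- c(
  "p_boc1", "p_boc2", "p_coa2", "p_trip4", "p_trip3", "k_c2", "p_ovun6",
  "p_trip2", "p_ovun7", "p_ovun8", "p_trip1", "swa", "swb", "nu14",
  "p_val6", "p_lp1", "p_val9", "p_val10", "nu19", "p_pen2", "p_pen3",
  "p_pen4", "nu23", "p_tor2", "p_tor3", "p_tor4", "nu27", "p_cot2",
  "p_vdw1", "bo_cutoff_x100", "p_coa4", "p_ovun4", "p_ovun3", "p_val8",
  "nu35", "nu36", "nu37", "nu38", "p_coa3"
)

ATOM_PARAM_NAMES <- c(
  "r_s", "valency", "mass", "r_vdw", "epsilon", "gamma", "r_pi", "valency_e",
  "alpha", "gamma_w", "valency_angle", "p_ovun5", "nu13", "chi", "eta",
  "p_hbond", "r_pipi", "p_lp2", "heat_inc", "p_boc4", "p_boc3", "p_boc5",
  "nu23", "nu24", "p_ovun2", "p_val3", "nu27", "valency_boc", "p_val5",
  "rcore", "ecore", "acore"
)

BOND_PARAM_NAMES <- c(
  "De_s", "De_p", "De_pp", "p_be1", "p_bo5", "v13corr", "p_bo6", "p_ovun1",
  "p_be2", "p_bo3", "p_bo4", "nu12", "p_bo1", "p_bo2", "ovc", "nu16"
)

OFFDIAG_PARAM_NAMES <- c("epsilon", "r_vdw", "alpha", "r_s", "r_p", "r_pp")

ANGLE_PARAM_NAMES <- c(
  "theta00", "p_val1", "p_val2", "p_coa1", "p_val7", "p_pen1", "p_val4"
)

TORSION_PARAM_NAMES <- c("V1", "V2", "V3", "p_tor1", "p_cot1", "nu6", "nu7")

HBOND_PARAM_NAMES <- c("r_hb", "p_hb1", "p_hb2", "p_hb3")

#' Construct a ReaxFF-style force field object
#'
#' Assembles a `reax_forcefield` from its parameter blocks. Most users will
#' obtain force fields from [read_ffield()] or [make_toy_forcefield()]
#' rather than calling this directly.
#'
#' @param general Named numeric vector of the 39 general parameters
#'   (see `GENERAL_PARAM_NAMES` for slot names; `swb` is the nonbonded taper
#'   radius in Angstrom, `bo_cutoff_x100` is 100 x the bond-order cutoff).
#' @param atoms Data frame with one row per element: column `element` plus
#'   the 32 per-element parameters (`ATOM_PARAM_NAMES`).
#' @param bonds Data frame with columns `el1`, `el2` plus the 16 bond
#'   parameters (`BOND_PARAM_NAMES`).
#' @param offdiag Data frame with columns `el1`, `el2` plus the 6
#'   off-diagonal overrides, or `NULL`.
#' @param angles Data frame with columns `el1`, `el2` (center), `el3` plus
#'   the 7 valence-angle parameters, or `NULL`.
#' @param torsions Data frame with columns `el1`..`el4` (`"X"` is a wildcard
#'   terminal) plus the 7 torsion parameters, or `NULL`.
#' @param hbonds Data frame with columns `donor`, `hydrogen`, `acceptor`
#'   plus the 4 hydrogen-bond parameters, or `NULL`.
#' @param header Single descriptive string stored as the file header.
#' @return An object of class `reax_forcefield`.
#' @export
reax_forcefield <- function(general, atoms, bonds, offdiag = NULL,
                            angles = NULL, torsions = NULL, hbonds = NULL,
                            header = "reaxkit force field") {
  stopifnot(length(general) == 39L)
  names(general) <- GENERAL_PARAM_NAMES
  empty <- function(cols, pre) {
    df <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(df) <- cols
    cbind(as.data.frame(matrix(character(0), 0, length(pre),
      dimnames = list(NULL, pre)
    )), df)
  }
  if (is.null(offdiag)) offdiag <- empty(OFFDIAG_PARAM_NAMES, c("el1", "el2"))
  if (is.null(angles)) angles <- empty(ANGLE_PARAM_NAMES, c("el1", "el2", "el3"))
  if (is.null(torsions)) {
    torsions <- empty(TORSION_PARAM_NAMES, c("el1", "el2", "el3", "el4"))
  }
  if (is.null(hbonds)) {
    hbonds <- empty(HBOND_PARAM_NAMES, c("donor", "hydrogen", "acceptor"))
  }
  ff <- structure(
    list(
      header = header, general = general, atoms = atoms, bonds = bonds,
      offdiag = offdiag, angles = angles, torsions = torsions,
      hbonds = hbonds
    ),
    class = "reax_forcefield"
  )
  validate_forcefield(ff)
  ff
}

#' Validate a force field object
#'
#' Checks block shapes, parameter counts and that every bond, off-diagonal,
#' angle, torsion and hydrogen-bond record references a declared element.
#'
#' @param ff A [reax_forcefield].
#' @return `ff`, invisibly; errors on inconsistency.
#' @export
validate_forcefield <- function(ff) {
  els <- ff$atoms$element
  if (length(els) < 1L) stop("force field declares no elements", call. = FALSE)
  if (!all(els %in% REAX_ELEMENTS)) {
    stop(
      "unsupported element(s): ",
      paste(setdiff(els, REAX_ELEMENTS), collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(ATOM_PARAM_NAMES %in% names(ff$atoms))) {
    stop("atom block is missing parameter columns", call. = FALSE)
  }
  if (!all(BOND_PARAM_NAMES %in% names(ff$bonds))) {
    stop("bond block is missing parameter columns", call. = FALSE)
  }
  chk <- function(df, cols, what) {
    for (cc in cols) {
      bad <- setdiff(unique(df[[cc]]), c(els, "X"))
      if (length(bad) > 0) {
        stop(what, " record references undeclared element: ",
          paste(bad, collapse = ", "),
          call. = FALSE
        )
      }
    }
  }
  chk(ff$bonds, c("el1", "el2"), "bond")
  chk(ff$offdiag, c("el1", "el2"), "off-diagonal")
  chk(ff$angles, c("el1", "el2", "el3"), "angle")
  chk(ff$torsions, c("el1", "el2", "el3", "el4"), "torsion")
  chk(ff$hbonds, c("donor", "hydrogen", "acceptor"), "hydrogen-bond")
  invisible(ff)
}

#' @export
print.reax_forcefield <- function(x, ...) {
  cat("<reax_forcefield> ", x$header, "\n", sep = "")
  cat(
    "  elements:", paste(x$atoms$element, collapse = " "),
    "| bonds:", nrow(x$bonds),
    "| off-diag:", nrow(x$offdiag),
    "| angles:", nrow(x$angles),
    "| torsions:", nrow(x$torsions),
    "| hbonds:", nrow(x$hbonds), "\n"
  )
  cat(
    "  taper radius:", x$general[["swb"]], "A",
    "| BO cutoff:", x$general[["bo_cutoff_x100"]] * 0.01, "\n"
  )
  invisible(x)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")

match_pair_row <- function(df, e1, e2) {
  hit <- which((df$el1 == e1 & df$el2 == e2) | (df$el1 == e2 & df$el2 == e1))
  if (length(hit) == 0) NA_integer_ else hit[1]
}

match_angle_row <- function(df, e1, e2, e3) {
  hit <- which(df$el2 == e2 &
    ((df$el1 == e1 & df$el3 == e3) | (df$el1 == e3 & df$el3 == e1)))
  if (length(hit) == 0) NA_integer_ else hit[1]
}

match_torsion_row <- function(df, e1, e2, e3, e4) {
  fwd <- (df$el2 == e2 & df$el3 == e3 &
    (df$el1 == e1 | df$el1 == "X") & (df$el4 == e4 | df$el4 == "X"))
  rev <- (df$el2 == e3 & df$el3 == e2 &
    (df$el1 == e4 | df$el1 == "X") & (df$el4 == e1 | df$el4 == "X"))
  cand <- which(fwd | rev)
  if (length(cand) == 0) {
    return(NA_integer_)
  }
  # prefer fully explicit records over wildcard ones
  explicit <- cand[df$el1[cand] != "X" & df$el4[cand] != "X"]
  if (length(explicit) > 0) explicit[1] else cand[1]
}

parse_ff_key <- function(section, key) {
  if (section == "general") {
    return(key)
  }
  strsplit(key, "-", fixed = TRUE)[[1]]
}

locate_param <- function(ff, section, key, param) {
  parts <- parse_ff_key(section, key)
  switch(section,
    general = {
      if (!param %in% names(ff$general) && !key %in% names(ff$general)) {
        stop("unknown general parameter: ", param, call. = FALSE)
      }
      list(row = NA_integer_, name = if (param %in% names(ff$general)) param else key)
    },
    atoms = {
      row <- match(key, ff$atoms$element)
      if (is.na(row)) stop("unknown element: ", key, call. = FALSE)
      if (!param %in% ATOM_PARAM_NAMES) {
        stop("unknown atom parameter: ", param, call. = FALSE)
      }
      list(row = row, name = param)
    },
    bonds = {
      row <- match_pair_row(ff$bonds, parts[1], parts[2])
      if (is.na(row)) stop("no bond record for ", key, call. = FALSE)
      if (!param %in% BOND_PARAM_NAMES) {
        stop("unknown bond parameter: ", param, call. = FALSE)
      }
      list(row = row, name = param)
    },
    offdiag = {
      row <- match_pair_row(ff$offdiag, parts[1], parts[2])
      if (is.na(row)) stop("no off-diagonal record for ", key, call. = FALSE)
      if (!param %in% OFFDIAG_PARAM_NAMES) {
        stop("unknown off-diagonal parameter: ", param, call. = FALSE)
      }
      list(row = row, name = param)
    },
    angles = {
      row <- match_angle_row(ff$angles, parts[1], parts[2], parts[3])
      if (is.na(row)) stop("no angle record for ", key, call. = FALSE)
      if (!param %in% ANGLE_PARAM_NAMES) {
        stop("unknown angle parameter: ", param, call. = FALSE)
      }
      list(row = row, name = param)
    },
    torsions = {
      row <- match_torsion_row(ff$torsions, parts[1], parts[2], parts[3], parts[4])
      if (is.na(row)) stop("no torsion record for ", key, call. = FALSE)
      if (!param %in% TORSION_PARAM_NAMES) {
        stop("unknown torsion parameter: ", param, call. = FALSE)
      }
      list(row = row, name = param)
    },
    hbonds = {
      hit <- which(ff$hbonds$donor == parts[1] &
        ff$hbonds$hydrogen == parts[2] & ff$hbonds$acceptor == parts[3])
      if (length(hit) == 0) stop("no hydrogen-bond record for ", key, call. = FALSE)
      if (!param %in% HBOND_PARAM_NAMES) {
        stop("unknown hydrogen-bond parameter: ", param, call. = FALSE)
      }
      list(row = hit[1], name = param)
    },
    stop("unknown section: ", section, call. = FALSE)
  )
}

#' Get a single force-field parameter
#'
#' @param ff A [reax_forcefield].
#' @param section One of `"general"`, `"atoms"`, `"bonds"`, `"offdiag"`,
#'   `"angles"`, `"torsions"`, `"hbonds"`.
#' @param key Record key: an element (`"O"`), pair (`"O-H"`), angle triple
#'   (`"H-O-H"`), torsion quadruple (`"X-O-O-X"`) or donor-H-acceptor triple
#'   (`"O-H-O"`). Ignored for `section = "general"`.
#' @param param Parameter name within the record (e.g. `"De_s"`).
#' @return Numeric scalar.
#' @export
ff_get_param <- function(ff, section, key, param) {
  loc <- locate_param(ff, section, key, param)
  if (section == "general") {
    return(unname(ff$general[[loc$name]]))
  }
  ff[[section]][loc$row, loc$name]
}

#' Set a single force-field parameter
#'
#' @inheritParams ff_get_param
#' @param value New numeric value.
#' @return The modified force field.
#' @export
ff_set_param <- function(ff, section, key, param, value) {
  loc <- locate_param(ff, section, key, param)
  if (section == "general") {
    ff$general[[loc$name]] <- value
  } else {
    ff[[section]][loc$row, loc$name] <- value
  }
  ff
}
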