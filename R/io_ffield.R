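# Reader/writer for the fixed-format ReaxFF 'ffield' parameter file.
#
# The writer emits fixed 9.4f columns; the reader tokenizes on whitespace but
# enforces the per-block record counts and per-record value counts, raising a
# parse error that names the offending line.

ffield_tokens <- function(lines, lineno, n_expected, n_leading_symbols = 0) {
  if (lineno > length(lines)) {
    stop("ffield parse error: unexpected end of file at line ", lineno,
      call. = FALSE
    )
  }
  toks <- strsplit(trimws(lines[lineno]), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) < n_leading_symbols + n_expected) {
    stop(
      "ffield parse error at line ", lineno, ": expected ",
      n_leading_symbols + n_expected, " fields, found ", length(toks),
      call. = FALSE
    )
  }
  vals <- suppressWarnings(as.numeric(
    toks[(n_leading_symbols + 1):(n_leading_symbols + n_expected)]
  ))
  if (anyNA(vals)) {
    stop("ffield parse error at line ", lineno, ": non-numeric field",
      call. = FALSE
    )
  }
  list(symbols = toks[seq_len(n_leading_symbols)], values = vals)
}

ffield_count <- function(lines, lineno) {
  toks <- strsplit(trimws(lines[lineno]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(toks[1]))
  if (is.na(n) || n < 0) {
    stop("ffield parse error at line ", lineno, ": expected a record count",
      call. = FALSE
    )
  }
  n
}

#' Read a fixed-format ReaxFF force-field file
#'
#' Parses the community-standard `ffield` layout: header comment, 39 general
#' parameters, 4-line element blocks, 2-line bond blocks and single-line
#' off-diagonal, valence-angle, torsion and hydrogen-bond records. Element
#' indices in the bonded blocks are resolved against the element order of the
#' atom section (index 0 in torsion records is the wildcard `"X"`).
#'
#' @param path Path to an `ffield`-format text file.
#' @return A [reax_forcefield].
#' @seealso [write_ffield()]
#' @export
read_ffield <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ln <- 1L
  header <- trimws(lines[ln])
  ln <- ln + 1L

  n_gen <- ffield_count(lines, ln)
  if (n_gen != 39L) {
    stop("ffield parse error at line ", ln, ": expected 39 general parameters, found ",
      n_gen,
      call. = FALSE
    )
  }
  ln <- ln + 1L
  general <- numeric(39)
  for (k in 1:39) {
    general[k] <- ffield_tokens(lines, ln, 1)$values
    ln <- ln + 1L
  }
  names(general) <- GENERAL_PARAM_NAMES

  n_at <- ffield_count(lines, ln)
  ln <- ln + 4L # count line plus three continuation header lines
  atoms <- vector("list", n_at)
  els <- character(n_at)
  for (k in seq_len(n_at)) {
    first <- ffield_tokens(lines, ln, 8, n_leading_symbols = 1)
    sym <- first$symbols
    if (!sym %in% REAX_ELEMENTS) {
      stop("ffield parse error at line ", ln, ": unknown element symbol '",
        sym, "'",
        call. = FALSE
      )
    }
    vals <- first$values
    for (j in 1:3) {
      vals <- c(vals, ffield_tokens(lines, ln + j, 8)$values)
    }
    els[k] <- sym
    atoms[[k]] <- vals
    ln <- ln + 4L
  }
  atoms <- as.data.frame(do.call(rbind, atoms))
  names(atoms) <- ATOM_PARAM_NAMES
  atoms <- cbind(element = els, atoms)

  el_of <- function(idx, lineno) {
    if (idx == 0) {
      return("X")
    }
    if (idx < 1 || idx > n_at) {
      stop("ffield parse error at line ", lineno, ": element index ", idx,
        " out of range",
        call. = FALSE
      )
    }
    els[idx]
  }

  n_bond <- ffield_count(lines, ln)
  ln <- ln + 2L # count line plus one continuation header line
  bonds <- vector("list", n_bond)
  b1 <- b2 <- character(n_bond)
  for (k in seq_len(n_bond)) {
    first <- ffield_tokens(lines, ln, 10)
    i <- as.integer(first$values[1])
    j <- as.integer(first$values[2])
    b1[k] <- el_of(i, ln)
    b2[k] <- el_of(j, ln)
    vals <- c(first$values[3:10], ffield_tokens(lines, ln + 1, 8)$values)
    bonds[[k]] <- vals
    ln <- ln + 2L
  }
  bonds <- as.data.frame(do.call(rbind, c(bonds, list(matrix(numeric(0), 0, 16)))))
  names(bonds) <- BOND_PARAM_NAMES
  bonds <- cbind(el1 = b1, el2 = b2, bonds)

  read_block <- function(nsym, nval, cols, symnames) {
    n <- ffield_count(lines, ln)
    ln <<- ln + 1L
    recs <- vector("list", n)
    syms <- matrix("", n, nsym)
    for (k in seq_len(n)) {
      row <- ffield_tokens(lines, ln, nsym + nval)
      syms[k, ] <- vapply(row$values[1:nsym], function(ii) el_of(as.integer(ii), ln), "")
      recs[[k]] <- row$values[(nsym + 1):(nsym + nval)]
      ln <<- ln + 1L
    }
    df <- as.data.frame(do.call(rbind, c(recs, list(matrix(numeric(0), 0, nval)))))
    names(df) <- cols
    sdf <- as.data.frame(syms, stringsAsFactors = FALSE)
    names(sdf) <- symnames
    cbind(sdf, df)
  }

  offdiag <- read_block(2, 6, OFFDIAG_PARAM_NAMES, c("el1", "el2"))
  angles <- read_block(3, 7, ANGLE_PARAM_NAMES, c("el1", "el2", "el3"))
  torsions <- read_block(4, 7, TORSION_PARAM_NAMES, c("el1", "el2", "el3", "el4"))
  hbonds <- read_block(3, 4, HBOND_PARAM_NAMES, c("donor", "hydrogen", "acceptor"))

  reax_forcefield(general, atoms, bonds, offdiag, angles, torsions, hbonds,
    header = header
  )
}

fmt_f <- function(x) sprintf("%9.4f", x)

#' Write a force field in fixed-format ffield layout
#'
#' Produces a file that [read_ffield()] parses back to identical values at
#' the printed precision (4 decimal places).
#'
#' @param ff A [reax_forcefield].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ffield <- function(ff, path) {
  validate_forcefield(ff)
  els <- ff$atoms$element
  idx_of <- function(e) ifelse(e == "X", 0L, match(e, els))
  out <- character(0)
  push <- function(...) out <<- c(out, paste0(...))

  push(ff$header)
  push(sprintf(" %2d       ! Number of general parameters", 39L))
  for (k in 1:39) {
    push(fmt_f(ff$general[[k]]), " !", GENERAL_PARAM_NAMES[k])
  }
  push(sprintf(
    "%3d    ! Nr of atoms; cov.r; valency;a.m;Rvdw;Evdw;gammaEEM;cov.r2;#el",
    nrow(ff$atoms)
  ))
  push("            alfa;gammavdW;valency;Eunder;n.u.;chiEEM;etaEEM;n.u.")
  push("            cov r3;Elp;Heat inc.;n.u.;n.u.;n.u.;n.u.")
  push("            ov/un;val1;n.u.;val3,vval4")
  for (k in seq_len(nrow(ff$atoms))) {
    v <- as.numeric(ff$atoms[k, ATOM_PARAM_NAMES])
    push(sprintf(" %-2s", els[k]), paste(fmt_f(v[1:8]), collapse = ""))
    push("   ", paste(fmt_f(v[9:16]), collapse = ""))
    push("   ", paste(fmt_f(v[17:24]), collapse = ""))
    push("   ", paste(fmt_f(v[25:32]), collapse = ""))
  }
  push(sprintf(
    "%3d      ! Nr of bonds; Edis1;LPpen;n.u.;pbe1;pbo5;13corr;pbo6",
    nrow(ff$bonds)
  ))
  push("                         pbe2;pbo3;pbo4;n.u.;pbo1;pbo2;ovcorr")
  for (k in seq_len(nrow(ff$bonds))) {
    v <- as.numeric(ff$bonds[k, BOND_PARAM_NAMES])
    push(
      sprintf("%3d%3d", idx_of(ff$bonds$el1[k]), idx_of(ff$bonds$el2[k])),
      paste(fmt_f(v[1:8]), collapse = "")
    )
    push("      ", paste(fmt_f(v[9:16]), collapse = ""))
  }
  push(sprintf("%3d    ! Nr of off-diagonal terms; Ediss;Ro;gamma;rsigma;rpi;rpi2", nrow(ff$offdiag)))
  for (k in seq_len(nrow(ff$offdiag))) {
    v <- as.numeric(ff$offdiag[k, OFFDIAG_PARAM_NAMES])
    push(
      sprintf("%3d%3d", idx_of(ff$offdiag$el1[k]), idx_of(ff$offdiag$el2[k])),
      paste(fmt_f(v), collapse = "")
    )
  }
  push(sprintf("%3d    ! Nr of angles; theta0;ka;kb;pv1;pv2;penal;pv3", nrow(ff$angles)))
  for (k in seq_len(nrow(ff$angles))) {
    v <- as.numeric(ff$angles[k, ANGLE_PARAM_NAMES])
    push(
      sprintf(
        "%3d%3d%3d", idx_of(ff$angles$el1[k]), idx_of(ff$angles$el2[k]),
        idx_of(ff$angles$el3[k])
      ),
      paste(fmt_f(v), collapse = "")
    )
  }
  push(sprintf("%3d    ! Nr of torsions; V1;V2;V3;V2(BO);vconj;n.u;n.u", nrow(ff$torsions)))
  for (k in seq_len(nrow(ff$torsions))) {
    v <- as.numeric(ff$torsions[k, TORSION_PARAM_NAMES])
    push(
      sprintf(
        "%3d%3d%3d%3d", idx_of(ff$torsions$el1[k]), idx_of(ff$torsions$el2[k]),
        idx_of(ff$torsions$el3[k]), idx_of(ff$torsions$el4[k])
      ),
      paste(fmt_f(v), collapse = "")
    )
  }
  push(sprintf("%3d    ! Nr of hydrogen bonds; Rhb;Dehb;vhb1;vhb2", nrow(ff$hbonds)))
  for (k in seq_len(nrow(ff$hbonds))) {
    v <- as.numeric(ff$hbonds[k, HBOND_PARAM_NAMES])
    push(
      sprintf(
        "%3d%3d%3d", idx_of(ff$hbonds$donor[k]), idx_of(ff$hbonds$hydrogen[k]),
        idx_of(ff$hbonds$acceptor[k])
      ),
      paste(fmt_f(v), collapse = "")
    )
  }
  writeLines(out, path)
  invisible(path)
}
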