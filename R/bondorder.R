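# Parameter table compilation, uncorrected/corrected bond orders with the
# partial derivatives needed for analytic forces, and EEM charge
# equilibration.

# Compile a force field into flat per-type lookup tables. Pair quantities are
# ntype x ntype matrices (NA where no record exists); angle/torsion/hbond
# records are resolved into dense index arrays so the energy kernel never
# string-matches. Torsion lookups fall back to X-j-k-X wildcards.
ff_tables <- function(ff) {
  validate_forcefield(ff)
  els <- ff$atoms$element
  nt <- length(els)
  at <- function(name) as.numeric(ff$atoms[[name]])

  g <- as.list(ff$general)
  tab <- list(
    els = els, nt = nt,
    # atom params
    r_s = at("r_s"), valency = at("valency"), mass = at("mass"),
    r_vdw = at("r_vdw"), epsilon = at("epsilon"), gamma = at("gamma"),
    r_pi = at("r_pi"), valency_e = at("valency_e"), alpha = at("alpha"),
    gamma_w = at("gamma_w"), valency_angle = at("valency_angle"),
    p_ovun5 = at("p_ovun5"), chi = at("chi"), eta = at("eta"),
    p_hbond = at("p_hbond"), r_pipi = at("r_pipi"), p_lp2 = at("p_lp2"),
    p_boc4 = at("p_boc4"), p_boc3 = at("p_boc3"), p_boc5 = at("p_boc5"),
    p_ovun2 = at("p_ovun2"), p_val3 = at("p_val3"),
    valency_boc = at("valency_boc"), p_val5 = at("p_val5"),
    general = g,
    bo_cut = g$bo_cutoff_x100 * 0.01,
    r_taper = g$swb
  )
  tab$nlp_opt <- 0.5 * (tab$valency_e - tab$valency)

  M <- function() matrix(NA_real_, nt, nt)
  pair_names <- c(
    "De_s", "De_p", "De_pp", "p_be1", "p_be2", "p_bo1", "p_bo2", "p_bo3",
    "p_bo4", "p_bo5", "p_bo6", "p_ovun1", "ovc", "v13corr"
  )
  P <- lapply(pair_names, function(nm) M())
  names(P) <- pair_names
  r_s_p <- M()
  r_p_p <- M()
  r_pp_p <- M()
  boc3 <- M()
  boc4 <- M()
  boc5 <- M()

  for (k in seq_len(nrow(ff$bonds))) {
    i <- match(ff$bonds$el1[k], els)
    j <- match(ff$bonds$el2[k], els)
    for (nm in pair_names) {
      P[[nm]][i, j] <- P[[nm]][j, i] <- ff$bonds[[nm]][k]
    }
    r_s_p[i, j] <- r_s_p[j, i] <-
      if (tab$r_s[i] > 0 && tab$r_s[j] > 0) 0.5 * (tab$r_s[i] + tab$r_s[j]) else -1
    r_p_p[i, j] <- r_p_p[j, i] <-
      if (tab$r_pi[i] > 0 && tab$r_pi[j] > 0) 0.5 * (tab$r_pi[i] + tab$r_pi[j]) else -1
    r_pp_p[i, j] <- r_pp_p[j, i] <-
      if (tab$r_pipi[i] > 0 && tab$r_pipi[j] > 0) 0.5 * (tab$r_pipi[i] + tab$r_pipi[j]) else -1
    boc3[i, j] <- boc3[j, i] <- sqrt(tab$p_boc3[i] * tab$p_boc3[j])
    boc4[i, j] <- boc4[j, i] <- sqrt(tab$p_boc4[i] * tab$p_boc4[j])
    boc5[i, j] <- boc5[j, i] <- sqrt(tab$p_boc5[i] * tab$p_boc5[j])
  }

  # vdW/Coulomb combination rules with off-diagonal overrides
  Dij <- sqrt(outer(tab$epsilon, tab$epsilon))
  Rvdw <- 2 * sqrt(outer(tab$r_vdw, tab$r_vdw))
  Avdw <- sqrt(outer(tab$alpha, tab$alpha))
  Gw <- sqrt(outer(tab$gamma_w, tab$gamma_w))
  Gc <- sqrt(outer(tab$gamma, tab$gamma))
  for (k in seq_len(nrow(ff$offdiag))) {
    i <- match(ff$offdiag$el1[k], els)
    j <- match(ff$offdiag$el2[k], els)
    od <- ff$offdiag[k, ]
    if (od$epsilon > 0) Dij[i, j] <- Dij[j, i] <- od$epsilon
    if (od$r_vdw > 0) Rvdw[i, j] <- Rvdw[j, i] <- 2 * od$r_vdw
    if (od$alpha > 0) Avdw[i, j] <- Avdw[j, i] <- od$alpha
    if (od$r_s > 0) r_s_p[i, j] <- r_s_p[j, i] <- od$r_s
    if (od$r_p > 0) r_p_p[i, j] <- r_p_p[j, i] <- od$r_p
    if (od$r_pp > 0) r_pp_p[i, j] <- r_pp_p[j, i] <- od$r_pp
  }
  tab <- c(tab, P)
  tab$r_s_pair <- r_s_p
  tab$r_p_pair <- r_p_p
  tab$r_pp_pair <- r_pp_p
  tab$p_boc3p <- boc3
  tab$p_boc4p <- boc4
  tab$p_boc5p <- boc5
  tab$Dij <- Dij
  tab$Rvdw <- Rvdw
  tab$Avdw <- Avdw
  tab$Gw <- Gw
  tab$Gc <- Gc

  # dense angle / torsion / hbond record indices
  ang_idx <- array(0L, c(nt, nt, nt))
  for (k in seq_len(nrow(ff$angles))) {
    i <- match(ff$angles$el1[k], els)
    j <- match(ff$angles$el2[k], els)
    l <- match(ff$angles$el3[k], els)
    ang_idx[i, j, l] <- k
    ang_idx[l, j, i] <- k
  }
  tor_idx <- array(0L, c(nt, nt, nt, nt))
  for (a in 1:nt) {
    for (b in 1:nt) {
      for (cc in 1:nt) {
        for (d in 1:nt) {
          row <- match_torsion_row(ff$torsions, els[a], els[b], els[cc], els[d])
          if (!is.na(row)) tor_idx[a, b, cc, d] <- row
        }
      }
    }
  }
  hb_idx <- array(0L, c(nt, nt, nt))
  for (k in seq_len(nrow(ff$hbonds))) {
    i <- match(ff$hbonds$donor[k], els)
    j <- match(ff$hbonds$hydrogen[k], els)
    l <- match(ff$hbonds$acceptor[k], els)
    hb_idx[i, j, l] <- k
  }
  tab$ang_idx <- ang_idx
  tab$tor_idx <- tor_idx
  tab$hb_idx <- hb_idx
  tab$angles <- ff$angles
  tab$torsions <- ff$torsions
  tab$hbonds <- ff$hbonds
  tab
}

atom_types <- function(s, tab) {
  t <- match(s$symbols, tab$els)
  if (anyNA(t)) {
    stop("force field lacks parameters for element(s): ",
      paste(unique(s$symbols[is.na(t)]), collapse = ", "),
      call. = FALSE
    )
  }
  t
}

zero_if <- function(x, ok) ifelse(ok, x, 0)

# Uncorrected and corrected bond orders plus every partial derivative the
# force resolution needs. `nl` must come from build_neighbor_list().
bond_order_stage <- function(s, tab, nl, t) {
  n <- n_atoms(s)
  sel <- which(nl$bonded)
  bi <- nl$i[sel]
  bj <- nl$j[sel]
  r <- nl$r[sel]
  d <- nl$d[sel, , drop = FALSE]
  ti <- t[bi]
  tj <- t[bj]
  ij <- cbind(ti, tj)

  rs <- tab$r_s_pair[ij]
  rp <- tab$r_p_pair[ij]
  rpp <- tab$r_pp_pair[ij]
  pbo1 <- tab$p_bo1[ij]
  pbo2 <- tab$p_bo2[ij]
  pbo3 <- tab$p_bo3[ij]
  pbo4 <- tab$p_bo4[ij]
  pbo5 <- tab$p_bo5[ij]
  pbo6 <- tab$p_bo6[ij]

  has_pars <- !is.na(pbo1)

  ok_s <- has_pars & !is.na(rs) & rs > 0
  ok_p <- has_pars & !is.na(rp) & rp > 0
  ok_pp <- has_pars & !is.na(rpp) & rpp > 0

  bos_u <- ifelse(ok_s, exp(zero_if(pbo1, ok_s) * (r / ifelse(ok_s, rs, 1))^zero_if(pbo2, ok_s)), 0)
  bop_u <- ifelse(ok_p, exp(zero_if(pbo3, ok_p) * (r / ifelse(ok_p, rp, 1))^zero_if(pbo4, ok_p)), 0)
  bopp_u <- ifelse(ok_pp, exp(zero_if(pbo5, ok_pp) * (r / ifelse(ok_pp, rpp, 1))^zero_if(pbo6, ok_pp)), 0)
  bot_u <- bos_u + bop_u + bopp_u

  # pairs close enough to bond (inside the summed sigma radii) but lacking a
  # bond record cannot be evaluated
  r_detect <- tab$r_s[ti] + tab$r_s[tj]
  missing <- which(!has_pars & r <= pmax(r_detect, 0))
  if (length(missing) > 0) {
    k <- missing[1]
    stop("missing bond parameters for pair ",
      tab$els[ti[k]], "-", tab$els[tj[k]],
      call. = FALSE
    )
  }

  keep <- which(has_pars & bot_u >= tab$bo_cut)
  bi <- bi[keep]
  bj <- bj[keep]
  r <- r[keep]
  d <- d[keep, , drop = FALSE]
  ti <- ti[keep]
  tj <- tj[keep]
  ij <- cbind(ti, tj)
  for (nm in c(
    "rs", "rp", "rpp", "pbo1", "pbo2", "pbo3", "pbo4", "pbo5", "pbo6",
    "bos_u", "bop_u", "bopp_u"
  )) {
    assign(nm, get(nm)[keep])
  }
  nb <- length(bi)

  # distance derivatives of the raw components
  dbos <- ifelse(bos_u > 0 & rs > 0,
    bos_u * pbo1 * pbo2 * (r / rs)^(pbo2 - 1) / rs, 0
  )
  dbop <- ifelse(bop_u > 0 & rp > 0,
    bop_u * pbo3 * pbo4 * (r / rp)^(pbo4 - 1) / rp, 0
  )
  dbopp <- ifelse(bopp_u > 0 & rpp > 0,
    bopp_u * pbo5 * pbo6 * (r / rpp)^(pbo6 - 1) / rpp, 0
  )

  # C1 switch on the sigma component: (b - c)^2 / b vanishes with zero slope
  # at the bond-order cutoff, so both the energy and the forces of every
  # bonded term go to zero continuously as a pair crosses the cutoff
  cc <- tab$bo_cut
  above <- bos_u > cc
  dbos <- dbos * ifelse(above, (bos_u - cc) * (bos_u + cc) / bos_u^2, 0)
  bos_u <- ifelse(above, (bos_u - cc)^2 / bos_u, 0)
  bot_u <- bos_u + bop_u + bopp_u

  # raw overcoordination
  sumBOp <- numeric(n)
  if (length(bi) > 0) {
    tmp <- rowsum(c(bot_u, bot_u), c(bi, bj))
    sumBOp[as.integer(rownames(tmp))] <- tmp[, 1]
  }
  Dp <- sumBOp - tab$valency[t]
  Dp_boc <- sumBOp - tab$valency_boc[t]

  Dpi <- Dp[bi]
  Dpj <- Dp[bj]
  Vi <- tab$valency[ti]
  Vj <- tab$valency[tj]

  l1 <- tab$general$p_boc1
  l2 <- tab$general$p_boc2

  ovc_on <- tab$ovc[ij] > 0.001
  e2i <- exp(-l1 * Dpi)
  e2j <- exp(-l1 * Dpj)
  f2 <- e2i + e2j
  e3i <- exp(-l2 * Dpi)
  e3j <- exp(-l2 * Dpj)
  f3 <- -1 / l2 * log(0.5 * (e3i + e3j))
  den_i <- Vi + f2 + f3
  den_j <- Vj + f2 + f3
  f1 <- 0.5 * ((Vi + f2) / den_i + (Vj + f2) / den_j)
  df1_df2 <- 0.5 * (f3 / den_i^2 + f3 / den_j^2)
  df1_df3 <- -0.5 * ((Vi + f2) / den_i^2 + (Vj + f2) / den_j^2)
  df2_dDi <- -l1 * e2i
  df2_dDj <- -l1 * e2j
  df3_dDi <- e3i / (e3i + e3j)
  df3_dDj <- e3j / (e3i + e3j)
  df1_dDi <- df1_df2 * df2_dDi + df1_df3 * df3_dDi
  df1_dDj <- df1_df2 * df2_dDj + df1_df3 * df3_dDj
  f1[!ovc_on] <- 1
  df1_dDi[!ovc_on] <- 0
  df1_dDj[!ovc_on] <- 0

  v13_on <- tab$v13corr[ij] > 0.001
  b3 <- tab$p_boc3p[ij]
  b4 <- tab$p_boc4p[ij]
  b5 <- tab$p_boc5p[ij]
  Dboci <- Dp_boc[bi]
  Dbocj <- Dp_boc[bj]
  ex4 <- exp(-b3 * (b4 * bot_u^2 - Dboci) + b5)
  ex5 <- exp(-b3 * (b4 * bot_u^2 - Dbocj) + b5)
  f4 <- 1 / (1 + ex4)
  f5 <- 1 / (1 + ex5)
  df4_dbot <- f4^2 * ex4 * b3 * b4 * 2 * bot_u
  df5_dbot <- f5^2 * ex5 * b3 * b4 * 2 * bot_u
  df4_dDi <- -f4^2 * ex4 * b3
  df5_dDj <- -f5^2 * ex5 * b3
  f4[!v13_on] <- 1
  f5[!v13_on] <- 1
  df4_dbot[!v13_on] <- 0
  df5_dbot[!v13_on] <- 0
  df4_dDi[!v13_on] <- 0
  df5_dDj[!v13_on] <- 0

  Fc <- f1 * f4 * f5
  Gc <- f1 * Fc # f1^2 f4 f5
  dF_dbot <- f1 * (df4_dbot * f5 + f4 * df5_dbot)
  dG_dbot <- f1 * dF_dbot
  dF_dDi <- df1_dDi * f4 * f5 + f1 * df4_dDi * f5
  dF_dDj <- df1_dDj * f4 * f5 + f1 * f4 * df5_dDj
  dG_dDi <- 2 * f1 * df1_dDi * f4 * f5 + f1^2 * df4_dDi * f5
  dG_dDj <- 2 * f1 * df1_dDj * f4 * f5 + f1^2 * f4 * df5_dDj

  bos <- bos_u * Fc
  bop <- bop_u * Gc
  bopp <- bopp_u * Gc
  bot <- bos + bop + bopp

  sum_bo <- numeric(n)
  if (nb > 0) {
    sb <- rowsum(c(bot, bot), c(bi, bj), reorder = FALSE)
    sum_bo[as.integer(rownames(sb))] <- as.numeric(sb)
  }
  Delta <- sum_bo - tab$valency[t]

  list(
    n = n, nb = nb, i = bi, j = bj, r = r, d = d, ti = ti, tj = tj,
    bos_u = bos_u, bop_u = bop_u, bopp_u = bopp_u, bot_u = bot_u,
    dbos = dbos, dbop = dbop, dbopp = dbopp,
    f1 = f1, f4 = f4, f5 = f5, Fc = Fc, Gc = Gc,
    dF_dbot = dF_dbot, dG_dbot = dG_dbot,
    dF_dDi = dF_dDi, dF_dDj = dF_dDj, dG_dDi = dG_dDi, dG_dDj = dG_dDj,
    bos = bos, bop = bop, bopp = bopp, bot = bot,
    sum_bo = sum_bo, Delta = Delta, Delta_p = Dp
  )
}

#' Compute bond orders for a structure
#'
#' Evaluates the three-exponential uncorrected sigma/pi/pi-pi bond orders for
#' every bonded-candidate pair, applies the standard overcoordination
#' correction factors, and reports per-atom total bond orders and
#' overcoordinations.
#'
#' @param s A [reax_structure].
#' @param ff A [reax_forcefield].
#' @param nl Optional pre-built [build_neighbor_list()] result.
#' @return A list of class `reax_bondorders`: tibble `pairs` (atoms, distance,
#'   uncorrected and corrected components), per-atom `total_bo` and
#'   overcoordination `delta`.
#' @export
compute_bond_orders <- function(s, ff, nl = NULL) {
  tab <- ff_tables(ff)
  t <- atom_types(s, tab)
  if (is.null(nl)) nl <- build_neighbor_list(s, ff)
  bo <- bond_order_stage(s, tab, nl, t)
  structure(
    list(
      pairs = tibble::tibble(
        i = bo$i, j = bo$j, r = bo$r,
        bo_sigma_raw = bo$bos_u, bo_pi_raw = bo$bop_u, bo_pipi_raw = bo$bopp_u,
        bo_sigma = bo$bos, bo_pi = bo$bop, bo_pipi = bo$bopp, bo = bo$bot
      ),
      total_bo = bo$sum_bo,
      delta = bo$Delta
    ),
    class = "reax_bondorders"
  )
}

# EEM kernel value and its distance derivative (kcal/mol/e^2 and per A)
eem_kernel <- function(r, gamma_ij, r_taper) {
  den <- (r^3 + gamma_ij^-3)^(1 / 3)
  KCAL_COULOMB * taper_value(r, r_taper) / den
}

eem_kernel_deriv <- function(r, gamma_ij, r_taper) {
  g <- gamma_ij^-3
  den <- (r^3 + g)^(1 / 3)
  KCAL_COULOMB * (taper_deriv(r, r_taper) / den -
    taper_value(r, r_taper) * r^2 * (r^3 + g)^(-4 / 3))
}

eem_solve <- function(s, tab, nl, t) {
  n <- n_atoms(s)
  chi <- tab$chi[t] * EV_TO_KCAL
  eta <- tab$eta[t] * EV_TO_KCAL
  if (n == 1L) {
    q <- s$total_charge
    return(list(
      q = q, chi = chi, eta = eta,
      pair_K = numeric(0), e_self = sum(chi * q + eta * q^2)
    ))
  }
  K <- eem_kernel(nl$r, tab$Gc[cbind(t[nl$i], t[nl$j])], tab$r_taper)
  H <- matrix(0, n, n)
  diag(H) <- 2 * eta
  # vectorized accumulation over (possibly duplicated) pair/image entries
  same <- nl$i == nl$j
  lin <- c(
    (nl$j[!same] - 1L) * n + nl$i[!same],
    (nl$i[!same] - 1L) * n + nl$j[!same],
    (nl$i[same] - 1L) * n + nl$i[same]
  )
  val <- c(K[!same], K[!same], 2 * K[same])
  if (length(lin) > 0) {
    agg <- rowsum(val, lin)
    idx <- as.integer(rownames(agg))
    H[idx] <- H[idx] + agg[, 1]
  }
  M <- rbind(cbind(H, 1), c(rep(1, n), 0))
  rhs <- c(-chi, s$total_charge)
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    stop("singular EEM system: ", conditionMessage(e), call. = FALSE)
  })
  q <- sol[1:n]
  list(q = q, chi = chi, eta = eta, pair_K = K, e_self = sum(chi * q + eta * q^2))
}

#' Equilibrate EEM partial charges
#'
#' Solves the electronegativity-equalization linear system: charges minimize
#' the quadratic electrostatic energy (electronegativity + hardness terms
#' plus the shielded, tapered pairwise Coulomb kernel) subject to the total
#' charge constraint.
#'
#' @param s A [reax_structure].
#' @param ff A [reax_forcefield] supplying per-element electronegativity
#'   (chi, eV), hardness (eta, eV) and shielding (gamma, 1/Angstrom).
#' @param nl Optional pre-built neighbor list.
#' @return Numeric vector of per-atom charges (e), summing to
#'   `s$total_charge`.
#' @export
equilibrate_charges <- function(s, ff, nl = NULL) {
  tab <- ff_tables(ff)
  t <- atom_types(s, tab)
  if (is.null(nl)) nl <- build_neighbor_list(s, ff)
  eem_solve(s, tab, nl, t)$q
}
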