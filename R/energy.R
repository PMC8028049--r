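# Full energy evaluation with per-term breakdown and analytic forces.
#
# Force evaluation uses adjoint (reverse-mode) accumulation: every energy
# term deposits derivatives with respect to corrected bond-order components,
# per-atom bond-order sums, lone-pair counts and geometric coordinates; a
# resolution pass then propagates these through the overcoordination
# corrections down to raw bond orders and interatomic distances. Charges are
# re-equilibrated at every evaluation; since the EEM objective is exactly the
# E_Coul + E_charge contribution to the total, the frozen-charge gradient is
# variationally exact (Hellmann-Feynman).

acc_atoms <- function(target, idx, vals) {
  if (length(idx) == 0) {
    return(target)
  }
  agg <- rowsum(vals, idx)
  ids <- as.integer(rownames(agg))
  target[ids] <- target[ids] + agg[, 1]
  target
}

.warned_records <- new.env(parent = emptyenv())

warn_missing_record <- function(kind, key) {
  id <- paste0(kind, "_", key)
  if (!is.null(.warned_records[[id]])) {
    return(invisible())
  }
  .warned_records[[id]] <- TRUE
  warning("no ", kind, " parameters for ", key, "; term contributes 0",
    call. = FALSE
  )
}

# Core evaluator. Returns breakdown, charges and (optionally) the gradient.
reax_eval <- function(s, ff, tables = NULL, nl = NULL, want_forces = FALSE,
                      hb_cutoff = 7.5, hb_bo_threshold = 0.01,
                      thb_cutoff = 0) {
  validate_structure(s)
  tab <- if (is.null(tables)) ff_tables(ff) else tables
  t <- atom_types(s, tab)
  if (is.null(nl)) {
    nl <- build_neighbor_list(s, list(general = c(swb = tab$r_taper)))
  }
  n <- n_atoms(s)
  g <- tab$general

  grad <- matrix(0, n, 3)

  ## ---- EEM charges, Coulomb, self energy -------------------------------
  eem <- eem_solve(s, tab, nl, t)
  q <- eem$q
  E_charge <- eem$e_self
  E_coul <- 0
  if (length(nl$i) > 0) {
    qq <- q[nl$i] * q[nl$j]
    E_coul <- sum(eem$pair_K * qq)
    if (want_forces) {
      dK <- eem_kernel_deriv(nl$r, tab$Gc[cbind(t[nl$i], t[nl$j])], tab$r_taper)
      dEdr_nb_coul <- dK * qq
    }
  }

  ## ---- van der Waals ----------------------------------------------------
  E_vdw <- 0
  dEdr_nb_vdw <- NULL
  if (length(nl$i) > 0) {
    ij <- cbind(t[nl$i], t[nl$j])
    Dv <- tab$Dij[ij]
    rv <- tab$Rvdw[ij]
    av <- tab$Avdw[ij]
    gw <- tab$Gw[ij]
    pv <- g$p_vdw1
    r <- nl$r
    f13 <- (r^pv + gw^(-pv))^(1 / pv)
    df13 <- r^(pv - 1) * (r^pv + gw^(-pv))^(1 / pv - 1)
    ex1 <- exp(av * (1 - f13 / rv))
    ex2 <- exp(0.5 * av * (1 - f13 / rv))
    tp <- taper_value(r, tab$r_taper)
    core <- Dv * (ex1 - 2 * ex2)
    E_vdw <- sum(tp * core)
    if (want_forces) {
      dtp <- taper_deriv(r, tab$r_taper)
      dcore <- Dv * (-av / rv) * (ex1 - ex2) * df13
      dEdr_nb_vdw <- dtp * core + tp * dcore
    }
  }

  ## ---- bond orders -------------------------------------------------------
  bo <- bond_order_stage(s, tab, nl, t)
  nb <- bo$nb
  bi <- bo$i
  bj <- bo$j
  ti <- bo$ti
  tj <- bo$tj
  bij <- cbind(ti, tj)

  # per-atom lone-pair bookkeeping (needs corrected bond orders)
  De <- bo$sum_bo - tab$valency_e[t]
  tr_ <- trunc(De / 2)
  xlp <- 2 + De - 2 * tr_
  explp <- exp(-g$p_lp1 * xlp^2)
  nlp <- -tr_ + explp
  dnlp_dDe <- -2 * g$p_lp1 * xlp * explp
  nlp_opt <- tab$nlp_opt[t]
  Dlp_at <- nlp_opt - nlp # Delta_lp per atom
  Delta <- bo$Delta
  Delta_val <- bo$sum_bo - tab$valency_angle[t]
  Delta_boc <- bo$sum_bo - tab$valency_boc[t]

  # adjoint accumulators
  A_s <- numeric(nb)
  A_p <- numeric(nb)
  A_pp <- numeric(nb)
  A_t <- numeric(nb)
  D_at <- numeric(n) # dE / d(sum of corrected BO), direct
  Dlp_adj <- numeric(n) # dE / d(Delta_lp)
  Dnlp_adj <- numeric(n) # dE / d(n_lp), direct
  S_adj <- numeric(n) # dE / dS (pi-overcoordination sum)
  SBO_adj <- numeric(n) # dE / dSBO

  ## ---- bond energy -------------------------------------------------------
  E_bond <- 0
  if (nb > 0) {
    De_s <- tab$De_s[bij]
    De_p <- tab$De_p[bij]
    De_pp <- tab$De_pp[bij]
    pbe1 <- tab$p_be1[bij]
    pbe2 <- tab$p_be2[bij]
    bos_safe <- pmax(bo$bos, 1e-300)
    ebs <- exp(pbe1 * (1 - bos_safe^pbe2))
    E_bond <- sum(-De_s * bo$bos * ebs - De_p * bo$bop - De_pp * bo$bopp)
    if (want_forces) {
      A_s <- A_s + (-De_s * ebs * (1 - pbe1 * pbe2 * bos_safe^pbe2))
      A_p <- A_p - De_p
      A_pp <- A_pp - De_pp
    }
  }

  ## ---- lone pair ---------------------------------------------------------
  e75 <- exp(-75 * Dlp_at)
  p_lp2_at <- tab$p_lp2[t]
  E_lp <- sum(p_lp2_at * Dlp_at / (1 + e75))
  if (want_forces) {
    Dlp_adj <- Dlp_adj +
      p_lp2_at * (1 / (1 + e75) + Dlp_at * 75 * e75 / (1 + e75)^2)
  }

  ## ---- over/undercoordination -------------------------------------------
  E_over <- 0
  E_under <- 0
  if (nb > 0) {
    bopipp <- bo$bop + bo$bopp
    wS <- Delta - Dlp_at # (Delta_j - Delta_lp_j), per atom
    S_at <- numeric(n)
    S_at <- acc_atoms(S_at, bi, wS[bj] * bopipp)
    S_at <- acc_atoms(S_at, bj, wS[bi] * bopipp)

    ov1 <- tab$p_ovun1[bij] * tab$De_s[bij]
    sumov1 <- numeric(n)
    sumov1 <- acc_atoms(sumov1, bi, ov1 * bo$bot)
    sumov1 <- acc_atoms(sumov1, bj, ov1 * bo$bot)

    expS <- exp(g$p_ovun4 * S_at)
    u_at <- 1 / (1 + g$p_ovun3 * expS)
    du_dS <- -g$p_ovun3 * g$p_ovun4 * expS * u_at^2
    Dlpc <- Delta - Dlp_at * u_at

    Val <- tab$valency[t]
    po2 <- tab$p_ovun2[t]
    g1 <- Dlpc / (Dlpc + Val)
    eo <- exp(po2 * Dlpc)
    g2 <- 1 / (1 + eo)
    E_over_at <- sumov1 * g1 * g2
    E_over <- sum(E_over_at)

    po5 <- tab$p_ovun5[t]
    e6u <- exp(g$p_ovun6 * Dlpc)
    em <- exp(-po2 * Dlpc)
    wqu <- (1 - e6u) / (1 + em)
    e8 <- exp(g$p_ovun8 * S_at)
    h_at <- 1 / (1 + g$p_ovun7 * e8)
    E_under_at <- -po5 * wqu * h_at
    E_under <- sum(E_under_at)

    if (want_forces) {
      dg1 <- Val / (Dlpc + Val)^2
      dg2 <- -po2 * eo / (1 + eo)^2
      dE_dDlpc <- sumov1 * (dg1 * g2 + g1 * dg2)
      dwqu <- (-g$p_ovun6 * e6u * (1 + em) + (1 - e6u) * po2 * em) / (1 + em)^2
      dE_dDlpc <- dE_dDlpc + (-po5) * h_at * dwqu
      dh <- -g$p_ovun7 * g$p_ovun8 * e8 * h_at^2
      S_adj <- S_adj + (-po5) * wqu * dh +
        dE_dDlpc * (-Dlp_at * du_dS)
      D_at <- D_at + dE_dDlpc
      Dlp_adj <- Dlp_adj + dE_dDlpc * (-u_at)
      gg <- g1 * g2 # dE/dsumov1
      A_t <- A_t + (gg[bi] + gg[bj]) * ov1
    }
  }

  ## ---- incidence lists for many-body terms -------------------------------
  # entry e: atom inc_at[e] is an end of bond inc_b[e]; the vector from
  # inc_at to its neighbour is inc_sign[e] * d[inc_b[e], ]
  E_val <- 0
  E_pen <- 0
  E_coa <- 0
  E_tors <- 0
  E_conj <- 0
  E_hb <- 0

  if (nb > 0) {
    inc_at <- c(bi, bj)
    inc_b <- c(seq_len(nb), seq_len(nb))
    inc_sign <- c(rep(1, nb), rep(-1, nb))
    inc_nbr <- c(bj, bi)
    by_atom <- split(seq_along(inc_at), inc_at)

    # per-atom product term for SBO
    P_at <- exp(-(acc_atoms(numeric(n), bi, bo$bot^8) +
      acc_atoms(numeric(n), bj, bo$bot^8)))
    SP_at <- acc_atoms(numeric(n), bi, bo$bop + bo$bopp)
    SP_at <- acc_atoms(SP_at, bj, bo$bop + bo$bopp)
    A8_at <- -Delta_boc - g$p_val8 * nlp
    SBO_at <- SP_at + (1 - P_at) * A8_at
    # SBO2 and its derivative
    SBO2_at <- numeric(n)
    dSBO2_at <- numeric(n)
    sb <- SBO_at
    m1 <- sb > 0 & sb <= 1
    m2 <- sb > 1 & sb < 2
    m3 <- sb >= 2
    SBO2_at[m1] <- sb[m1]^g$p_val9
    dSBO2_at[m1] <- g$p_val9 * sb[m1]^(g$p_val9 - 1)
    SBO2_at[m2] <- 2 - (2 - sb[m2])^g$p_val9
    dSBO2_at[m2] <- g$p_val9 * (2 - sb[m2])^(g$p_val9 - 1)
    SBO2_at[m3] <- 2

    ## ---- valence angles (+ penalty + three-body conjugation) ------------
    ang_c <- integer(0)
    ang_e1 <- integer(0)
    ang_e2 <- integer(0)
    for (a_chr in names(by_atom)) {
      ents <- by_atom[[a_chr]]
      ents <- ents[bo$bot[inc_b[ents]] > thb_cutoff]
      if (length(ents) < 2) next
      cmb <- utils::combn(ents, 2)
      ang_c <- c(ang_c, rep(as.integer(a_chr), ncol(cmb)))
      ang_e1 <- c(ang_e1, cmb[1, ])
      ang_e2 <- c(ang_e2, cmb[2, ])
    }
    if (length(ang_c) > 0) {
      b1 <- inc_b[ang_e1]
      b2 <- inc_b[ang_e2]
      a_i <- inc_nbr[ang_e1]
      a_k <- inc_nbr[ang_e2]
      rows <- tab$ang_idx[cbind(t[a_i], t[ang_c], t[a_k])]
      have <- rows > 0
      if (any(!have)) {
        miss <- unique(paste(tab$els[t[a_i[!have]]], tab$els[t[ang_c[!have]]],
          tab$els[t[a_k[!have]]],
          sep = "-"
        ))
        for (key in miss) warn_missing_record("angle", key)
      }
      sel <- which(have)
      if (length(sel) > 0) {
        b1 <- b1[sel]
        b2 <- b2[sel]
        cc <- ang_c[sel]
        ai <- a_i[sel]
        ak <- a_k[sel]
        e1 <- ang_e1[sel]
        e2 <- ang_e2[sel]
        pars <- tab$angles[rows[sel], , drop = FALSE]
        th00 <- pars$theta00 * DEG2RAD
        pval1 <- pars$p_val1
        pval2 <- pars$p_val2
        pval4 <- pars$p_val4
        pval7 <- pars$p_val7
        pcoa1 <- pars$p_coa1
        ppen1 <- pars$p_pen1
        pval3 <- tab$p_val3[t[cc]]
        pval5 <- tab$p_val5[t[cc]]

        u <- bo$d[b1, , drop = FALSE] * inc_sign[e1]
        v <- bo$d[b2, , drop = FALSE] * inc_sign[e2]
        ak_geo <- angle_kernel(u, v)
        theta <- ak_geo$theta

        bo1 <- bo$bot[b1]
        bo2 <- bo$bot[b2]
        ef7_1 <- exp(-pval3 * bo1^pval4)
        ef7_2 <- exp(-pval3 * bo2^pval4)
        f7_1 <- 1 - ef7_1
        f7_2 <- 1 - ef7_2

        dv <- Delta_val[cc]
        e6 <- exp(g$p_val6 * dv)
        e7m <- exp(-pval7 * dv)
        denf8 <- 1 + e6 + e7m
        f8 <- pval5 - (pval5 - 1) * (2 + e6) / denf8

        th0 <- pi - th00 * (1 - exp(-g$p_val10 * (2 - SBO2_at[cc])))
        xth <- th0 - theta
        exv <- exp(-pval2 * xth^2)
        K <- pval1 - pval1 * exv
        E_val_terms <- f7_1 * f7_2 * f8 * K
        E_val <- E_val + sum(E_val_terms)

        # penalty (two double bonds at the pivot)
        f9den <- 1 + exp(-g$p_pen3 * Delta[cc]) + exp(g$p_pen4 * Delta[cc])
        f9 <- (2 + exp(-g$p_pen3 * Delta[cc])) / f9den
        ep1 <- exp(-g$p_pen2 * (bo1 - 2)^2)
        ep2 <- exp(-g$p_pen2 * (bo2 - 2)^2)
        E_pen_terms <- ppen1 * f9 * ep1 * ep2
        E_pen <- E_pen + sum(E_pen_terms)

        # three-body conjugation
        ecoa_d <- 1 + exp(g$p_coa2 * dv)
        ci1 <- bo$sum_bo[ai] - bo1
        ci2 <- bo$sum_bo[ak] - bo2
        eca <- exp(-g$p_coa3 * ci1^2) * exp(-g$p_coa3 * ci2^2) *
          exp(-g$p_coa4 * (bo1 - 1.5)^2) * exp(-g$p_coa4 * (bo2 - 1.5)^2)
        E_coa_terms <- pcoa1 / ecoa_d * eca
        E_coa <- E_coa + sum(E_coa_terms)

        if (want_forces) {
          dK_dx <- 2 * pval1 * pval2 * xth * exv # dK/d(th0 - theta)
          pref <- f7_1 * f7_2 * f8
          dE_dtheta <- -pref * dK_dx
          dE_dth0 <- pref * dK_dx
          # geometric part
          gu <- ak_geo$dtheta_du * dE_dtheta
          gv <- ak_geo$dtheta_dv * dE_dtheta
          grad <- rowsum_into(grad, ai, gu)
          grad <- rowsum_into(grad, ak, gv)
          grad <- rowsum_into(grad, cc, -(gu + gv))
          # f7 wrt leg bond orders
          df7_1 <- pval3 * pval4 * pmax(bo1, 1e-12)^(pval4 - 1) * ef7_1
          df7_2 <- pval3 * pval4 * pmax(bo2, 1e-12)^(pval4 - 1) * ef7_2
          A_t <- acc_vec(A_t, b1, df7_1 * f7_2 * f8 * K)
          A_t <- acc_vec(A_t, b2, f7_1 * df7_2 * f8 * K)
          # f8 wrt Delta_val
          df8 <- -(pval5 - 1) *
            (g$p_val6 * e6 * denf8 - (2 + e6) * (g$p_val6 * e6 - pval7 * e7m)) /
            denf8^2
          D_at <- acc_atoms(D_at, cc, f7_1 * f7_2 * df8 * K)
          # theta0 wrt SBO2 -> SBO (per pivot)
          dth0_dSBO2 <- th00 * g$p_val10 * exp(-g$p_val10 * (2 - SBO2_at[cc]))
          SBO_adj <- acc_atoms(
            SBO_adj, cc,
            dE_dth0 * dth0_dSBO2 * dSBO2_at[cc]
          )
          # penalty adjoints
          e3p <- exp(-g$p_pen3 * Delta[cc])
          e4p <- exp(g$p_pen4 * Delta[cc])
          df9 <- (-g$p_pen3 * e3p * f9den -
            (2 + e3p) * (-g$p_pen3 * e3p + g$p_pen4 * e4p)) / f9den^2
          D_at <- acc_atoms(D_at, cc, ppen1 * df9 * ep1 * ep2)
          A_t <- acc_vec(A_t, b1, E_pen_terms * (-2 * g$p_pen2 * (bo1 - 2)))
          A_t <- acc_vec(A_t, b2, E_pen_terms * (-2 * g$p_pen2 * (bo2 - 2)))
          # conjugation adjoints
          D_at <- acc_atoms(
            D_at, cc,
            E_coa_terms * (-g$p_coa2 * exp(g$p_coa2 * dv) / ecoa_d)
          )
          D_at <- acc_atoms(D_at, ai, E_coa_terms * (-2 * g$p_coa3 * ci1))
          D_at <- acc_atoms(D_at, ak, E_coa_terms * (-2 * g$p_coa3 * ci2))
          A_t <- acc_vec(A_t, b1, E_coa_terms *
            (2 * g$p_coa3 * ci1 - 2 * g$p_coa4 * (bo1 - 1.5)))
          A_t <- acc_vec(A_t, b2, E_coa_terms *
            (2 * g$p_coa3 * ci2 - 2 * g$p_coa4 * (bo2 - 1.5)))
        }
      }
    }

    ## ---- torsions (+ four-body conjugation) ------------------------------
    tor <- enumerate_torsions(by_atom, inc_b, inc_nbr, inc_sign, bi, bj, bo,
      thb_cutoff
    )
    if (!is.null(tor)) {
      rows <- tab$tor_idx[cbind(t[tor$ai], t[tor$aj], t[tor$ak], t[tor$al])]
      have <- rows > 0
      if (any(!have)) {
        miss <- unique(paste(tab$els[t[tor$ai[!have]]], tab$els[t[tor$aj[!have]]],
          tab$els[t[tor$ak[!have]]], tab$els[t[tor$al[!have]]],
          sep = "-"
        ))
        for (key in miss) warn_missing_record("torsion", key)
      }
      sel <- which(have)
      if (length(sel) > 0) {
        ai <- tor$ai[sel]
        aj <- tor$aj[sel]
        ak <- tor$ak[sel]
        al <- tor$al[sel]
        bij_t <- tor$b_ij[sel]
        bjk_t <- tor$b_jk[sel]
        bkl_t <- tor$b_kl[sel]
        u1 <- tor$u1[sel, , drop = FALSE] # j -> i
        bb2 <- tor$b2[sel, , drop = FALSE] # j -> k
        v1 <- tor$v1[sel, , drop = FALSE] # k -> l
        pars <- tab$torsions[rows[sel], , drop = FALSE]

        dk <- dihedral_kernel(-u1, bb2, v1)
        om <- dk$omega
        ak1 <- angle_kernel(u1, bb2)
        ak2 <- angle_kernel(-bb2, v1)
        s1 <- sin(ak1$theta)
        s2 <- sin(ak2$theta)

        bo_ij <- bo$bot[bij_t]
        bo_jk <- bo$bot[bjk_t]
        bo_kl <- bo$bot[bkl_t]
        bop_jk <- bo$bop[bjk_t]

        et1 <- 1 - exp(-g$p_tor2 * bo_ij)
        et2 <- 1 - exp(-g$p_tor2 * bo_jk)
        et3 <- 1 - exp(-g$p_tor2 * bo_kl)
        f10 <- et1 * et2 * et3
        sdv <- Delta_val[aj] + Delta_val[ak]
        e3t <- exp(-g$p_tor3 * sdv)
        e4t <- exp(g$p_tor4 * sdv)
        denf11 <- 1 + e3t + e4t
        f11 <- (2 + e3t) / denf11
        argt <- bop_jk - 1 + f11
        expt <- exp(pars$p_tor1 * argt^2)
        V1 <- pars$V1
        V2 <- pars$V2
        V3 <- pars$V3
        bracket <- 0.5 * V1 * (1 + cos(om)) +
          0.5 * V2 * expt * (1 - cos(2 * om)) +
          0.5 * V3 * (1 + cos(3 * om))
        E_tors_terms <- f10 * s1 * s2 * bracket
        E_tors <- E_tors + sum(E_tors_terms)

        f12 <- exp(-g$p_cot2 * (bo_ij - 1.5)^2) *
          exp(-g$p_cot2 * (bo_jk - 1.5)^2) *
          exp(-g$p_cot2 * (bo_kl - 1.5)^2)
        cos2m1 <- cos(om)^2 - 1
        E_conj_terms <- pars$p_cot1 * f12 * (1 + cos2m1 * s1 * s2)
        E_conj <- E_conj + sum(E_conj_terms)

        if (want_forces) {
          # omega derivative
          dbracket_dom <- -0.5 * V1 * sin(om) +
            V2 * expt * sin(2 * om) -
            1.5 * V3 * sin(3 * om)
          dE_dom <- f10 * s1 * s2 * dbracket_dom +
            pars$p_cot1 * f12 * s1 * s2 * (-sin(2 * om))
          grad <- rowsum_into(grad, ai, dE_dom * dk$d_i)
          grad <- rowsum_into(grad, aj, dE_dom * dk$d_j)
          grad <- rowsum_into(grad, ak, dE_dom * dk$d_k)
          grad <- rowsum_into(grad, al, dE_dom * dk$d_l)
          # theta derivatives via sin factors
          pre_s <- f10 * bracket + pars$p_cot1 * f12 * cos2m1
          dE_dth1 <- pre_s * cos(ak1$theta) * s2
          dE_dth2 <- pre_s * s1 * cos(ak2$theta)
          g1u <- ak1$dtheta_du * dE_dth1
          g1v <- ak1$dtheta_dv * dE_dth1
          # u = u1 (j->i), v = b2 (j->k)
          grad <- rowsum_into(grad, ai, g1u)
          grad <- rowsum_into(grad, ak, g1v)
          grad <- rowsum_into(grad, aj, -(g1u + g1v))
          g2u <- ak2$dtheta_du * dE_dth2
          g2v <- ak2$dtheta_dv * dE_dth2
          # u = -b2 (k->j), v = v1 (k->l)
          grad <- rowsum_into(grad, aj, g2u)
          grad <- rowsum_into(grad, al, g2v)
          grad <- rowsum_into(grad, ak, -(g2u + g2v))
          # bond-order adjoints
          sb12 <- s1 * s2 * bracket
          A_t <- acc_vec(A_t, bij_t, sb12 * g$p_tor2 * (1 - et1) * et2 * et3)
          A_t <- acc_vec(A_t, bjk_t, sb12 * g$p_tor2 * et1 * (1 - et2) * et3)
          A_t <- acc_vec(A_t, bkl_t, sb12 * g$p_tor2 * et1 * et2 * (1 - et3))
          dexpt <- expt * pars$p_tor1 * 2 * argt
          A_p <- acc_vec(
            A_p, bjk_t,
            f10 * s1 * s2 * 0.5 * V2 * (1 - cos(2 * om)) * dexpt
          )
          df11 <- (-g$p_tor3 * e3t * denf11 -
            (2 + e3t) * (-g$p_tor3 * e3t + g$p_tor4 * e4t)) / denf11^2
          dE_dsdv <- f10 * s1 * s2 * 0.5 * V2 * (1 - cos(2 * om)) * dexpt * df11
          D_at <- acc_atoms(D_at, aj, dE_dsdv)
          D_at <- acc_atoms(D_at, ak, dE_dsdv)
          # conjugation bond adjoints
          ecp <- pars$p_cot1 * (1 + cos2m1 * s1 * s2) * f12
          A_t <- acc_vec(A_t, bij_t, ecp * (-2 * g$p_cot2 * (bo_ij - 1.5)))
          A_t <- acc_vec(A_t, bjk_t, ecp * (-2 * g$p_cot2 * (bo_jk - 1.5)))
          A_t <- acc_vec(A_t, bkl_t, ecp * (-2 * g$p_cot2 * (bo_kl - 1.5)))
        }
      }
    }

    ## ---- hydrogen bonds --------------------------------------------------
    hb <- enumerate_hbonds(s, tab, nl, t, bo, hb_cutoff, hb_bo_threshold)
    if (!is.null(hb)) {
      pars <- tab$hbonds[hb$rows, , drop = FALSE]
      r0 <- pars$r_hb
      rhz <- hb$r_hz
      bo_xh <- bo$bot[hb$b_xh]
      exb <- exp(-pars$p_hb2 * bo_xh)
      exd <- exp(-pars$p_hb3 * (r0 / rhz + rhz / r0 - 2))
      akh <- angle_kernel(hb$u_x, hb$v_z) # at the H vertex
      sh <- sin(akh$theta / 2)
      E_hb_terms <- pars$p_hb1 * (1 - exb) * exd * sh^4
      E_hb <- E_hb + sum(E_hb_terms)
      if (want_forces) {
        A_t <- acc_vec(
          A_t, hb$b_xh,
          pars$p_hb1 * pars$p_hb2 * exb * exd * sh^4
        )
        dE_drhz <- pars$p_hb1 * (1 - exb) * sh^4 *
          exd * (-pars$p_hb3 * (-r0 / rhz^2 + 1 / r0))
        ghz <- dE_drhz / rhz
        grad <- rowsum_into(grad, hb$a_z, ghz * hb$v_z)
        grad <- rowsum_into(grad, hb$a_h, -ghz * hb$v_z)
        dE_dth <- pars$p_hb1 * (1 - exb) * exd * 2 * sh^3 * cos(akh$theta / 2)
        gxu <- akh$dtheta_du * dE_dth
        gzv <- akh$dtheta_dv * dE_dth
        grad <- rowsum_into(grad, hb$a_x, gxu)
        grad <- rowsum_into(grad, hb$a_z, gzv)
        grad <- rowsum_into(grad, hb$a_h, -(gxu + gzv))
      }
    }
  }

  breakdown <- list(
    E_bond = E_bond, E_lp = E_lp, E_over = E_over, E_under = E_under,
    E_val = E_val, E_pen = E_pen, E_coa = E_coa, E_tors = E_tors,
    E_conj = E_conj, E_hbond = E_hb, E_vdW = E_vdw, E_Coul = E_coul,
    E_charge = E_charge
  )
  total <- sum(unlist(breakdown))

  forces <- NULL
  if (want_forces) {
    if (nb > 0) {
      ## ---- resolve SBO adjoints into bond adjoints ----------------------
      # SBO = SP + (1 - P) * A8 per pivot atom
      sboi <- SBO_adj[bi]
      sboj <- SBO_adj[bj]
      A_p <- A_p + sboi + sboj
      A_pp <- A_pp + sboi + sboj
      A_t <- A_t + 8 * bo$bot^7 *
        (sboi * P_at[bi] * A8_at[bi] + sboj * P_at[bj] * A8_at[bj])
      D_at <- D_at + SBO_adj * (-(1 - P_at))
      Dnlp_adj <- Dnlp_adj + SBO_adj * (-g$p_val8 * (1 - P_at))

      ## ---- resolve S adjoints (pi overcoordination sum) ------------------
      bopipp <- bo$bop + bo$bopp
      wS <- Delta - Dlp_at
      csi <- S_adj[bi]
      csj <- S_adj[bj]
      addp <- csi * wS[bj] + csj * wS[bi]
      A_p <- A_p + addp
      A_pp <- A_pp + addp
      D_at <- acc_atoms(D_at, bj, csi * bopipp)
      D_at <- acc_atoms(D_at, bi, csj * bopipp)
      Dlp_adj <- acc_atoms(Dlp_adj, bj, -csi * bopipp)
      Dlp_adj <- acc_atoms(Dlp_adj, bi, -csj * bopipp)

      ## ---- fold lone-pair dependence into D ------------------------------
      D_at <- D_at + (Dnlp_adj - Dlp_adj) * dnlp_dDe

      ## ---- propagate to raw bond orders ---------------------------------
      a_s <- A_s + A_t + D_at[bi] + D_at[bj]
      a_p <- A_p + A_t + D_at[bi] + D_at[bj]
      a_pp <- A_pp + A_t + D_at[bi] + D_at[bj]

      wF <- a_s * bo$bos_u
      wG <- a_p * bo$bop_u + a_pp * bo$bopp_u
      # contributions to Delta' (raw bond-order sums)
      Dp_adj <- numeric(n)
      Dp_adj <- acc_atoms(Dp_adj, bi, wF * bo$dF_dDi + wG * bo$dG_dDi)
      Dp_adj <- acc_atoms(Dp_adj, bj, wF * bo$dF_dDj + wG * bo$dG_dDj)
      # total raw-BO adjoint per bond
      Tb <- wF * bo$dF_dbot + wG * bo$dG_dbot + Dp_adj[bi] + Dp_adj[bj]
      g_s <- a_s * bo$Fc + Tb
      g_p <- a_p * bo$Gc + Tb
      g_pp <- a_pp * bo$Gc + Tb
      dEdr_bond <- g_s * bo$dbos + g_p * bo$dbop + g_pp * bo$dbopp
      gb <- (dEdr_bond / bo$r) * bo$d
      grad <- rowsum_into(grad, bj, gb)
      grad <- rowsum_into(grad, bi, -gb)
    }
    if (length(nl$i) > 0) {
      dEdr_nb <- dEdr_nb_coul + dEdr_nb_vdw
      gn <- (dEdr_nb / nl$r) * nl$d
      grad <- rowsum_into(grad, nl$j, gn)
      grad <- rowsum_into(grad, nl$i, -gn)
    }
    forces <- -grad
  }

  structure(
    list(
      breakdown = breakdown, total = total, charges = q, forces = forces,
      neighbor_list = nl, n_bonds = nb
    ),
    class = "reax_evaluation"
  )
}

acc_vec <- function(target, idx, vals) {
  if (length(idx) == 0) {
    return(target)
  }
  agg <- rowsum(vals, idx)
  ids <- as.integer(rownames(agg))
  target[ids] <- target[ids] + agg[, 1]
  target
}

rowsum_into <- function(target, idx, vals) {
  if (length(idx) == 0) {
    return(target)
  }
  agg <- rowsum(vals, idx)
  ids <- as.integer(rownames(agg))
  target[ids, ] <- target[ids, , drop = FALSE] + agg
  target
}

# Torsion enumeration around each central bond j-k: neighbours i of j and l
# of k, excluding back-tracking and i == l, with all three bond orders above
# the three-body cutoff.
enumerate_torsions <- function(by_atom, inc_b, inc_nbr, inc_sign, bi, bj, bo,
                               thb_cutoff) {
  nb <- length(bi)
  out_ai <- integer(0)
  out_aj <- integer(0)
  out_ak <- integer(0)
  out_al <- integer(0)
  out_bij <- integer(0)
  out_bjk <- integer(0)
  out_bkl <- integer(0)
  u1 <- NULL
  b2 <- NULL
  v1 <- NULL
  u1l <- list()
  b2l <- list()
  v1l <- list()
  for (b in seq_len(nb)) {
    if (bo$bot[b] <= thb_cutoff) next
    j <- bi[b]
    k <- bj[b]
    ents_j <- by_atom[[as.character(j)]]
    ents_k <- by_atom[[as.character(k)]]
    ents_j <- ents_j[inc_b[ents_j] != b & bo$bot[inc_b[ents_j]] > thb_cutoff]
    ents_k <- ents_k[inc_b[ents_k] != b & bo$bot[inc_b[ents_k]] > thb_cutoff]
    if (length(ents_j) == 0 || length(ents_k) == 0) next
    gridij <- expand.grid(ej = ents_j, ek = ents_k)
    ii <- inc_nbr[gridij$ej]
    ll <- inc_nbr[gridij$ek]
    keep <- ii != ll & ii != k & ll != j
    if (!any(keep)) next
    gridij <- gridij[keep, , drop = FALSE]
    ii <- ii[keep]
    ll <- ll[keep]
    m <- nrow(gridij)
    out_ai <- c(out_ai, ii)
    out_aj <- c(out_aj, rep(j, m))
    out_ak <- c(out_ak, rep(k, m))
    out_al <- c(out_al, ll)
    out_bij <- c(out_bij, inc_b[gridij$ej])
    out_bjk <- c(out_bjk, rep(b, m))
    out_bkl <- c(out_bkl, inc_b[gridij$ek])
    u1l[[length(u1l) + 1]] <- bo$d[inc_b[gridij$ej], , drop = FALSE] *
      inc_sign[gridij$ej]
    b2l[[length(b2l) + 1]] <- matrix(rep(bo$d[b, ], m), m, 3, byrow = TRUE)
    v1l[[length(v1l) + 1]] <- bo$d[inc_b[gridij$ek], , drop = FALSE] *
      inc_sign[gridij$ek]
  }
  if (length(out_ai) == 0) {
    return(NULL)
  }
  list(
    ai = out_ai, aj = out_aj, ak = out_ak, al = out_al,
    b_ij = out_bij, b_jk = out_bjk, b_kl = out_bkl,
    u1 = do.call(rbind, u1l), b2 = do.call(rbind, b2l),
    v1 = do.call(rbind, v1l)
  )
}

# Hydrogen-bond triple enumeration: covalent donor-H bonds (donor flagged as
# acceptor-capable heavy atom, H flagged as donor hydrogen, bond order above
# threshold) combined with nonbonded H...acceptor pairs within the cutoff.
enumerate_hbonds <- function(s, tab, nl, t, bo, hb_cutoff, hb_bo_threshold) {
  if (nrow(tab$hbonds) == 0 || bo$nb == 0) {
    return(NULL)
  }
  ph <- tab$p_hbond[t]
  # donor bonds: X(2) - H(1)
  is_xh <- (ph[bo$i] == 2 & ph[bo$j] == 1) | (ph[bo$i] == 1 & ph[bo$j] == 2)
  don <- which(is_xh & bo$bot > hb_bo_threshold)
  if (length(don) == 0) {
    return(NULL)
  }
  h_at <- ifelse(ph[bo$i[don]] == 1, bo$i[don], bo$j[don])
  x_at <- ifelse(ph[bo$i[don]] == 1, bo$j[don], bo$i[don])
  # vector H -> X
  sgn <- ifelse(bo$i[don] == h_at, 1, -1)
  u_x <- bo$d[don, , drop = FALSE] * sgn

  # acceptor pairs from the nonbonded list (both orientations)
  cand_i <- c(nl$i, nl$j)
  cand_j <- c(nl$j, nl$i)
  cand_d <- rbind(nl$d, -nl$d)
  cand_r <- c(nl$r, nl$r)
  is_hz <- ph[cand_i] == 1 & ph[cand_j] == 2 & cand_r <= hb_cutoff
  hz <- which(is_hz)
  if (length(hz) == 0) {
    return(NULL)
  }

  hz_by_h <- split(hz, cand_i[hz])
  out <- list()
  for (kk in seq_along(don)) {
    h <- h_at[kk]
    lst <- hz_by_h[[as.character(h)]]
    if (is.null(lst)) next
    zz <- cand_j[lst]
    keep <- zz != x_at[kk]
    lst <- lst[keep]
    if (length(lst) == 0) next
    zz <- zz[keep]
    rows <- tab$hb_idx[cbind(t[x_at[kk]], t[h], t[zz])]
    ok <- rows > 0
    if (!any(ok)) next
    lst <- lst[ok]
    zz <- zz[ok]
    out[[length(out) + 1]] <- list(
      b_xh = rep(don[kk], length(lst)),
      a_x = rep(x_at[kk], length(lst)),
      a_h = rep(h, length(lst)),
      a_z = zz,
      rows = rows[ok],
      r_hz = cand_r[lst],
      u_x = matrix(rep(u_x[kk, ], length(lst)), ncol = 3, byrow = TRUE),
      v_z = cand_d[lst, , drop = FALSE]
    )
  }
  if (length(out) == 0) {
    return(NULL)
  }
  list(
    b_xh = unlist(lapply(out, `[[`, "b_xh")),
    a_x = unlist(lapply(out, `[[`, "a_x")),
    a_h = unlist(lapply(out, `[[`, "a_h")),
    a_z = unlist(lapply(out, `[[`, "a_z")),
    rows = unlist(lapply(out, `[[`, "rows")),
    r_hz = unlist(lapply(out, `[[`, "r_hz")),
    u_x = do.call(rbind, lapply(out, `[[`, "u_x")),
    v_z = do.call(rbind, lapply(out, `[[`, "v_z"))
  )
}

#' Evaluate the total energy and its per-term breakdown
#'
#' Computes every contribution of the reactive potential: bond energy, lone
#' pairs, over- and under-coordination, valence angles with penalty and
#' three-body conjugation, torsions with four-body conjugation, hydrogen
#' bonds, tapered van der Waals and Coulomb interactions, and the EEM
#' self/polarization energy. Charges are equilibrated on the fly.
#'
#' @param s A [reax_structure].
#' @param ff A [reax_forcefield].
#' @param nl Optional pre-built neighbor list.
#' @return An object of class `reax_energy`: the named per-term breakdown
#'   (kcal/mol), `total`, and the equilibrated `charges` (e).
#' @export
#' @examples
#' ff <- make_toy_forcefield(c("H", "O"))
#' e <- compute_energy(water_molecule(), ff)
#' e$total
compute_energy <- function(s, ff, nl = NULL) {
  ev <- reax_eval(s, ff, nl = nl, want_forces = FALSE)
  structure(
    c(ev$breakdown, list(total = ev$total, charges = ev$charges)),
    class = "reax_energy"
  )
}

#' @export
print.reax_energy <- function(x, ...) {
  cat("<reax_energy> total:", sprintf("%.6f", x$total), "kcal/mol\n")
  terms <- setdiff(names(x), c("total", "charges"))
  for (nm in terms) cat(sprintf("  %-9s %14.6f\n", nm, x[[nm]]))
  invisible(x)
}

#' Tidy an energy breakdown into a tibble
#'
#' @param x A `reax_energy` from [compute_energy()].
#' @param ... Unused.
#' @return Tibble with columns `term` and `energy` (kcal/mol), including the
#'   total.
#' @export
tidy.reax_energy <- function(x, ...) {
  terms <- setdiff(names(x), "charges")
  tibble::tibble(term = terms, energy = unlist(x[terms], use.names = FALSE))
}

#' Compute atomic forces
#'
#' Analytic mode accumulates the gradient of every energy term through the
#' bond-order machinery (frozen equilibrated charges, which is variationally
#' exact for the EEM energy); numerical mode is a central-difference
#' gradient of [compute_energy()] and serves as the independent oracle.
#'
#' @param s A [reax_structure].
#' @param ff A [reax_forcefield].
#' @param mode `"analytic"` or `"numerical"`.
#' @param step Central-difference step (Angstrom) for numerical mode.
#' @return N x 3 matrix of forces (kcal/mol/Angstrom).
#' @export
compute_forces <- function(s, ff, mode = c("analytic", "numerical"),
                           step = 1e-5) {
  mode <- match.arg(mode)
  if (mode == "analytic") {
    return(reax_eval(s, ff, want_forces = TRUE)$forces)
  }
  n <- n_atoms(s)
  f <- matrix(0, n, 3)
  tab <- ff_tables(ff)
  for (a in seq_len(n)) {
    for (k in 1:3) {
      sp <- s
      sp$coords[a, k] <- sp$coords[a, k] + step
      ep <- reax_eval(sp, ff, tables = tab, want_forces = FALSE)$total
      sm <- s
      sm$coords[a, k] <- sm$coords[a, k] - step
      em <- reax_eval(sm, ff, tables = tab, want_forces = FALSE)$total
      f[a, k] <- -(ep - em) / (2 * step)
    }
  }
  f
}
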