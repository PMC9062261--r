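# Right-hand-side assembly (reference R path).  Each ODE entry is the printed
# signed sum of fluxes divided by the volume of the compartment that heads its
# rate-of-change table (cytosol rows / Vcyto, IMS rows / Vims, matrix rows /
# Vmatrix, extracellular rows / Vextra); dPsi is not volume-scaled.

#' Apply the model's assignment rules to a state
#'
#' Recomputes the assignment-kind species from their rules: cytosolic
#' Mg-bound ADP from the binding polynomial, free cytosolic Mg as the total
#' minus the bound fraction, and the intermembrane-space adenine totals as
#' aliases of the matrix totals.  Idempotent.
#'
#' @param state named numeric full state vector.
#' @param model A [CardioModel-class].
#' @return the state with assignment species recomputed.
#' @export
applyAssignments <- function(state, model) {
  p <- model@parameters
  state["mADP_c"] <- betaADP(state[["ADP_c"]], p$MgBc$KMgADP, p$phys$MgtotC)
  state["Mg_c"]   <- p$phys$MgtotC - state[["mADP_c"]]
  state["ADP_x"]  <- state[["fADP_x"]] + state[["mADP_x"]]
  state["ATP_x"]  <- state[["fATP_x"]] + state[["mATP_x"]]
  state["ADP_i"]  <- state[["ADP_x"]]
  state["ATP_i"]  <- state[["ATP_x"]]
  state["fADP_i"] <- max(state[["ADP_i"]] - state[["mADP_i"]], 0)
  state["fATP_i"] <- max(state[["ATP_i"]] - state[["mATP_i"]], 0)
  state
}

#' Time derivatives of the full model state (reference implementation)
#'
#' Assembles dC/dt for every ODE-kind species and d(dPsi)/dt from the flux
#' vector, exactly as the printed per-compartment rate-of-change tables.
#' Constant-kind species receive a zero entry; assignment-kind species carry
#' no derivative (NA).
#'
#' @param time time (s); the dynamics are autonomous given the vessel oxygen.
#' @param state named numeric full state vector (assignments are reapplied).
#' @param model A [CardioModel-class].
#' @param o2v vessel oxygen (mM) to impose, or NULL to use the state's value.
#' @return list with \code{derivatives} (named, full registry; NA for
#'   assignment species), \code{fluxes} and \code{thermo}.
#' @export
modelDerivatives <- function(time, state, model, o2v = NULL) {
  if (!is.null(o2v)) state["O2_v"] <- o2v
  state <- applyAssignments(state, model)
  ev <- computeFluxes(state, model, check = FALSE)
  J <- as.list(ev$fluxes)
  p <- model@parameters
  aF1 <- ev$thermo[["aF1"]]
  # availability gate on the synthase->cytosol shadow coupling (see the
  # matching note in src/model_rhs.c); k = 1e-5 mM regularization
  gate <- if (J$F1 >= 0) state[["ADP_c"]] / (state[["ADP_c"]] + 1e-5)
          else state[["ATP_c"]] / (state[["ATP_c"]] + 1e-5)
  jF1c <- gate * J$F1
  jDHc <- if (J$DH >= 0) J$DH * state[["PYR_c"]] / (state[["PYR_c"]] + 1e-5) else J$DH
  aDH <- p$phys$aDH
  Vc <- p$phys$Vc; Vi <- p$phys$Vi; Vx <- p$phys$Vx; Ve <- p$phys$Ve

  d <- stats::setNames(rep(0, length(state)), names(state))
  # cytosol (table reference volume Vcyto)
  d["AMP_c"]   <- J$AK / Vc
  d["ADP_c"]   <- (-J$CK - 2 * J$AK + J$HK + J$PFK - J$PGK - J$PK +
                   J$ATPase - aF1 * jF1c) / Vc
  d["ATP_c"]   <- (J$CK + J$AK - J$ATPase - J$HK - J$PFK + J$PGK + J$PK +
                   aF1 * jF1c) / Vc
  d["BPG13_c"] <- (J$GAPDH - J$PGK - J$G16BPS) / Vc
  d["PG2_c"]   <- (J$PGM - J$Enolase) / Vc
  d["PG3_c"]   <- (J$PGK - J$PGM + J$G16BPS) / Vc
  d["Cr_c"]    <- J$CK / Vc
  d["CrP_c"]   <- -J$CK / Vc
  d["DHAP_c"]  <- (J$FBPA - J$TPI - J$G3PDH) / Vc
  d["F16BP_c"] <- (J$PFK - J$FBPA) / Vc
  d["F6P_c"]   <- (J$PGI - J$PFK) / Vc
  d["G1P_c"]   <- (-J$PGluM - J$UDPGP + J$GP - J$G16BPS) / Vc
  d["G6P_c"]   <- (J$HK - J$PGI + J$PGluM - J$G6PDH) / Vc
  d["GAP_c"]   <- (J$FBPA + J$TPI - J$GAPDH) / Vc
  d["GLY_c"]   <- (J$GSD + J$GSI - J$GP) / Vc
  d["LAC_c"]   <- (J$LHX - J$LA + J$LDH) / Vc
  d["LACH_c"]  <- J$LA / Vc
  d["Mb_c"]    <- -J$MB / Vc
  d["MbO2_c"]  <- J$MB / Vc
  d["O2_c"]    <- (-p$phys$o2PerC4 * J$C4 + J$O2EC - J$MB) / Vc
  d["PEP_c"]   <- (J$Enolase - J$PK) / Vc
  d["Pi_c"]    <- (-J$GAPDH + 2 * J$UDPGP - J$GP + J$G6PDH + J$G3PDH +
                   2 * J$G16BPS + J$ATPase - aF1 * jF1c) / Vc
  d["PYR_c"]   <- (J$PK - J$LDH - aDH * jDHc) / Vc
  d["UDPG_c"]  <- (J$UDPGP - J$GSD - J$GSI) / Vc
  # intermembrane space (reference volume Vims; dPsi unscaled).  Free IMS
  # adenine is an assignment (total minus Mg-bound); only the bound species
  # carry the binding ODEs.
  d["mADP_i"]  <-  J$MgADPi / Vi
  d["mATP_i"]  <-  J$MgATPi / Vi
  d["Pi_i"]    <- (J$Pi2 - J$Pi1) / Vi
  d["Cox_i"]   <- (2 * J$C4 - 2 * J$C3) / Vi
  d["Cred_i"]  <- (2 * J$C3 - 2 * J$C4) / Vi
  d["dPsi"]    <- (4 * J$C1 + 2 * J$C3 + 4 * J$C4 - 3 * J$F1 - J$ANT -
                   J$Hle) / p$phys$CIM
  # matrix (reference volume Vmatrix); proton row carries the buffering
  # prefactor [H]x / rbuff
  # ANT exchanges the free species, the synthase interconverts the Mg-bound
  # species; the matrix totals (assignments fADP+mADP, fATP+mATP) then obey
  # d[ADP]x = (J_ANT - J_F1)/Vx and d[ATP]x = (J_F1 - J_ANT)/Vx exactly.
  d["fADP_x"]  <- (J$ANT - J$MgADPx) / Vx
  d["mADP_x"]  <- (J$MgADPx - J$F1) / Vx
  d["fATP_x"]  <- (-J$ANT - J$MgATPx) / Vx
  d["mATP_x"]  <- (J$MgATPx + J$F1) / Vx
  d["H_x"]     <- (state[["H_x"]] / p$phys$rbuff) *
                  (J$DH - 5 * J$C1 - 2 * J$C3 - 4 * J$C4 + 2 * J$F1 +
                   2 * J$Pi1 + J$Hle - J$KH) / Vx
  d["K_x"]     <- J$KH / Vx
  d["Mg_x"]    <- (-J$MgADPx - J$MgATPx) / Vx
  d["NAD_x"]   <- (J$C1 - J$DH) / Vx
  d["NADH_x"]  <- (J$DH - J$C1) / Vx
  d["Pi_x"]    <- (J$Pi1 - J$F1) / Vx
  d["Q_x"]     <- (J$C3 - J$C1) / Vx
  d["QH2_x"]   <- (J$C1 - J$C3) / Vx
  # extracellular
  d["O2_e"]    <- (J$O2VE - J$O2EC) / Ve

  kinds <- stats::setNames(model@species$kind, model@species$name)
  d[names(d)[kinds[names(d)] == "assignment"]] <- NA_real_
  list(derivatives = d, fluxes = ev$fluxes, thermo = ev$thermo)
}
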