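# Reference (pure-R) evaluation of every reaction and transport flux.
# This transcription of the printed rate laws is kept independent of the
# compiled production path in src/model_rhs.c; the two are cross-checked to
# 1e-10 relative tolerance in the test suite.

#' Evaluate all reaction and transport fluxes at a state
#'
#' Computes every flux J (mM/s, per the reference compartment of the printed
#' rate-of-change tables) plus the thermodynamic terms: the proton-motive
#' energy dGH = F*dPsi + RT*ln(H_i/H_x) and the concentration-corrected
#' reaction free energies of complexes I, III and IV (kJ/mol), and the
#' synthase->cytosol coupling factor aF1 (a structural constant,
#' (fATP_x/ATP_x) * Vcyto/Vmatrix evaluated at the tabulated state).
#'
#' This is the reference implementation, evaluated species-by-species in R;
#' simulations use an equivalent compiled version.  The optional \code{s1}
#' saturation modifier of the phosphoglycerate kinase/mutase, enolase and
#' pyruvate kinase laws defaults to the constant-1 modifier (cytosolic pH is clamped, so
#' any pH-dependent form is constant).
#'
#' @param state named numeric vector over the full species registry
#'   (see [initialState()]).
#' @param model A [CardioModel-class] (or a nested parameter list).
#' @param s1 unary saturation modifier applied where the printed laws carry
#'   s1(.); the default (constant 1) leaves the Michaelis-Menten forms
#'   unmodulated, since cytosolic pH is clamped.
#' @param check validate non-negativity of concentrations (domain error).
#' @return named list with \code{fluxes} (named numeric, one entry per flux)
#'   and \code{thermo} (dGH, dGC1, dGC3, dGC4, aF1).
#' @examples
#' f <- computeFluxes(initialState(defaultModel()), defaultModel())
#' f$fluxes[c("CK", "ATPase", "Hle")]
#' @export
computeFluxes <- function(state, model, s1 = function(x) 1, check = TRUE) {
  p <- if (is(model, "CardioModel")) model@parameters else model
  if (check) {
    conc <- state[setdiff(names(state), c("dPsi", "pH_c"))]
    if (any(conc < 0))
      stop("negative concentration(s): ",
           paste(names(conc)[conc < 0], collapse = ", "))
  }
  s <- as.list(state)
  F  <- p$phys$F; RT <- p$phys$RT
  u  <- F * s$dPsi / RT

  J <- numeric(0)
  # R1 creatine kinase: ADP + CrP + H -> ATP + Cr
  J["CK"] <- p$CK$X * (p$CK$K * s$ADP_c * s$CrP_c * s$H_c - s$ATP_c * s$Cr_c)
  # R2 adenylate kinase: 2 ADP -> AMP + ATP
  J["AK"] <- p$AK$X * (p$AK$K * s$ADP_c^2 - s$ATP_c * s$AMP_c)
  # R3 ATP consumption, feedback-inhibited by the Pi*ADP/ATP energy state
  J["ATPase"] <- if (s$ATP_c > 0)
    p$ATPase$X / (1 + p$ATPase$R * s$Pi_c * s$ADP_c / s$ATP_c) else 0
  # R4 hexokinase (reversible MM with ATP saturation on the forward term)
  J["HK"] <- (p$HK$Vf * s$GLC_c * s$ATP_c / (p$HK$Kmf * (s$ATP_c + p$HK$KmATP)) -
              p$HK$Vr * s$G6P_c / p$HK$Kmr) /
             (1 + s$GLC_c / p$HK$Kmf + s$G6P_c / p$HK$Kmr)
  # R5 phosphoglucose isomerase
  J["PGI"] <- (p$PGI$Vf * s$G6P_c / p$PGI$Kmf - p$PGI$Vr * s$F6P_c / p$PGI$Kmr) /
              (1 + s$G6P_c / p$PGI$Kmf + s$F6P_c / p$PGI$Kmr)
  # R6 phosphofructokinase
  J["PFK"] <- p$PFK$Vf * (s$F6P_c / (p$PFK$Kmf + s$F6P_c)) /
              (1 + p$PFK$KmATP / s$ATP_c)
  # R7 aldolase
  J["FBPA"] <- p$FBPA$Vf * s$F16BP_c / (s$F16BP_c + p$FBPA$Kmf)
  # R8 triosephosphate isomerase
  J["TPI"] <- p$TPI$Vf * s$DHAP_c / (s$DHAP_c + p$TPI$Kmf)
  # R9 GAPDH (NAD-saturation factor)
  J["GAPDH"] <- p$GAPDH$Vf * (s$GAP_c / (p$GAPDH$Kmf + s$GAP_c)) /
                (1 + p$GAPDH$KmNAD / s$NAD_c)
  # R10 phosphoglycerate kinase
  J["PGK"] <- (p$PGK$Vf * s$BPG13_c * s1(s$BPG13_c) /
                 (p$PGK$Kmf * (1 + p$PGK$KmADP / s$ADP_c)) -
               p$PGK$Vr * s$PG3_c * s1(s$PG3_c) /
                 (p$PGK$Kmr * (1 + p$PGK$KmATP / s$ATP_c))) /
              (1 + s$BPG13_c / p$PGK$Kmf + s$PG3_c / p$PGK$Kmr)
  # R11 phosphoglycerate mutase
  J["PGM"] <- (p$PGM$Vf * s$PG3_c * s1(s$PG3_c) / p$PGM$Kmf -
               p$PGM$Vr * s$PG2_c * s1(s$PG2_c) / p$PGM$Kmr) /
              (1 + s$PG3_c / p$PGM$Kmf + s$PG2_c / p$PGM$Kmr)
  # R12 enolase
  J["Enolase"] <- (p$Enolase$Vf * s$PG2_c * s1(s$PG2_c) / p$Enolase$Kmf -
                   p$Enolase$Vr * s$PEP_c / p$Enolase$Kmr) /
                  (1 + s$PG2_c / p$Enolase$Kmf + s$PEP_c / p$Enolase$Kmr)
  # R13 pyruvate kinase
  J["PK"] <- (p$PK$Vf * s$PEP_c * s1(s$PEP_c) /
                (p$PK$Kmf * (1 + p$PK$KmADP / s$ADP_c)) -
              p$PK$Vr * s$PYR_c * s1(s$PYR_c) / p$PK$Kmr) /
             (1 + s$PEP_c / p$PK$Kmf + s$PYR_c / p$PK$Kmr)
  # R14 G6PDH sink, slaved to the isomerase flux
  J["G6PDH"] <- p$G6PDH$Vf * J[["PGI"]] / p$G6PDH$vss
  # R15 glycerol-3-phosphate dehydrogenase (ordered bi-bi)
  J["G3PDH"] <- p$G3PDH$Vf * s$DHAP_c * s$NADH_c /
                (p$G3PDH$Kia * p$G3PDH$KmDHAP + p$G3PDH$KmDHAP * s$NADH_c +
                 p$G3PDH$KmNADH * s$DHAP_c + s$DHAP_c * s$NADH_c)
  # R16 glucose-1,6-bisphosphate synthase
  J["G16BPS"] <- (p$G16BPS$Vf * s$BPG13_c /
                    (p$G16BPS$Kmf * (1 + p$G16BPS$KmG1P / s$G1P_c)) -
                  p$G16BPS$Vr * s$PG3_c /
                    (p$G16BPS$Kmr * (1 + p$G16BPS$KmG16BP / s$G16BP_c))) /
                 (1 + s$BPG13_c / p$G16BPS$Kmf + s$PG3_c / p$G16BPS$Kmr)
  # R17 phosphoglucomutase
  J["PGluM"] <- (p$PGluM$Vf * s$G1P_c / p$PGluM$Kmf -
                 p$PGluM$Vr * s$G6P_c / p$PGluM$Kmr) /
                (1 + s$G1P_c / p$PGluM$Kmf + s$G6P_c / p$PGluM$Kmr)
  # AMP modulation shared by glycogen-handling reactions
  ampMod <- function(km) if (s$AMP_c > 0) 1 + (km / s$AMP_c)^1.5 else Inf
  # R18 UDP-glucose pyrophosphorylase
  J["UDPGP"] <- p$UDPGP$X * (p$UDPGP$kf * s$G1P_c - p$UDPGP$kr * s$UDPG_c) /
                ampMod(p$UDPGP$KmAMP)
  # R19 glycogen synthase, D and I forms
  J["GSD"] <- p$GS$VfD * s$UDPG_c / ((p$GS$KmD + s$UDPG_c) * ampMod(p$GS$KmAMP))
  J["GSI"] <- p$GS$VfI * s$UDPG_c / ((p$GS$KmI + s$UDPG_c) * ampMod(p$GS$KmAMP))
  # R20 glycogen phosphorylase
  J["GP"] <- (p$GP$Vf * s$GLY_c / p$GP$Kmf - p$GP$Vr * s$G1P_c / p$GP$Kmr) /
             ((1 + s$GLY_c / p$GP$Kmf + s$G1P_c / p$GP$Kmr) * ampMod(p$GP$KmAMP))
  # R21 lactate dehydrogenase
  J["LDH"] <- p$LDH$Vf * (s$PYR_c / (p$LDH$Kmf + s$PYR_c)) /
              (1 + p$LDH$KmNADH / s$NADH_c)
  # R22 lactate/H cotransport (net influx)
  J["LHX"] <- p$LHX$Vf * s$LAC_e / (s$LAC_e + p$LHX$Kmf) -
              p$LHX$Vr * s$LAC_c / (s$LAC_c + p$LHX$Kmr)
  # R23 lactic acid association
  J["LA"] <- p$LA$X * (s$LAC_c * s$H_c / p$LA$Km - s$LACH_c)
  # R24 myoglobin-oxygen binding
  J["MB"] <- p$MB$ka * s$Mb_c * s$O2_c - p$MB$kd * s$MbO2_c
  # R26/27 magnesium binding, intermembrane space ([Mg]i fixed parameter)
  J["MgADPi"] <- p$MgB$X * (s$fADP_i * p$phys$MgI - p$MgB$KMgADP * s$mADP_i)
  J["MgATPi"] <- p$MgB$X * (s$fATP_i * p$phys$MgI - p$MgB$KMgATP * s$mATP_i)
  # R37 magnesium binding, matrix
  J["MgADPx"] <- p$MgB$X * (s$fADP_x * s$Mg_x - p$MgB$KMgADP * s$mADP_x)
  J["MgATPx"] <- p$MgB$X * (s$fATP_x * s$Mg_x - p$MgB$KMgATP * s$mATP_x)
  # R28 phosphate/H cotransport (H2PO4 speciation from total Pi, pKa 6.75)
  h2po4 <- function(pi, h) pi * h / (h + p$phys$KaPi)
  pII <- h2po4(s$Pi_i, s$H_i); pIX <- h2po4(s$Pi_x, s$H_x)
  J["Pi1"] <- p$Pi1$X * (s$H_x * pII - s$H_i * pIX) / (pII + p$Pi1$kPiH)
  # R29 passive phosphate permeation through the outer membrane
  # (cytosol -> IMS; gamma is the outer-membrane area factor)
  J["Pi2"] <- p$Pi2$p * p$Pi2$gamma * (s$Pi_c - s$Pi_i)
  # R30 adenine nucleotide translocase (dPsi-partitioned, 0.35/0.65)
  J["ANT"] <- p$ANT$X *
    (s$fADP_i / (s$fADP_i + s$fATP_i * exp(-0.35 * u)) -
     s$fADP_x / (s$fADP_x + s$fATP_x * exp(0.65 * u))) *
    s$fADP_i / (s$fADP_i + p$ANT$KmADP)
  # R31 phenomenological TCA-cycle dehydrogenase
  J["DH"] <- p$DH$X * (p$DH$r * s$NAD_x - s$NADH_x) *
             (1 + s$Pi_x / p$DH$kPi1) / (1 + s$Pi_x / p$DH$kPi2)
  # proton-motive energy and complex free energies (kJ/mol)
  dGH  <- F * s$dPsi + RT * log(s$H_i / s$H_x)
  dGC1 <- p$C1$dG0 - RT * log(s$H_x / 1e-4) - RT * log(s$Q_x / s$QH2_x)
  dGC3 <- p$C3$dG0 + RT * log(s$H_x / 1e-4) - RT * log(s$QH2_x / s$Q_x)
  dGC4 <- p$C4$dG0 - 2 * RT * log(s$H_x / 1e-4) - 0.5 * RT * log(s$O2_c * 1e-3)
  # R32 complex I (thermodynamically balanced; negative = reverse transport)
  J["C1"] <- p$C1$X * (exp(-(dGC1 + 4 * dGH) / RT) * s$NADH_x - s$NAD_x)
  # R33 complex III with Pi modulation
  J["C3"] <- p$C3$X *
    (exp(-0.5 * (dGC3 + 4 * dGH - 2 * F * s$dPsi) / RT) * s$Cox_i - s$Cred_i) *
    (1 + s$Pi_x / p$C3$kPi1) / (1 + s$Pi_x / p$C3$kPi2)
  # R34 complex IV with O2 saturation
  J["C4"] <- p$C4$X * (1 / (1 + p$C4$kO2 / s$O2_c)) *
    (s$Cred_i / (s$Cred_i + s$Cox_i)) *
    (exp(-0.5 * (dGC4 + 2 * dGH) / RT) * s$Cred_i * s$O2_c^0.25 -
     s$Cox_i * exp(u))
  # R35 F1F0-ATP synthase (1000 mM = 1 M reference concentration)
  J["F1"] <- p$F1$X * (exp(-(p$F1$dG0 - 3 * dGH) / RT) *
                       (p$MgB$KMgADP / p$MgB$KMgATP) * s$mADP_x * s$Pi_x -
                       1000 * s$mATP_x)
  # R36 proton leak (Goldman-type; series expansion at the removable
  # singularity dPsi = 0)
  J["Hle"] <- if (abs(u) < 1e-4) {
    p$Hle$X * (RT / F) *
      ((s$H_i - s$H_x) + u * (s$H_i - (s$H_i - s$H_x) / 2))
  } else {
    p$Hle$X * s$dPsi * (s$H_i * exp(u) - s$H_x) / expm1(u)
  }
  # R38 potassium/hydrogen antiport
  J["KH"] <- p$KH$X * (s$K_i * s$H_x - s$K_x * s$H_i)
  # R39/R40 oxygen transport: vessel -> extracellular -> cytosol
  J["O2VE"] <- p$O2VE$pA * p$O2VE$gamma * (s$O2_v - s$O2_e)
  J["O2EC"] <- p$O2EC$pA * p$O2EC$gamma * (s$O2_e - s$O2_c)

  aF1 <- p$phys$aF1
  list(fluxes = J[.fluxNames()],
       thermo = c(dGH = dGH, dGC1 = dGC1, dGC3 = dGC3, dGC4 = dGC4, aF1 = aF1))
}

#' Cytosolic Mg/ADP binding polynomial
#'
#' Equilibrium magnesium-bound ADP for a total cytosolic ADP concentration,
#' from the quadratic binding polynomial with total magnesium
#' \code{Mgtot} and dissociation constant \code{K} (both mM).
#'
#' @param adp total cytosolic ADP (mM).
#' @param K Mg-ADP dissociation constant (mM).
#' @param Mgtot total cytosolic magnesium (mM).
#' @return Mg-bound ADP, mADP_c (mM).
#' @export
betaADP <- function(adp, K = 0.347, Mgtot = 5) {
  s <- K + Mgtot + adp
  0.5 * (s - sqrt(s * s - 4 * adp * Mgtot))
}
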