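# SBML Level 3 export/import (xml2-based).
#
# Mapping: all species are exported with boundaryCondition=true and their
# dynamics encoded as rate rules referencing reaction identifiers (reaction
# ids denote rates in SBML L3 math), which reproduces the per-compartment
# volume scalings and coupling coefficients of the printed rate-of-change
# tables exactly.  dPsi is a global parameter governed by a rate rule (it is
# a potential, not a concentration); the synthase coupling factor alpha_F1 is
# a parameter under an assignment rule.

.sbmlParamId <- function(x) gsub(".", "_", x, fixed = TRUE)

# infix kinetic-law formulas in SBML identifiers (species ids as in the
# registry; parameter ids with '_' for '.').  The G6PDH law inlines the
# isomerase flux it is slaved to; thermodynamic terms are inlined via tokens.
.fluxFormulas <- function() {
  dGH  <- "(phys_F * dPsi + phys_RT * log(H_i / H_x))"
  dGC1 <- "(C1_dG0 - phys_RT * log(H_x / 1e-4) - phys_RT * log(Q_x / QH2_x))"
  dGC3 <- "(C3_dG0 + phys_RT * log(H_x / 1e-4) - phys_RT * log(QH2_x / Q_x))"
  dGC4 <- "(C4_dG0 - 2 * phys_RT * log(H_x / 1e-4) - 0.5 * phys_RT * log(O2_c * 1e-3))"
  pgi <- "((PGI_Vf * G6P_c / PGI_Kmf - PGI_Vr * F6P_c / PGI_Kmr) / (1 + G6P_c / PGI_Kmf + F6P_c / PGI_Kmr))"
  h2pi <- "(Pi_i * H_i / (H_i + phys_KaPi))"
  h2px <- "(Pi_x * H_x / (H_x + phys_KaPi))"
  f <- c(
    CK = "CK_X * (CK_K * ADP_c * CrP_c * H_c - ATP_c * Cr_c)",
    AK = "AK_X * (AK_K * ADP_c^2 - ATP_c * AMP_c)",
    ATPase = "ATPase_X / (1 + ATPase_R * Pi_c * ADP_c / ATP_c)",
    HK = "(HK_Vf * GLC_c * ATP_c / (HK_Kmf * (ATP_c + HK_KmATP)) - HK_Vr * G6P_c / HK_Kmr) / (1 + GLC_c / HK_Kmf + G6P_c / HK_Kmr)",
    PGI = "@PGI@",
    PFK = "PFK_Vf * (F6P_c / (PFK_Kmf + F6P_c)) / (1 + PFK_KmATP / ATP_c)",
    FBPA = "FBPA_Vf * F16BP_c / (F16BP_c + FBPA_Kmf)",
    TPI = "TPI_Vf * DHAP_c / (DHAP_c + TPI_Kmf)",
    GAPDH = "GAPDH_Vf * (GAP_c / (GAPDH_Kmf + GAP_c)) / (1 + GAPDH_KmNAD / NAD_c)",
    PGK = "(PGK_Vf * BPG13_c / (PGK_Kmf * (1 + PGK_KmADP / ADP_c)) - PGK_Vr * PG3_c / (PGK_Kmr * (1 + PGK_KmATP / ATP_c))) / (1 + BPG13_c / PGK_Kmf + PG3_c / PGK_Kmr)",
    PGM = "(PGM_Vf * PG3_c / PGM_Kmf - PGM_Vr * PG2_c / PGM_Kmr) / (1 + PG3_c / PGM_Kmf + PG2_c / PGM_Kmr)",
    Enolase = "(Enolase_Vf * PG2_c / Enolase_Kmf - Enolase_Vr * PEP_c / Enolase_Kmr) / (1 + PG2_c / Enolase_Kmf + PEP_c / Enolase_Kmr)",
    PK = "(PK_Vf * PEP_c / (PK_Kmf * (1 + PK_KmADP / ADP_c)) - PK_Vr * PYR_c / PK_Kmr) / (1 + PEP_c / PK_Kmf + PYR_c / PK_Kmr)",
    G6PDH = "G6PDH_Vf * @PGI@ / G6PDH_vss",
    G3PDH = "G3PDH_Vf * DHAP_c * NADH_c / (G3PDH_Kia * G3PDH_KmDHAP + G3PDH_KmDHAP * NADH_c + G3PDH_KmNADH * DHAP_c + DHAP_c * NADH_c)",
    G16BPS = "(G16BPS_Vf * BPG13_c / (G16BPS_Kmf * (1 + G16BPS_KmG1P / G1P_c)) - G16BPS_Vr * PG3_c / (G16BPS_Kmr * (1 + G16BPS_KmG16BP / G16BP_c))) / (1 + BPG13_c / G16BPS_Kmf + PG3_c / G16BPS_Kmr)",
    PGluM = "(PGluM_Vf * G1P_c / PGluM_Kmf - PGluM_Vr * G6P_c / PGluM_Kmr) / (1 + G1P_c / PGluM_Kmf + G6P_c / PGluM_Kmr)",
    UDPGP = "UDPGP_X * (UDPGP_kf * G1P_c - UDPGP_kr * UDPG_c) / (1 + (UDPGP_KmAMP / AMP_c)^1.5)",
    GSD = "GS_VfD * UDPG_c / ((GS_KmD + UDPG_c) * (1 + (GS_KmAMP / AMP_c)^1.5))",
    GSI = "GS_VfI * UDPG_c / ((GS_KmI + UDPG_c) * (1 + (GS_KmAMP / AMP_c)^1.5))",
    GP = "(GP_Vf * GLY_c / GP_Kmf - GP_Vr * G1P_c / GP_Kmr) / ((1 + GLY_c / GP_Kmf + G1P_c / GP_Kmr) * (1 + (GP_KmAMP / AMP_c)^1.5))",
    LDH = "LDH_Vf * (PYR_c / (LDH_Kmf + PYR_c)) / (1 + LDH_KmNADH / NADH_c)",
    LHX = "LHX_Vf * LAC_e / (LAC_e + LHX_Kmf) - LHX_Vr * LAC_c / (LAC_c + LHX_Kmr)",
    LA = "LA_X * (LAC_c * H_c / LA_Km - LACH_c)",
    MB = "MB_ka * Mb_c * O2_c - MB_kd * MbO2_c",
    MgADPi = "MgB_X * (fADP_i * phys_MgI - MgB_KMgADP * mADP_i)",
    MgATPi = "MgB_X * (fATP_i * phys_MgI - MgB_KMgATP * mATP_i)",
    MgADPx = "MgB_X * (fADP_x * Mg_x - MgB_KMgADP * mADP_x)",
    MgATPx = "MgB_X * (fATP_x * Mg_x - MgB_KMgATP * mATP_x)",
    Pi1 = "Pi1_X * (H_x * @H2PI@ - H_i * @H2PX@) / (@H2PI@ + Pi1_kPiH)",
    Pi2 = "Pi2_p * Pi2_gamma * (Pi_c - Pi_i)",
    ANT = "ANT_X * (fADP_i / (fADP_i + fATP_i * exp(-0.35 * phys_F * dPsi / phys_RT)) - fADP_x / (fADP_x + fATP_x * exp(0.65 * phys_F * dPsi / phys_RT))) * fADP_i / (fADP_i + ANT_KmADP)",
    DH = "DH_X * (DH_r * NAD_x - NADH_x) * (1 + Pi_x / DH_kPi1) / (1 + Pi_x / DH_kPi2)",
    C1 = "C1_X * (exp(-(@DGC1@ + 4 * @DGH@) / phys_RT) * NADH_x - NAD_x)",
    C3 = "C3_X * (exp(-0.5 * (@DGC3@ + 4 * @DGH@ - 2 * phys_F * dPsi) / phys_RT) * Cox_i - Cred_i) * (1 + Pi_x / C3_kPi1) / (1 + Pi_x / C3_kPi2)",
    C4 = "C4_X * (1 / (1 + C4_kO2 / O2_c)) * (Cred_i / (Cred_i + Cox_i)) * (exp(-0.5 * (@DGC4@ + 2 * @DGH@) / phys_RT) * Cred_i * O2_c^0.25 - Cox_i * exp(phys_F * dPsi / phys_RT))",
    F1 = "F1_X * (exp(-(F1_dG0 - 3 * @DGH@) / phys_RT) * (MgB_KMgADP / MgB_KMgATP) * mADP_x * Pi_x - 1000 * mATP_x)",
    Hle = "Hle_X * dPsi * (H_i * exp(phys_F * dPsi / phys_RT) - H_x) / (exp(phys_F * dPsi / phys_RT) - 1)",
    KH = "KH_X * (K_i * H_x - K_x * H_i)",
    O2VE = "O2VE_pA * O2VE_gamma * (O2_v - O2_e)",
    O2EC = "O2EC_pA * O2EC_gamma * (O2_e - O2_c)"
  )
  f <- gsub("@PGI@", pgi, f, fixed = TRUE)
  f <- gsub("@DGH@", dGH, f, fixed = TRUE)
  f <- gsub("@DGC1@", dGC1, f, fixed = TRUE)
  f <- gsub("@DGC3@", dGC3, f, fixed = TRUE)
  f <- gsub("@DGC4@", dGC4, f, fixed = TRUE)
  f <- gsub("@H2PI@", h2pi, f, fixed = TRUE)
  f <- gsub("@H2PX@", h2px, f, fixed = TRUE)
  f[.fluxNames()]
}

# rate rules (ODE species + dPsi) in SBML identifiers; reaction ids stand for
# their rates
.odeFormulas <- function() {
  c(
    AMP_c   = "AK / phys_Vc",
    ADP_c   = "(-CK - 2 * AK + HK + PFK - PGK - PK + ATPase - alpha_F1 * F1) / phys_Vc",
    ATP_c   = "(CK + AK - ATPase - HK - PFK + PGK + PK + alpha_F1 * F1) / phys_Vc",
    BPG13_c = "(GAPDH - PGK - G16BPS) / phys_Vc",
    PG2_c   = "(PGM - Enolase) / phys_Vc",
    PG3_c   = "(PGK - PGM + G16BPS) / phys_Vc",
    Cr_c    = "CK / phys_Vc",
    CrP_c   = "-CK / phys_Vc",
    DHAP_c  = "(FBPA - TPI - G3PDH) / phys_Vc",
    F16BP_c = "(PFK - FBPA) / phys_Vc",
    F6P_c   = "(PGI - PFK) / phys_Vc",
    G1P_c   = "(-PGluM - UDPGP + GP - G16BPS) / phys_Vc",
    G6P_c   = "(HK - PGI + PGluM - G6PDH) / phys_Vc",
    GAP_c   = "(FBPA + TPI - GAPDH) / phys_Vc",
    GLY_c   = "(GSD + GSI - GP) / phys_Vc",
    LAC_c   = "(LHX - LA + LDH) / phys_Vc",
    LACH_c  = "LA / phys_Vc",
    Mb_c    = "-MB / phys_Vc",
    MbO2_c  = "MB / phys_Vc",
    O2_c    = "(-phys_o2PerC4 * C4 + O2EC - MB) / phys_Vc",
    PEP_c   = "(Enolase - PK) / phys_Vc",
    Pi_c    = "(-GAPDH + 2 * UDPGP - GP + G6PDH + G3PDH + 2 * G16BPS + ATPase - alpha_F1 * F1) / phys_Vc",
    PYR_c   = "(PK - LDH - phys_aDH * DH) / phys_Vc",
    UDPG_c  = "(UDPGP - GSD - GSI) / phys_Vc",
    mADP_i  = "MgADPi / phys_Vi",
    mATP_i  = "MgATPi / phys_Vi",
    Pi_i    = "(Pi2 - Pi1) / phys_Vi",
    Cox_i   = "(2 * C4 - 2 * C3) / phys_Vi",
    Cred_i  = "(2 * C3 - 2 * C4) / phys_Vi",
    dPsi    = "(4 * C1 + 2 * C3 + 4 * C4 - 3 * F1 - ANT - Hle) / phys_CIM",
    fADP_x  = "(ANT - MgADPx) / phys_Vx",
    mADP_x  = "(MgADPx - F1) / phys_Vx",
    fATP_x  = "(-ANT - MgATPx) / phys_Vx",
    mATP_x  = "(MgATPx + F1) / phys_Vx",
    H_x     = "(H_x / phys_rbuff) * (DH - 5 * C1 - 2 * C3 - 4 * C4 + 2 * F1 + 2 * Pi1 + Hle - KH) / phys_Vx",
    K_x     = "KH / phys_Vx",
    Mg_x    = "(-MgADPx - MgATPx) / phys_Vx",
    NAD_x   = "(C1 - DH) / phys_Vx",
    NADH_x  = "(DH - C1) / phys_Vx",
    Pi_x    = "(Pi1 - F1) / phys_Vx",
    Q_x     = "(C3 - C1) / phys_Vx",
    QH2_x   = "(C1 - C3) / phys_Vx",
    O2_e    = "(O2VE - O2EC) / phys_Ve"
  )
}

.assignmentFormulas <- function() {
  c(
    mADP_c = "0.5 * ((MgBc_KMgADP + phys_MgtotC + ADP_c) - ((MgBc_KMgADP + phys_MgtotC + ADP_c)^2 - 4 * ADP_c * phys_MgtotC)^0.5)",
    Mg_c   = "phys_MgtotC - mADP_c",
    ADP_x  = "fADP_x + mADP_x",
    ATP_x  = "fATP_x + mATP_x",
    ADP_i  = "ADP_x",
    ATP_i  = "ATP_x",
    fADP_i = "ADP_i - mADP_i",
    fATP_i = "ATP_i - mATP_i"
  )
}

# ---- infix -> MathML -------------------------------------------------------

.mathmlNumber <- function(x) {
  sprintf("<cn>%s</cn>", format(as.numeric(x), scientific = FALSE, trim = TRUE))
}

.exprToMathml <- function(e) {
  if (is.numeric(e)) return(.mathmlNumber(e))
  if (is.name(e)) return(sprintf("<ci>%s</ci>", as.character(e)))
  if (!is.call(e)) stop("cannot translate expression element: ", deparse(e))
  op <- as.character(e[[1]])
  args <- as.list(e)[-1]
  if (op == "(") return(.exprToMathml(args[[1]]))
  if (op == "-" && length(args) == 1L)
    return(sprintf("<apply><minus/>%s</apply>", .exprToMathml(args[[1]])))
  tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                "/" = "divide", "^" = "power",
                "exp" = "exp", "log" = "ln",
                stop("operator not supported in SBML math: ", op))
  sprintf("<apply><%s/>%s</apply>", tag,
          paste(vapply(args, .exprToMathml, character(1)), collapse = ""))
}

.mathml <- function(formula) {
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">',
         .exprToMathml(str2lang(formula)), "</math>")
}

# ---- export ----------------------------------------------------------------

#' Export the model as an SBML Level 3 document
#'
#' Writes the five compartments, the full species registry (initial
#' concentrations; constant-kind species flagged constant), every kinetic
#' parameter, all reactions with their kinetic laws, the membrane potential
#' as a global parameter with a rate rule, assignment rules for the
#' assignment-kind species, and rate rules for every ODE species (species are
#' flagged as boundary species so the rate rules are the single source of
#' dynamics, reproducing the printed volume scalings exactly).
#'
#' @param model A [CardioModel-class].
#' @param path output file (.xml).
#' @return the path, invisibly.
#' @export
exportSBML <- function(model, path) {
  cmp <- model@compartments
  sp <- model@species
  sp <- sp[sp$name != "dPsi", ]
  flat <- .flattenParams(model@parameters)
  flat <- flat[!grepl("^const\\.", names(flat))]
  cmpIds <- c(vessel = "vessel", extracellular = "extracellular",
              cytosol = "cytosol", ims = "ims", matrix = "matrix")

  L <- c('<?xml version="1.0" encoding="UTF-8"?>',
         '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
         '<model id="cardiomyosim" name="Cardiomyocyte energy metabolism">',
         "<listOfCompartments>")
  for (i in seq_len(nrow(cmp)))
    L <- c(L, sprintf('<compartment id="%s" size="%s" constant="true" spatialDimensions="3"/>',
                      cmpIds[[cmp$name[i]]], .fmtNum(cmp$volume[i])))
  L <- c(L, "</listOfCompartments>", "<listOfSpecies>")
  for (i in seq_len(nrow(sp)))
    L <- c(L, sprintf(paste0('<species id="%s" compartment="%s" initialConcentration="%s"',
                             ' hasOnlySubstanceUnits="false" boundaryCondition="true" constant="%s"/>'),
                      sp$name[i], cmpIds[[sp$compartment[i]]],
                      .fmtNum(sp$initial[i]),
                      if (sp$kind[i] == "constant") "true" else "false"))
  L <- c(L, "</listOfSpecies>", "<listOfParameters>")
  dpsi0 <- model@species$initial[model@species$name == "dPsi"]
  L <- c(L, sprintf('<parameter id="dPsi" value="%s" constant="false"/>', .fmtNum(dpsi0)),
         sprintf('<parameter id="alpha_F1" value="%s" constant="true"/>', .fmtNum(model@parameters$phys$aF1)))
  for (nm in names(flat))
    L <- c(L, sprintf('<parameter id="%s" value="%s" constant="true"/>',
                      .sbmlParamId(nm), .fmtNum(flat[[nm]])))
  L <- c(L, "</listOfParameters>", "<listOfRules>")
  asg <- .assignmentFormulas()
  for (v in names(asg))
    L <- c(L, sprintf('<assignmentRule variable="%s">%s</assignmentRule>',
                      v, .mathml(asg[[v]])))
  odes <- .odeFormulas()
  for (v in names(odes))
    L <- c(L, sprintf('<rateRule variable="%s">%s</rateRule>',
                      v, .mathml(odes[[v]])))
  L <- c(L, "</listOfRules>", "<listOfReactions>")
  ff <- .fluxFormulas()
  for (v in names(ff))
    L <- c(L, sprintf('<reaction id="%s" reversible="true"><kineticLaw>%s</kineticLaw></reaction>',
                      v, .mathml(ff[[v]])))
  L <- c(L, "</listOfReactions>", "</model>", "</sbml>")

  doc <- xml2::read_xml(paste(L, collapse = ""))  # well-formedness check
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a model from an SBML document written by [exportSBML()]
#'
#' Reads back the compartment sizes, species initial concentrations and
#' parameter values and reconstitutes a [CardioModel-class] (dynamics kinds
#' come from the package registry; the kinetic laws of this model family are
#' native to the package, so a re-simulated import reproduces the original
#' trajectories exactly).
#'
#' @param path SBML file.
#' @return A [CardioModel-class].
#' @export
importSBML <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core")
  getAttrs <- function(xp) {
    nodes <- xml2::xml_find_all(doc, xp, ns)
    list(id = xml2::xml_attr(nodes, "id"), nodes = nodes)
  }
  cmpN <- getAttrs("//s:compartment")
  vol <- stats::setNames(as.numeric(xml2::xml_attr(cmpN$nodes, "size")), cmpN$id)
  spN <- getAttrs("//s:species")
  conc <- stats::setNames(as.numeric(xml2::xml_attr(spN$nodes, "initialConcentration")),
                          spN$id)
  parN <- getAttrs("//s:parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(parN$nodes, "value")), parN$id)

  base <- .modelFromRegistry()
  need <- setdiff(.speciesOrder(), "dPsi")
  miss <- setdiff(need, names(conc))
  if (length(miss))
    stop("document is not a model of this family; missing species: ",
         paste(utils::head(miss, 5), collapse = ", "))
  base@species$initial <- unname(c(conc, dPsi = unname(pval[["dPsi"]]))[
    ifelse(base@species$name == "dPsi", "dPsi", base@species$name)])
  base@compartments$volume <- unname(vol[base@compartments$name])
  ord <- .paramOrder()
  for (nm in ord[!grepl("^const\\.", ord)]) {
    key <- strsplit(nm, ".", fixed = TRUE)[[1]]
    v <- pval[[.sbmlParamId(nm)]]
    if (is.null(v) || is.na(v)) stop("parameter missing from document: ", nm)
    base@parameters[[key[1]]][[key[2]]] <- v
  }
  validObject(base)
  base
}
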