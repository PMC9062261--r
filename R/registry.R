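# Internal registry: canonical species ordering, compartments, dynamics kinds,
# initial values and the flat parameter layout shared with the compiled code.
#
# Suffix convention: _c cytosol, _i intermembrane space, _x matrix,
# _e extracellular space, _v vessel.  dPsi is the inner-membrane potential (mV).
# All concentrations in mM, time in s.

.compartmentTable <- function() {
  data.frame(
    name   = c("vessel", "extracellular", "cytosol", "ims", "matrix"),
    volume = c(0.06842, 0.24063, 1, 0.0715, 0.6435),
    stringsAsFactors = FALSE
  )
}

# Full canonical state ordering (61 concentration species + dPsi).
# kind: "ode", "assignment" or "constant".  pH_c is a bookkeeping row (the
# proton concentration H_c carries the same information); it is excluded from
# flux evaluation.
.speciesTable <- function() {
  sp <- function(name, compartment, unit, initial, kind)
    data.frame(name = name, compartment = compartment, unit = unit,
               initial = initial, kind = kind, stringsAsFactors = FALSE)
  rbind(
    # -- cytosol (Table of cytosolic species) --
    sp("AMP_c",   "cytosol", "mM", 1e-5,      "ode"),
    sp("ADP_c",   "cytosol", "mM", 1e-5,      "ode"),
    sp("ATP_c",   "cytosol", "mM", 7,         "ode"),
    sp("NAD_c",   "cytosol", "mM", 2.2565,    "constant"),
    sp("NADH_c",  "cytosol", "mM", 0.7135,    "constant"),
    sp("GLC_c",   "cytosol", "mM", 1.91,      "constant"),
    sp("BPG13_c", "cytosol", "mM", 8.69e-4,   "ode"),
    sp("PG2_c",   "cytosol", "mM", 0.009,     "ode"),
    sp("PG3_c",   "cytosol", "mM", 0.071,     "ode"),
    sp("Cr_c",    "cytosol", "mM", 0,         "ode"),
    sp("CrP_c",   "cytosol", "mM", 25,        "ode"),
    sp("DHAP_c",  "cytosol", "mM", 0.036,     "ode"),
    sp("F16BP_c", "cytosol", "mM", 6.78e-4,   "ode"),
    sp("F6P_c",   "cytosol", "mM", 0.041,     "ode"),
    sp("G16BP_c", "cytosol", "mM", 0.007,     "constant"),
    sp("G1P_c",   "cytosol", "mM", 0.02,      "ode"),
    sp("G6P_c",   "cytosol", "mM", 0.169,     "ode"),
    sp("GAP_c",   "cytosol", "mM", 0.00162,   "ode"),
    sp("GLY_c",   "cytosol", "mM", 21.4,      "ode"),
    sp("LAC_c",   "cytosol", "mM", 0.247,     "ode"),
    sp("LACH_c",  "cytosol", "mM", 155.84,    "ode"),
    sp("Mb_c",    "cytosol", "mM", 0.00543,   "ode"),
    sp("MbO2_c",  "cytosol", "mM", 0.18457,   "ode"),
    sp("O2_c",    "cytosol", "mM", 0.11017,   "ode"),
    sp("PEP_c",   "cytosol", "mM", 0.013,     "ode"),
    sp("Pi_c",    "cytosol", "mM", 7,         "ode"),
    sp("PYR_c",   "cytosol", "mM", 0.055,     "ode"),
    sp("UDPG_c",  "cytosol", "mM", 0.099,     "ode"),
    sp("H_c",     "cytosol", "mM", 7.94e-4,   "constant"),
    sp("K_c",     "cytosol", "mM", 150,       "constant"),
    sp("Mg_c",    "cytosol", "mM", 5,         "assignment"),
    sp("mADP_c",  "cytosol", "mM", 9.35e-6,   "assignment"),
    sp("pH_c",    "cytosol", "unitless", 7.1, "constant"),
    # -- mitochondrial intermembrane space --
    sp("ADP_i",   "ims", "mM", 10,        "assignment"),
    sp("fADP_i",  "ims", "mM", 10,        "assignment"),
    sp("mADP_i",  "ims", "mM", 0,         "ode"),
    sp("ATP_i",   "ims", "mM", 7,         "assignment"),
    sp("fATP_i",  "ims", "mM", 7,         "assignment"),
    sp("mATP_i",  "ims", "mM", 0,         "ode"),
    sp("H_i",     "ims", "mM", 7.94e-5,   "constant"),
    sp("K_i",     "ims", "mM", 150,       "constant"),
    sp("Pi_i",    "ims", "mM", 1,         "ode"),
    sp("Cox_i",   "ims", "mM", 1.7,       "ode"),
    sp("Cred_i",  "ims", "mM", 1,         "ode"),
    sp("dPsi",    "ims", "mV", 170,       "ode"),
    # -- mitochondrial matrix --
    sp("ADP_x",   "matrix", "mM", 10,      "assignment"),
    sp("fADP_x",  "matrix", "mM", 10,      "ode"),
    sp("mADP_x",  "matrix", "mM", 0,       "ode"),
    sp("ATP_x",   "matrix", "mM", 7,       "assignment"),
    sp("fATP_x",  "matrix", "mM", 7,       "ode"),
    sp("mATP_x",  "matrix", "mM", 0,       "ode"),
    sp("H_x",     "matrix", "mM", 6.31e-5, "ode"),
    sp("K_x",     "matrix", "mM", 140,     "ode"),
    sp("Mg_x",    "matrix", "mM", 5,       "ode"),
    sp("NAD_x",   "matrix", "mM", 1.47,    "ode"),
    sp("NADH_x",  "matrix", "mM", 1.5,     "ode"),
    sp("Pi_x",    "matrix", "mM", 1,       "ode"),
    sp("Q_x",     "matrix", "mM", 0.55,    "ode"),
    sp("QH2_x",   "matrix", "mM", 0.8,     "ode"),
    # -- extracellular space and vessel --
    sp("O2_e",    "extracellular", "mM", 0.1289, "ode"),
    sp("O2_v",    "vessel",        "mM", 0.1326, "constant"),
    sp("LAC_e",   "extracellular", "mM", 0.33,   "constant")
  )
}

.speciesOrder <- function() .speciesTable()$name

.odeSpecies <- function() {
  tab <- .speciesTable()
  tab$name[tab$kind == "ode"]
}

.fluxNames <- function() {
  c("CK", "AK", "ATPase", "HK", "PGI", "PFK", "FBPA", "TPI", "GAPDH",
    "PGK", "PGM", "Enolase", "PK", "G6PDH", "G3PDH", "G16BPS", "PGluM",
    "UDPGP", "GSD", "GSI", "GP", "LDH", "LHX", "LA", "MB",
    "MgADPi", "MgATPi", "MgADPx", "MgATPx", "Pi1", "Pi2", "ANT",
    "DH", "C1", "C3", "C4", "F1", "Hle", "KH", "O2VE", "O2EC")
}

.thermoNames <- function() c("dGH", "dGC1", "dGC3", "dGC4", "aF1")

# Flat parameter layout.  Order must match the PAR_* indices in src/model_rhs.c;
# the compiled/reference equivalence tests guard the correspondence.
.paramOrder <- function() {
  c("phys.F", "phys.RT", "phys.CIM", "phys.rbuff", "phys.aDH",
    "phys.MgtotC", "phys.MgI", "phys.KaPi",
    "phys.Vc", "phys.Vi", "phys.Vx", "phys.Ve", "phys.Vv",
    "CK.X", "CK.K",
    "AK.X", "AK.K",
    "ATPase.X", "ATPase.R",
    "HK.Vf", "HK.Kmf", "HK.KmATP", "HK.Vr", "HK.Kmr",
    "PGI.Vf", "PGI.Kmf", "PGI.Vr", "PGI.Kmr",
    "PFK.Vf", "PFK.Kmf", "PFK.KmATP",
    "FBPA.Vf", "FBPA.Kmf",
    "TPI.Vf", "TPI.Kmf",
    "GAPDH.Vf", "GAPDH.Kmf", "GAPDH.KmNAD",
    "PGK.Vf", "PGK.Kmf", "PGK.KmADP", "PGK.Vr", "PGK.Kmr", "PGK.KmATP",
    "PGM.Vf", "PGM.Kmf", "PGM.Vr", "PGM.Kmr",
    "Enolase.Vf", "Enolase.Kmf", "Enolase.Vr", "Enolase.Kmr",
    "PK.Vf", "PK.Kmf", "PK.KmADP", "PK.Vr", "PK.Kmr",
    "G6PDH.Vf", "G6PDH.vss",
    "G3PDH.Vf", "G3PDH.Kia", "G3PDH.KmDHAP", "G3PDH.KmNADH",
    "G16BPS.Vf", "G16BPS.Kmf", "G16BPS.KmG1P",
    "G16BPS.Vr", "G16BPS.Kmr", "G16BPS.KmG16BP",
    "PGluM.Vf", "PGluM.Kmf", "PGluM.Vr", "PGluM.Kmr",
    "UDPGP.X", "UDPGP.kf", "UDPGP.kr", "UDPGP.KmAMP",
    "GS.VfD", "GS.KmD", "GS.VfI", "GS.KmI", "GS.KmAMP",
    "GP.Vf", "GP.Kmf", "GP.Vr", "GP.Kmr", "GP.KmAMP",
    "LDH.Vf", "LDH.Kmf", "LDH.KmNADH",
    "LHX.Vf", "LHX.Kmf", "LHX.Vr", "LHX.Kmr",
    "LA.X", "LA.Km",
    "MB.ka", "MB.kd",
    "MgBc.KMgADP",
    "MgB.X", "MgB.KMgADP", "MgB.KMgATP",
    "Pi1.X", "Pi1.kPiH",
    "Pi2.p", "Pi2.gamma",
    "ANT.X", "ANT.KmADP",
    "DH.X", "DH.r", "DH.kPi1", "DH.kPi2",
    "C1.X", "C1.dG0",
    "C3.X", "C3.dG0", "C3.kPi1", "C3.kPi2",
    "C4.X", "C4.kO2", "C4.dG0",
    "F1.X", "F1.dG0",
    "Hle.X",
    "KH.X",
    "O2VE.pA", "O2VE.gamma",
    "O2EC.pA", "O2EC.gamma",
    "const.NAD_c", "const.NADH_c", "const.GLC_c", "const.G16BP_c",
    "const.H_c", "const.K_c", "const.H_i", "const.K_i",
    "const.O2_v", "const.LAC_e",
    "phys.o2PerC4", "phys.aF1")
}

# Default kinetic parameters (printed per-reaction tables), nested by reaction.
# phys.CIM and phys.rbuff are adopted from the Beard (2005) mitochondrial model
# (inner-membrane capacitance 6.75e-6 mol/(l*mV) -> 6.75e-3 mM/mV; matrix proton
# buffering x_buff = 100 1/M -> r_buff = 10 mM); they are not part of the printed
# parameter tables.
.defaultParams <- function() {
  R  <- 8.314       # J/(mol K)
  Tk <- 310         # K
  list(
    phys = list(
      F      = 0.096484,           # kJ/(mol mV)
      RT     = R * Tk / 1000,      # kJ/mol
      CIM    = 6.75e-3,            # mM/mV (imported from Beard 2005)
      rbuff  = 10,                 # mM    (imported from Beard 2005)
      aDH    = 0.6435,             # V_matrix / V_cytosol (default choice)
      MgtotC = 5,                  # mM total cytosolic Mg
      MgI    = 5,                  # mM IMS free Mg (fixed; not a tabulated species)
      KaPi   = 10^(-6.75) * 1000,  # mM, phosphate pKa 6.75
      o2PerC4 = 0.5,               # O2 consumed per complex-IV event (R34: 1/2 O2)
      aF1    = 1 / 0.6435,         # synthase->cytosol coupling, (fATP/ATP)0 * Vc/Vx
      glcCoupling = 1,             # clamped glucose follows the perfusion fraction^k
      Vc = 1, Vi = 0.0715, Vx = 0.6435, Ve = 0.24063, Vv = 0.06842
    ),
    CK      = list(X = 10000, K = 1660000),
    AK      = list(X = 10000, K = 1),
    ATPase  = list(X = 0.39, R = 0.0658),
    HK      = list(Vf = 0.550, Kmf = 0.072, KmATP = 0.236,
                   Vr = 1.06e-4, Kmr = 0.042),
    PGI     = list(Vf = 10.067, Kmf = 0.425, Vr = 9.6, Kmr = 0.175),
    PFK     = list(Vf = 1.328, Kmf = 0.224, KmATP = 0.127),
    FBPA    = list(Vf = 0.992, Kmf = 0.038),
    TPI     = list(Vf = 5.933, Kmf = 1.53),
    GAPDH   = list(Vf = 5.35, Kmf = 0.042, KmNAD = 0.058),
    PGK     = list(Vf = 251, Kmf = 0.021, KmADP = 0.565,
                   Vr = 15.98, Kmr = 0.51, KmATP = 0.008),
    PGM     = list(Vf = 11.233, Kmf = 0.145, Vr = 48.0, Kmr = 0.139),
    Enolase = list(Vf = 1.85, Kmf = 0.045, Vr = 2.00, Kmr = 0.089),
    PK      = list(Vf = 9.433, Kmf = 0.11, KmADP = 0.00268,
                   Vr = 0.00105, Kmr = 10),
    G6PDH   = list(Vf = 0.095, vss = 0.125),
    G3PDH   = list(Vf = 0.095, Kia = 0.095, KmDHAP = 0.095, KmNADH = 0.095),
    G16BPS  = list(Vf = 10, Kmf = 0.021, KmG1P = 0.008,
                   Vr = 6, Kmr = 0.51, KmG16BP = 0.565),
    PGluM   = list(Vf = 1.933, Kmf = 0.045, Vr = 1.12, Kmr = 0.67),
    UDPGP   = list(X = 10000, kf = 4.36, kr = 0.881, KmAMP = 0.016),
    GS      = list(VfD = 0.147, KmD = 1.42, VfI = 0.147, KmI = 0.08,
                   KmAMP = 0.016),
    GP      = list(Vf = 0.782, Kmf = 0.1, Vr = 55.83, Kmr = 5, KmAMP = 0.016),
    LDH     = list(Vf = 23.93, Kmf = 0.125, KmNADH = 0.001),
    LHX     = list(Vf = 0.048, Kmf = 2.2, Vr = 0.182, Kmr = 6.92),
    LA      = list(X = 10000, Km = 1.259e-6),
    MB      = list(ka = 15400, kd = 60),
    MgBc    = list(KMgADP = 0.347),
    MgB     = list(X = 1000, KMgADP = 0.347, KMgATP = 0.024),
    Pi1     = list(X = 3.394e5, kPiH = 0.4508),
    Pi2     = list(p = 327, gamma = 5.99),
    ANT     = list(X = 4.752, KmADP = 3.5e-3),
    DH      = list(X = 0.092, r = 4.581, kPi1 = 0.134, kPi2 = 0.677),
    C1      = list(X = 0.369, dG0 = -69.37),
    C3      = list(X = 0.092, dG0 = -32.53, kPi1 = 0.192, kPi2 = 25.31),
    C4      = list(X = 2.267e-5, kO2 = 3e-3, dG0 = -122.94),
    F1      = list(X = 2.267e-5, dG0 = 36.03),
    Hle     = list(X = 0.25),
    KH      = list(X = 29802),
    O2VE    = list(pA = 50, gamma = 0.284),
    O2EC    = list(pA = 10, gamma = 0.241)
  )
}

# Reaction -> "activity" parameters (maximal-rate constants scaled jointly so
# that equilibrium constants are preserved) and pathway annotation.
.activityMap <- function() {
  list(
    CK      = list(pars = "CK.X",                     pathway = "Energy Buffer"),
    AK      = list(pars = "AK.X",                     pathway = "Energy Buffer"),
    ATPase  = list(pars = "ATPase.X",                 pathway = "ATP Consumption"),
    HK      = list(pars = c("HK.Vf", "HK.Vr"),        pathway = "Glycolysis"),
    PGI     = list(pars = c("PGI.Vf", "PGI.Vr"),      pathway = "Glycolysis"),
    PFK     = list(pars = "PFK.Vf",                   pathway = "Glycolysis"),
    FBPA    = list(pars = "FBPA.Vf",                  pathway = "Glycolysis"),
    TPI     = list(pars = "TPI.Vf",                   pathway = "Glycolysis"),
    GAPDH   = list(pars = "GAPDH.Vf",                 pathway = "Glycolysis"),
    PGK     = list(pars = c("PGK.Vf", "PGK.Vr"),      pathway = "Glycolysis"),
    PGM     = list(pars = c("PGM.Vf", "PGM.Vr"),      pathway = "Glycolysis"),
    Enolase = list(pars = c("Enolase.Vf", "Enolase.Vr"), pathway = "Glycolysis"),
    PK      = list(pars = c("PK.Vf", "PK.Vr"),        pathway = "Glycolysis"),
    G6PDH   = list(pars = "G6PDH.Vf",                 pathway = "Pentose Phosphate"),
    G3PDH   = list(pars = "G3PDH.Vf",                 pathway = "Glycerol Phosphate"),
    G16BPS  = list(pars = c("G16BPS.Vf", "G16BPS.Vr"), pathway = "Glycolysis"),
    PGluM   = list(pars = c("PGluM.Vf", "PGluM.Vr"),  pathway = "Glycogen"),
    UDPGP   = list(pars = "UDPGP.X",                  pathway = "Glycogen"),
    GS      = list(pars = c("GS.VfD", "GS.VfI"),      pathway = "Glycogen"),
    GP      = list(pars = c("GP.Vf", "GP.Vr"),        pathway = "Glycogen"),
    LDH     = list(pars = "LDH.Vf",                   pathway = "Lactate"),
    LHX     = list(pars = c("LHX.Vf", "LHX.Vr"),      pathway = "Lactate"),
    LA      = list(pars = "LA.X",                     pathway = "Lactate"),
    MB      = list(pars = c("MB.ka", "MB.kd"),        pathway = "Oxygen Buffer"),
    MgB     = list(pars = "MgB.X",                    pathway = "Mg Binding"),
    Pi1     = list(pars = "Pi1.X",                    pathway = "Pi Transport"),
    Pi2     = list(pars = "Pi2.p",                    pathway = "Pi Transport"),
    ANT     = list(pars = "ANT.X",                    pathway = "ATP/ADP Transporter"),
    DH      = list(pars = "DH.X",                     pathway = "TCA Cycle"),
    C1      = list(pars = "C1.X",                     pathway = "Oxidative Phosphorylation"),
    C3      = list(pars = "C3.X",                     pathway = "Oxidative Phosphorylation"),
    C4      = list(pars = "C4.X",                     pathway = "Oxidative Phosphorylation"),
    F1      = list(pars = "F1.X",                     pathway = "Oxidative Phosphorylation"),
    Hle     = list(pars = "Hle.X",                    pathway = "Proton Leak"),
    KH      = list(pars = "KH.X",                     pathway = "K/H Transport"),
    O2VE    = list(pars = "O2VE.pA",                  pathway = "Oxygen Transport"),
    O2EC    = list(pars = "O2EC.pA",                  pathway = "Oxygen Transport")
  )
}

# Conserved pools (pairs whose printed rate rows cancel exactly).
.conservedPools <- function() {
  list(
    creatine   = c("Cr_c", "CrP_c"),
    myoglobin  = c("Mb_c", "MbO2_c"),
    ubiquinone = c("Q_x", "QH2_x"),
    matrixNAD  = c("NAD_x", "NADH_x"),
    cytochromeC = c("Cox_i", "Cred_i"),
    matrixAdenine = c("ATP_x", "ADP_x")
  )
}

.flattenParams <- function(params) {
  ord <- .paramOrder()
  out <- numeric(length(ord))
  names(out) <- ord
  for (i in seq_along(ord)) {
    key <- strsplit(ord[i], ".", fixed = TRUE)[[1]]
    if (key[1] == "const") next  # filled by caller from species table
    val <- params[[key[1]]][[key[2]]]
    if (is.null(val)) stop("parameter not found: ", ord[i])
    out[i] <- val
  }
  out
}

# Full flat vector including constant-species values taken from the model's
# initial values.  `fraction` is the perfusion fraction of a protocol
# segment: it scales the vessel oxygen linearly and the clamped cytosolic
# glucose as fraction^glcCoupling (vessel occlusion interrupts substrate
# delivery along with oxygen; glcCoupling = 0 keeps glucose clamped).
.paramVector <- function(model, fraction = 1, o2v = NULL) {
  p <- .flattenParams(model@parameters)
  init <- initialState(model)
  consts <- c("NAD_c", "NADH_c", "GLC_c", "G16BP_c", "H_c", "K_c",
              "H_i", "K_i", "O2_v", "LAC_e")
  p[paste0("const.", consts)] <- init[consts]
  p["const.O2_v"] <- if (!is.null(o2v)) o2v else fraction * init[["O2_v"]]
  p["const.GLC_c"] <- init[["GLC_c"]] *
    fraction^(model@parameters$phys$glcCoupling %||% 0)
  p
}
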