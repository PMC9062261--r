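/* Compiled right-hand side of the cardiomyocyte metabolism model.
 *
 * State, flux and parameter orderings must match the R-side registry
 * (R/registry.R); the reference/compiled equivalence tests guard this.
 * Units: concentrations mM, membrane potential mV, time s, energies kJ/mol.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NFULL 62
#define NODE  43
#define NFLUX 41
#define NEXTRA 5
#define NPAR  141

/* ---- full-state indices (registry order) ---- */
enum {
  iAMP_c, iADP_c, iATP_c, iNAD_c, iNADH_c, iGLC_c, iBPG13_c, iPG2_c, iPG3_c,
  iCr_c, iCrP_c, iDHAP_c, iF16BP_c, iF6P_c, iG16BP_c, iG1P_c, iG6P_c, iGAP_c,
  iGLY_c, iLAC_c, iLACH_c, iMb_c, iMbO2_c, iO2_c, iPEP_c, iPi_c, iPYR_c,
  iUDPG_c, iH_c, iK_c, iMg_c, imADP_c, ipH_c,
  iADP_i, ifADP_i, imADP_i, iATP_i, ifATP_i, imATP_i, iH_i, iK_i, iPi_i,
  iCox_i, iCred_i, idPsi,
  iADP_x, ifADP_x, imADP_x, iATP_x, ifATP_x, imATP_x, iH_x, iK_x, iMg_x,
  iNAD_x, iNADH_x, iPi_x, iQ_x, iQH2_x,
  iO2_e, iO2_v, iLAC_e
};

/* ODE subset -> full-state index */
static const int ODE_IDX[NODE] = {
  iAMP_c, iADP_c, iATP_c, iBPG13_c, iPG2_c, iPG3_c, iCr_c, iCrP_c, iDHAP_c,
  iF16BP_c, iF6P_c, iG1P_c, iG6P_c, iGAP_c, iGLY_c, iLAC_c, iLACH_c, iMb_c,
  iMbO2_c, iO2_c, iPEP_c, iPi_c, iPYR_c, iUDPG_c,
  imADP_i, imATP_i, iPi_i, iCox_i, iCred_i, idPsi,
  ifADP_x, imADP_x, ifATP_x, imATP_x, iH_x, iK_x, iMg_x,
  iNAD_x, iNADH_x, iPi_x, iQ_x, iQH2_x,
  iO2_e
};

/* ---- flux indices ---- */
enum {
  jCK, jAK, jATPase, jHK, jPGI, jPFK, jFBPA, jTPI, jGAPDH, jPGK, jPGM,
  jENO, jPK, jG6PDH, jG3PDH, jG16BPS, jPGluM, jUDPGP, jGSD, jGSI, jGP,
  jLDH, jLHX, jLA, jMB, jMgADPi, jMgATPi, jMgADPx, jMgATPx, jPi1, jPi2,
  jANT, jDH, jC1, jC3, jC4, jF1, jHle, jKH, jO2VE, jO2EC
};

/* ---- parameter indices (R .paramOrder) ---- */
enum {
  pF, pRT, pCIM, pRBUFF, pADH, pMGTOTC, pMGI, pKAPI, pVC, pVI, pVX, pVE, pVV,
  pCK_X, pCK_K, pAK_X, pAK_K, pATPASE_X, pATPASE_R,
  pHK_VF, pHK_KMF, pHK_KMATP, pHK_VR, pHK_KMR,
  pPGI_VF, pPGI_KMF, pPGI_VR, pPGI_KMR,
  pPFK_VF, pPFK_KMF, pPFK_KMATP,
  pFBPA_VF, pFBPA_KMF, pTPI_VF, pTPI_KMF,
  pGAPDH_VF, pGAPDH_KMF, pGAPDH_KMNAD,
  pPGK_VF, pPGK_KMF, pPGK_KMADP, pPGK_VR, pPGK_KMR, pPGK_KMATP,
  pPGM_VF, pPGM_KMF, pPGM_VR, pPGM_KMR,
  pENO_VF, pENO_KMF, pENO_VR, pENO_KMR,
  pPK_VF, pPK_KMF, pPK_KMADP, pPK_VR, pPK_KMR,
  pG6PDH_VF, pG6PDH_VSS,
  pG3PDH_VF, pG3PDH_KIA, pG3PDH_KMDHAP, pG3PDH_KMNADH,
  pG16BPS_VF, pG16BPS_KMF, pG16BPS_KMG1P,
  pG16BPS_VR, pG16BPS_KMR, pG16BPS_KMG16BP,
  pPGLUM_VF, pPGLUM_KMF, pPGLUM_VR, pPGLUM_KMR,
  pUDPGP_X, pUDPGP_KF, pUDPGP_KR, pUDPGP_KMAMP,
  pGS_VFD, pGS_KMD, pGS_VFI, pGS_KMI, pGS_KMAMP,
  pGP_VF, pGP_KMF, pGP_VR, pGP_KMR, pGP_KMAMP,
  pLDH_VF, pLDH_KMF, pLDH_KMNADH,
  pLHX_VF, pLHX_KMF, pLHX_VR, pLHX_KMR,
  pLA_X, pLA_KM, pMB_KA, pMB_KD,
  pMGBC_KMGADP, pMGB_X, pMGB_KMGADP, pMGB_KMGATP,
  pPI1_X, pPI1_KPIH, pPI2_P, pPI2_GAMMA,
  pANT_X, pANT_KMADP,
  pDH_X, pDH_R, pDH_KPI1, pDH_KPI2,
  pC1_X, pC1_DG0,
  pC3_X, pC3_DG0, pC3_KPI1, pC3_KPI2,
  pC4_X, pC4_KO2, pC4_DG0,
  pF1_X, pF1_DG0,
  pHLE_X, pKH_X,
  pO2VE_PA, pO2VE_GAMMA, pO2EC_PA, pO2EC_GAMMA,
  pcNAD_C, pcNADH_C, pcGLC_C, pcG16BP_C, pcH_C, pcK_C, pcH_I, pcK_I,
  pcO2_V, pcLAC_E, pO2PERC4, pAF1
};

static double parms[NPAR];

static double posguard(double x) { return x > 1e-15 ? x : 1e-15; }

/* cytosolic Mg-ADP binding polynomial (total ADP -> bound mADP) */
static double beta_adp(double adp, double K, double mgtot)
{
  double s = K + mgtot + adp;
  return 0.5 * (s - sqrt(s * s - 4.0 * adp * mgtot));
}

/* Assemble the full state from the ODE subset + constants + assignments.
 * Concentrations are clamped at zero: implicit solvers probe trial states
 * with small negative components, and several rate laws (ANT partition
 * denominators, logarithmic free energies) are only defined for
 * non-negative concentrations.  dPsi (a potential) is not clamped. */
static void full_state(const double *y, const double *p, double *s)
{
  int k;
  for (k = 0; k < NFULL; k++) s[k] = 0.0;
  for (k = 0; k < NODE; k++) {
    double v = y[k];
    if (ODE_IDX[k] != idPsi && v < 0.0) v = 0.0;
    s[ODE_IDX[k]] = v;
  }
  s[iNAD_c]   = p[pcNAD_C];
  s[iNADH_c]  = p[pcNADH_C];
  s[iGLC_c]   = p[pcGLC_C];
  s[iG16BP_c] = p[pcG16BP_C];
  s[iH_c]     = p[pcH_C];
  s[iK_c]     = p[pcK_C];
  s[iH_i]     = p[pcH_I];
  s[iK_i]     = p[pcK_I];
  s[iO2_v]    = p[pcO2_V];
  s[iLAC_e]   = p[pcLAC_E];
  s[ipH_c]    = 7.1; /* bookkeeping only; dynamics use H_c */
  s[imADP_c]  = beta_adp(s[iADP_c], p[pMGBC_KMGADP], p[pMGTOTC]);
  s[iMg_c]    = p[pMGTOTC] - s[imADP_c];
  s[iADP_x]   = s[ifADP_x] + s[imADP_x];
  s[iATP_x]   = s[ifATP_x] + s[imATP_x];
  s[iADP_i]   = s[iADP_x];
  s[iATP_i]   = s[iATP_x];
  s[ifADP_i]  = s[iADP_i] - s[imADP_i]; if (s[ifADP_i] < 0.0) s[ifADP_i] = 0.0;
  s[ifATP_i]  = s[iATP_i] - s[imATP_i]; if (s[ifATP_i] < 0.0) s[ifATP_i] = 0.0;
}

static void compute_fluxes(const double *s, const double *p,
                           double *J, double *extra)
{
  const double F = p[pF], RT = p[pRT];
  const double u = F * s[idPsi] / RT;
  double dGH, dGC1, dGC3, dGC4, ampmod, pII, pIX, o2g;

  J[jCK] = p[pCK_X] * (p[pCK_K] * s[iADP_c] * s[iCrP_c] * s[iH_c]
                       - s[iATP_c] * s[iCr_c]);
  J[jAK] = p[pAK_X] * (p[pAK_K] * s[iADP_c] * s[iADP_c]
                       - s[iATP_c] * s[iAMP_c]);
  J[jATPase] = s[iATP_c] > 0.0
    ? p[pATPASE_X] / (1.0 + p[pATPASE_R] * s[iPi_c] * s[iADP_c] / s[iATP_c])
    : 0.0;
  J[jHK] = (p[pHK_VF] * s[iGLC_c] * s[iATP_c]
              / (p[pHK_KMF] * (s[iATP_c] + p[pHK_KMATP]))
            - p[pHK_VR] * s[iG6P_c] / p[pHK_KMR])
           / (1.0 + s[iGLC_c] / p[pHK_KMF] + s[iG6P_c] / p[pHK_KMR]);
  J[jPGI] = (p[pPGI_VF] * s[iG6P_c] / p[pPGI_KMF]
             - p[pPGI_VR] * s[iF6P_c] / p[pPGI_KMR])
            / (1.0 + s[iG6P_c] / p[pPGI_KMF] + s[iF6P_c] / p[pPGI_KMR]);
  J[jPFK] = p[pPFK_VF] * (s[iF6P_c] / (p[pPFK_KMF] + s[iF6P_c]))
            / (1.0 + p[pPFK_KMATP] / s[iATP_c]);
  J[jFBPA] = p[pFBPA_VF] * s[iF16BP_c] / (s[iF16BP_c] + p[pFBPA_KMF]);
  J[jTPI] = p[pTPI_VF] * s[iDHAP_c] / (s[iDHAP_c] + p[pTPI_KMF]);
  J[jGAPDH] = p[pGAPDH_VF] * (s[iGAP_c] / (p[pGAPDH_KMF] + s[iGAP_c]))
              / (1.0 + p[pGAPDH_KMNAD] / s[iNAD_c]);
  J[jPGK] = (p[pPGK_VF] * s[iBPG13_c]
               / (p[pPGK_KMF] * (1.0 + p[pPGK_KMADP] / s[iADP_c]))
             - p[pPGK_VR] * s[iPG3_c]
               / (p[pPGK_KMR] * (1.0 + p[pPGK_KMATP] / s[iATP_c])))
            / (1.0 + s[iBPG13_c] / p[pPGK_KMF] + s[iPG3_c] / p[pPGK_KMR]);
  J[jPGM] = (p[pPGM_VF] * s[iPG3_c] / p[pPGM_KMF]
             - p[pPGM_VR] * s[iPG2_c] / p[pPGM_KMR])
            / (1.0 + s[iPG3_c] / p[pPGM_KMF] + s[iPG2_c] / p[pPGM_KMR]);
  J[jENO] = (p[pENO_VF] * s[iPG2_c] / p[pENO_KMF]
             - p[pENO_VR] * s[iPEP_c] / p[pENO_KMR])
            / (1.0 + s[iPG2_c] / p[pENO_KMF] + s[iPEP_c] / p[pENO_KMR]);
  J[jPK] = (p[pPK_VF] * s[iPEP_c]
              / (p[pPK_KMF] * (1.0 + p[pPK_KMADP] / s[iADP_c]))
            - p[pPK_VR] * s[iPYR_c] / p[pPK_KMR])
           / (1.0 + s[iPEP_c] / p[pPK_KMF] + s[iPYR_c] / p[pPK_KMR]);
  J[jG6PDH] = p[pG6PDH_VF] * J[jPGI] / p[pG6PDH_VSS];
  J[jG3PDH] = p[pG3PDH_VF] * s[iDHAP_c] * s[iNADH_c]
              / (p[pG3PDH_KIA] * p[pG3PDH_KMDHAP]
                 + p[pG3PDH_KMDHAP] * s[iNADH_c]
                 + p[pG3PDH_KMNADH] * s[iDHAP_c]
                 + s[iDHAP_c] * s[iNADH_c]);
  J[jG16BPS] = (p[pG16BPS_VF] * s[iBPG13_c]
                  / (p[pG16BPS_KMF] * (1.0 + p[pG16BPS_KMG1P] / s[iG1P_c]))
                - p[pG16BPS_VR] * s[iPG3_c]
                  / (p[pG16BPS_KMR]
                     * (1.0 + p[pG16BPS_KMG16BP] / s[iG16BP_c])))
               / (1.0 + s[iBPG13_c] / p[pG16BPS_KMF]
                  + s[iPG3_c] / p[pG16BPS_KMR]);
  J[jPGluM] = (p[pPGLUM_VF] * s[iG1P_c] / p[pPGLUM_KMF]
               - p[pPGLUM_VR] * s[iG6P_c] / p[pPGLUM_KMR])
              / (1.0 + s[iG1P_c] / p[pPGLUM_KMF] + s[iG6P_c] / p[pPGLUM_KMR]);
  ampmod = s[iAMP_c] > 0.0
    ? 1.0 + pow(p[pUDPGP_KMAMP] / s[iAMP_c], 1.5) : R_PosInf;
  J[jUDPGP] = p[pUDPGP_X]
              * (p[pUDPGP_KF] * s[iG1P_c] - p[pUDPGP_KR] * s[iUDPG_c])
              / ampmod;
  ampmod = s[iAMP_c] > 0.0
    ? 1.0 + pow(p[pGS_KMAMP] / s[iAMP_c], 1.5) : R_PosInf;
  J[jGSD] = p[pGS_VFD] * s[iUDPG_c] / ((p[pGS_KMD] + s[iUDPG_c]) * ampmod);
  J[jGSI] = p[pGS_VFI] * s[iUDPG_c] / ((p[pGS_KMI] + s[iUDPG_c]) * ampmod);
  ampmod = s[iAMP_c] > 0.0
    ? 1.0 + pow(p[pGP_KMAMP] / s[iAMP_c], 1.5) : R_PosInf;
  J[jGP] = (p[pGP_VF] * s[iGLY_c] / p[pGP_KMF]
            - p[pGP_VR] * s[iG1P_c] / p[pGP_KMR])
           / ((1.0 + s[iGLY_c] / p[pGP_KMF] + s[iG1P_c] / p[pGP_KMR])
              * ampmod);
  J[jLDH] = p[pLDH_VF] * (s[iPYR_c] / (p[pLDH_KMF] + s[iPYR_c]))
            / (1.0 + p[pLDH_KMNADH] / s[iNADH_c]);
  J[jLHX] = p[pLHX_VF] * s[iLAC_e] / (s[iLAC_e] + p[pLHX_KMF])
            - p[pLHX_VR] * s[iLAC_c] / (s[iLAC_c] + p[pLHX_KMR]);
  J[jLA] = p[pLA_X] * (s[iLAC_c] * s[iH_c] / p[pLA_KM] - s[iLACH_c]);
  J[jMB] = p[pMB_KA] * s[iMb_c] * s[iO2_c] - p[pMB_KD] * s[iMbO2_c];
  J[jMgADPi] = p[pMGB_X] * (s[ifADP_i] * p[pMGI]
                            - p[pMGB_KMGADP] * s[imADP_i]);
  J[jMgATPi] = p[pMGB_X] * (s[ifATP_i] * p[pMGI]
                            - p[pMGB_KMGATP] * s[imATP_i]);
  J[jMgADPx] = p[pMGB_X] * (s[ifADP_x] * s[iMg_x]
                            - p[pMGB_KMGADP] * s[imADP_x]);
  J[jMgATPx] = p[pMGB_X] * (s[ifATP_x] * s[iMg_x]
                            - p[pMGB_KMGATP] * s[imATP_x]);
  pII = s[iPi_i] * s[iH_i] / (s[iH_i] + p[pKAPI]);
  pIX = s[iPi_x] * s[iH_x] / (s[iH_x] + p[pKAPI]);
  J[jPi1] = p[pPI1_X] * (s[iH_x] * pII - s[iH_i] * pIX)
            / (pII + p[pPI1_KPIH]);
  J[jPi2] = p[pPI2_P] * p[pPI2_GAMMA] * (s[iPi_c] - s[iPi_i]);
  J[jANT] = p[pANT_X]
            * (s[ifADP_i] / (s[ifADP_i] + s[ifATP_i] * exp(-0.35 * u))
               - s[ifADP_x] / (s[ifADP_x] + s[ifATP_x] * exp(0.65 * u)))
            * s[ifADP_i] / (s[ifADP_i] + p[pANT_KMADP]);
  J[jDH] = p[pDH_X] * (p[pDH_R] * s[iNAD_x] - s[iNADH_x])
           * (1.0 + s[iPi_x] / p[pDH_KPI1])
           / (1.0 + s[iPi_x] / p[pDH_KPI2]);
  dGH  = F * s[idPsi] + RT * log(posguard(s[iH_i]) / posguard(s[iH_x]));
  dGC1 = p[pC1_DG0] - RT * log(posguard(s[iH_x]) / 1e-4)
         - RT * log(posguard(s[iQ_x]) / posguard(s[iQH2_x]));
  dGC3 = p[pC3_DG0] + RT * log(posguard(s[iH_x]) / 1e-4)
         - RT * log(posguard(s[iQH2_x]) / posguard(s[iQ_x]));
  o2g  = posguard(s[iO2_c]);
  dGC4 = p[pC4_DG0] - 2.0 * RT * log(posguard(s[iH_x]) / 1e-4)
         - 0.5 * RT * log(o2g * 1e-3);
  J[jC1] = p[pC1_X] * (exp(-(dGC1 + 4.0 * dGH) / RT) * s[iNADH_x]
                       - s[iNAD_x]);
  J[jC3] = p[pC3_X]
           * (exp(-0.5 * (dGC3 + 4.0 * dGH - 2.0 * F * s[idPsi]) / RT)
                * s[iCox_i] - s[iCred_i])
           * (1.0 + s[iPi_x] / p[pC3_KPI1])
           / (1.0 + s[iPi_x] / p[pC3_KPI2]);
  J[jC4] = p[pC4_X] * (1.0 / (1.0 + p[pC4_KO2] / o2g))
           * (s[iCred_i] / posguard(s[iCred_i] + s[iCox_i]))
           * (exp(-0.5 * (dGC4 + 2.0 * dGH) / RT) * s[iCred_i]
                * pow(o2g, 0.25)
              - s[iCox_i] * exp(u));
  J[jF1] = p[pF1_X] * (exp(-(p[pF1_DG0] - 3.0 * dGH) / RT)
                         * (p[pMGB_KMGADP] / p[pMGB_KMGATP])
                         * s[imADP_x] * s[iPi_x]
                       - 1000.0 * s[imATP_x]);
  if (fabs(u) < 1e-4) {
    J[jHle] = p[pHLE_X] * (RT / F)
              * ((s[iH_i] - s[iH_x])
                 + u * (s[iH_i] - (s[iH_i] - s[iH_x]) / 2.0));
  } else {
    J[jHle] = p[pHLE_X] * s[idPsi]
              * (s[iH_i] * exp(u) - s[iH_x]) / expm1(u);
  }
  J[jKH] = p[pKH_X] * (s[iK_i] * s[iH_x] - s[iK_x] * s[iH_i]);
  J[jO2VE] = p[pO2VE_PA] * p[pO2VE_GAMMA] * (s[iO2_v] - s[iO2_e]);
  J[jO2EC] = p[pO2EC_PA] * p[pO2EC_GAMMA] * (s[iO2_e] - s[iO2_c]);

  extra[0] = dGH; extra[1] = dGC1; extra[2] = dGC3; extra[3] = dGC4;
  extra[4] = p[pAF1];
}

static void assemble_ydot(const double *s, const double *p, const double *J,
                          double aF1, double *dfull)
{
  const double Vc = p[pVC], Vi = p[pVI], Vx = p[pVX], Ve = p[pVE];
  const double aDH = p[pADH];
  /* The synthase->cytosol shadow coupling aF1*J_F1 books mitochondrial ATP
   * turnover against the cytosolic pools but carries no dependence on them,
   * so it can drive cytosolic ADP (or ATP, when the synthase reverses)
   * through zero.  Gate it on the availability of the consumed cytosolic
   * substrate; k = 1e-5 mM (~2% of resting ADP) is a numerical
   * regularization, not a kinetic parameter. */
  const double kgate = 1e-5;
  const double gate = J[jF1] >= 0.0
    ? s[iADP_c] / (s[iADP_c] + kgate)
    : s[iATP_c] / (s[iATP_c] + kgate);
  const double jF1c = gate * J[jF1];
  /* same availability gating for the pyruvate drawn by the lumped TCA flux */
  const double jDHc = J[jDH] >= 0.0
    ? J[jDH] * s[iPYR_c] / (s[iPYR_c] + kgate) : J[jDH];
  int k;
  for (k = 0; k < NFULL; k++) dfull[k] = 0.0;

  dfull[iAMP_c]   = J[jAK] / Vc;
  dfull[iADP_c]   = (-J[jCK] - 2.0 * J[jAK] + J[jHK] + J[jPFK] - J[jPGK]
                     - J[jPK] + J[jATPase] - aF1 * jF1c) / Vc;
  dfull[iATP_c]   = (J[jCK] + J[jAK] - J[jATPase] - J[jHK] - J[jPFK]
                     + J[jPGK] + J[jPK] + aF1 * jF1c) / Vc;
  dfull[iBPG13_c] = (J[jGAPDH] - J[jPGK] - J[jG16BPS]) / Vc;
  dfull[iPG2_c]   = (J[jPGM] - J[jENO]) / Vc;
  dfull[iPG3_c]   = (J[jPGK] - J[jPGM] + J[jG16BPS]) / Vc;
  dfull[iCr_c]    = J[jCK] / Vc;
  dfull[iCrP_c]   = -J[jCK] / Vc;
  dfull[iDHAP_c]  = (J[jFBPA] - J[jTPI] - J[jG3PDH]) / Vc;
  dfull[iF16BP_c] = (J[jPFK] - J[jFBPA]) / Vc;
  dfull[iF6P_c]   = (J[jPGI] - J[jPFK]) / Vc;
  dfull[iG1P_c]   = (-J[jPGluM] - J[jUDPGP] + J[jGP] - J[jG16BPS]) / Vc;
  dfull[iG6P_c]   = (J[jHK] - J[jPGI] + J[jPGluM] - J[jG6PDH]) / Vc;
  dfull[iGAP_c]   = (J[jFBPA] + J[jTPI] - J[jGAPDH]) / Vc;
  dfull[iGLY_c]   = (J[jGSD] + J[jGSI] - J[jGP]) / Vc;
  dfull[iLAC_c]   = (J[jLHX] - J[jLA] + J[jLDH]) / Vc;
  dfull[iLACH_c]  = J[jLA] / Vc;
  dfull[iMb_c]    = -J[jMB] / Vc;
  dfull[iMbO2_c]  = J[jMB] / Vc;
  dfull[iO2_c]    = (-p[pO2PERC4] * J[jC4] + J[jO2EC] - J[jMB]) / Vc;
  dfull[iPEP_c]   = (J[jENO] - J[jPK]) / Vc;
  dfull[iPi_c]    = (-J[jGAPDH] + 2.0 * J[jUDPGP] - J[jGP] + J[jG6PDH]
                     + J[jG3PDH] + 2.0 * J[jG16BPS] + J[jATPase]
                     - aF1 * jF1c) / Vc;
  dfull[iPYR_c]   = (J[jPK] - J[jLDH] - aDH * jDHc) / Vc;
  dfull[iUDPG_c]  = (J[jUDPGP] - J[jGSD] - J[jGSI]) / Vc;

  dfull[imADP_i]  =  J[jMgADPi] / Vi;
  dfull[imATP_i]  =  J[jMgATPi] / Vi;
  dfull[iPi_i]    = (J[jPi2] - J[jPi1]) / Vi;
  dfull[iCox_i]   = (2.0 * J[jC4] - 2.0 * J[jC3]) / Vi;
  dfull[iCred_i]  = (2.0 * J[jC3] - 2.0 * J[jC4]) / Vi;
  dfull[idPsi]    = (4.0 * J[jC1] + 2.0 * J[jC3] + 4.0 * J[jC4]
                     - 3.0 * J[jF1] - J[jANT] - J[jHle]) / p[pCIM];

  /* ANT moves free species, F1 interconverts Mg-bound species; the matrix
   * totals (assignments) then follow d[ADP]x = (J_ANT - J_F1)/Vx exactly. */
  dfull[ifADP_x]  = (J[jANT] - J[jMgADPx]) / Vx;
  dfull[imADP_x]  = (J[jMgADPx] - J[jF1]) / Vx;
  dfull[ifATP_x]  = (-J[jANT] - J[jMgATPx]) / Vx;
  dfull[imATP_x]  = (J[jMgATPx] + J[jF1]) / Vx;
  dfull[iH_x]     = (s[iH_x] / p[pRBUFF])
                    * (J[jDH] - 5.0 * J[jC1] - 2.0 * J[jC3] - 4.0 * J[jC4]
                       + 2.0 * J[jF1] + 2.0 * J[jPi1] + J[jHle] - J[jKH])
                    / Vx;
  dfull[iK_x]     = J[jKH] / Vx;
  dfull[iMg_x]    = (-J[jMgADPx] - J[jMgATPx]) / Vx;
  dfull[iNAD_x]   = (J[jC1] - J[jDH]) / Vx;
  dfull[iNADH_x]  = (J[jDH] - J[jC1]) / Vx;
  dfull[iPi_x]    = (J[jPi1] - J[jF1]) / Vx;
  dfull[iQ_x]     = (J[jC3] - J[jC1]) / Vx;
  dfull[iQH2_x]   = (J[jC1] - J[jC3]) / Vx;

  dfull[iO2_e]    = (J[jO2VE] - J[jO2EC]) / Ve;
}

/* ---- deSolve compiled-model interface ---- */

void cardio_initmod(void (*odeparms)(int *, double *))
{
  int n = NPAR;
  odeparms(&n, parms);
}

void cardio_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
  double s[NFULL], J[NFLUX], extra[NEXTRA], dfull[NFULL];
  int k;
  if (ip[0] < NFLUX + NEXTRA)
    error("nout should be at least %d", NFLUX + NEXTRA);
  full_state(y, parms, s);
  compute_fluxes(s, parms, J, extra);
  assemble_ydot(s, parms, J, extra[4], dfull);
  for (k = 0; k < NODE; k++) ydot[k] = dfull[ODE_IDX[k]];
  for (k = 0; k < NFLUX; k++) yout[k] = J[k];
  for (k = 0; k < NEXTRA; k++) yout[NFLUX + k] = extra[k];
}

/* ---- .Call wrappers for direct evaluation from R ---- */

SEXP C_modelFluxes(SEXP state, SEXP params)
{
  SEXP out;
  double J[NFLUX], extra[NEXTRA];
  if (LENGTH(state) != NFULL) error("state must have %d entries", NFULL);
  if (LENGTH(params) != NPAR) error("params must have %d entries", NPAR);
  compute_fluxes(REAL(state), REAL(params), J, extra);
  out = PROTECT(allocVector(REALSXP, NFLUX + NEXTRA));
  memcpy(REAL(out), J, NFLUX * sizeof(double));
  memcpy(REAL(out) + NFLUX, extra, NEXTRA * sizeof(double));
  UNPROTECT(1);
  return out;
}

SEXP C_modelDerivs(SEXP state, SEXP params)
{
  SEXP out;
  double J[NFLUX], extra[NEXTRA], dfull[NFULL];
  if (LENGTH(state) != NFULL) error("state must have %d entries", NFULL);
  if (LENGTH(params) != NPAR) error("params must have %d entries", NPAR);
  compute_fluxes(REAL(state), REAL(params), J, extra);
  assemble_ydot(REAL(state), REAL(params), J, extra[4], dfull);
  out = PROTECT(allocVector(REALSXP, NFULL));
  memcpy(REAL(out), dfull, NFULL * sizeof(double));
  UNPROTECT(1);
  return out;
}

/* ---- registration ---- */

static const R_CMethodDef CEntries[] = {
  {"cardio_initmod", (DL_FUNC) &cardio_initmod, 1},
  {"cardio_derivs",  (DL_FUNC) &cardio_derivs,  6},
  {NULL, NULL, 0}
};

static const R_CallMethodDef CallEntries[] = {
  {"C_modelFluxes", (DL_FUNC) &C_modelFluxes, 2},
  {"C_modelDerivs", (DL_FUNC) &C_modelDerivs, 2},
  {NULL, NULL, 0}
};

void R_init_cardiomyosim(DllInfo *dll)
{
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
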