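/* Right-hand side of the PERK-branch ATF4-GADD34-CHOP ODE system,
 * in the deSolve compiled-model convention.  The parameter vector packs
 * the 22 rate constants, the 4 loop toggles, the stress level and the
 * intervention terms for one piecewise-constant segment; segment switching
 * is handled on the R side so every quantity here is constant in time.
 *
 * State order: eP, mA, A, mC, C, mG, G.
 */
#include <R.h>

static double parms[32];

#define k_ph    parms[0]
#define k_dp0   parms[1]
#define k_dpG   parms[2]
#define k_smA0  parms[3]
#define k_smA   parms[4]
#define k_dmA   parms[5]
#define k_sA    parms[6]
#define k_GA    parms[7]
#define k_CA    parms[8]
#define k_dA    parms[9]
#define k_smC0  parms[10]
#define k_smC   parms[11]
#define k_dmC   parms[12]
#define k_sC    parms[13]
#define k_SC    parms[14]
#define k_dC    parms[15]
#define k_smG0  parms[16]
#define k_smG   parms[17]
#define k_dmG   parms[18]
#define k_sG    parms[19]
#define k_CG    parms[20]
#define k_dG    parms[21]
#define L1      parms[22]
#define L2      parms[23]
#define L3      parms[24]
#define L4      parms[25]
#define S_lev   parms[26]
#define gbscale parms[27]
#define sichop  parms[28]
#define sigadd  parms[29]
#define oechop  parms[30]
#define oegadd  parms[31]

void perktriad_initmod(void (*odeparms)(int *, double *))
{
    int n = 32;
    odeparms(&n, parms);
}

void perktriad_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double eP = y[0], mA = y[1], A = y[2], mC = y[3],
           C  = y[4], mG = y[5], G = y[6];
    double G_act = G * gbscale;

    ydot[0] = k_ph * S_lev * (1.0 - eP) -
              (k_dp0 + L4 * k_dpG * G_act) * eP;
    ydot[1] = k_smA0 + k_smA * S_lev - k_dmA * mA;
    ydot[2] = k_sA * mA * eP * (1.0 + L1 * k_GA * G_act) /
              (1.0 + L2 * k_CA * C) - k_dA * A;
    ydot[3] = k_smC0 + k_smC * A - (k_dmC + sichop) * mC;
    ydot[4] = k_sC * mC * (1.0 + k_SC * S_lev) + oechop - k_dC * C;
    ydot[5] = k_smG0 + k_smG * A - (k_dmG + sigadd) * mG;
    ydot[6] = k_sG * mG * (1.0 + L3 * k_CG * C) + oegadd - k_dG * G;
}
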