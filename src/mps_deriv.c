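/* Compiled right-hand side of the two-compartment liver-islet model for
 * deSolve. State order: NG_liver, NG_pancreas, NI_liver, NI_pancreas,
 * G_int, G_slow, V_beta, V_m_liver_now, V_m_pancreas_now (volumes carried
 * as constant states so sampling events can change them).
 *
 * Must stay numerically identical to mps_rhs() in R/model_core.R; the two
 * are cross-checked in the test suite.
 */
#include <R.h>

static double parms[17];
#define V_hepaRG  parms[0]
#define Q         parms[1]
#define EGP       parms[2]
#define E_G0      parms[3]
#define S_I0      parms[4]
#define Imax_Si   parms[5]
#define EC50_Si   parms[6]
#define G_normo   parms[7]
#define sigma_max parms[8]
#define alpha     parms[9]
#define EC50_I    parms[10]
#define d0        parms[11]
#define r1        parms[12]
#define r2        parms[13]
#define k_v       parms[14]
#define tau_slow  parms[15]
#define CL_I      parms[16]

void mps_initmod(void (*odeparms)(int *, double *))
{
    int n = 17;
    odeparms(&n, parms);
}

void mps_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double Vl = y[7], Vp = y[8];
    double G_l = y[0] / Vl, G_p = y[1] / Vp;
    double I_l = y[2] / Vl, I_p = y[3] / Vp;
    double G_int = y[4], G_slow = y[5], V_beta = y[6];

    double expos = (EC50_Si + G_int > 0.0) ? G_int / (EC50_Si + G_int) : 0.0;
    double S_I = S_I0 * (1.0 - Imax_Si * expos);
    double tt = *t;
    double sig = (alpha + tt * tt > 0.0)
        ? sigma_max * (1.0 - tt * tt / (alpha + tt * tt))
        : sigma_max;
    double uptake = V_hepaRG * (E_G0 + S_I * I_l) * G_l;
    double denom = EC50_I * EC50_I + G_p * G_p;
    double secretion = (denom > 0.0)
        ? V_beta * sig * G_p * G_p / denom : 0.0;
    double clearance = CL_I * V_hepaRG * I_l;
    double excess = G_l - G_normo;

    ydot[0] = V_hepaRG * EGP - uptake + Q * (G_p - G_l);
    ydot[1] = Q * (G_l - G_p);
    ydot[2] = -clearance + Q * (I_p - I_l);
    ydot[3] = secretion + Q * (I_l - I_p);
    ydot[4] = excess > 0.0 ? excess : 0.0;
    ydot[5] = (G_p - G_slow) / tau_slow;
    ydot[6] = k_v * (-d0 + r1 * G_slow - r2 * G_slow * G_slow) * V_beta;
    ydot[7] = 0.0;
    ydot[8] = 0.0;
}
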