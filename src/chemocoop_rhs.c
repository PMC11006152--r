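/* Right-hand sides of the chemostat ODE systems, in the layout deSolve
 * expects from compiled models (initfunc + derivs).
 *
 * Parameter vector (15):
 *  0 Deff  effective dilution rate for the current phase (0 in batch)
 *  1 S0    inflow substrate concentration (mmol/l)
 *  2 mu_max, 3 k_cat, 4 K_S, 5 K_M, 6 eta, 7 gamma, 8 sigma,
 *  9 q, 10 QS_min, 11 n
 *  12 alpha    mutation rate (1/h), evolved systems only
 *  13 mu_max_2 evolved-mutant maximal growth rate (1/h)
 *  14 variant  1 = cheater from lasR, 2 = cheater from WT,
 *              3 = cooperator from WT
 *
 * States are floored at zero inside the rate expressions so that tiny
 * solver undershoots below zero cannot feed back into the dynamics.
 */
#include <R.h>
#include <math.h>

static double parms[15];
#define P_Deff   parms[0]
#define P_S0     parms[1]
#define P_mu     parms[2]
#define P_kcat   parms[3]
#define P_KS     parms[4]
#define P_KM     parms[5]
#define P_eta    parms[6]
#define P_gamma  parms[7]
#define P_sigma  parms[8]
#define P_q      parms[9]
#define P_QSmin  parms[10]
#define P_n      parms[11]
#define P_alpha  parms[12]
#define P_mu2    parms[13]
#define P_var    parms[14]

void chemocoop_init(void (*odeparms)(int *, double *))
{
    int n = 15;
    odeparms(&n, parms);
}

static double pos(double x) { return x > 0.0 ? x : 0.0; }

/* Hill-type quorum-sensing burden; continuous extension Q(0) = 0. */
static double hill_q(double x)
{
    double xn, kn;
    if (x <= 0.0)
        return 0.0;
    if (P_QSmin <= 0.0)
        return P_q;
    xn = pow(x, P_n);
    kn = pow(P_QSmin, P_n);
    return P_q * xn / (xn + kn);
}

static double monod(double p, double mu)
{
    return mu * p / (P_KS + p);
}

/* Base five-state system: S, P, E, X1 (cooperator), X2 (cheater). */
void chemocoop_base(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double S = pos(y[0]), P = pos(y[1]), E = pos(y[2]);
    double X1 = pos(y[3]), X2 = pos(y[4]);
    double Q = hill_q(X1);
    double F = monod(P, P_mu);
    double G = P_kcat * E * S / (P_KM + S);

    ydot[0] = P_Deff * (P_S0 - S) - G;
    ydot[1] = P_sigma * G - (X1 + X2) * F / P_gamma - P_Deff * P;
    ydot[2] = P_eta * Q * X1 * F - P_Deff * E;
    ydot[3] = X1 * ((1.0 - Q) * F - P_Deff);
    ydot[4] = X2 * (F - P_Deff);
}

/* Evolved six-state systems: S, P, E, X1, X2, X3 (evolved mutant). */
void chemocoop_evolved(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double S = pos(y[0]), P = pos(y[1]), E = pos(y[2]);
    double X1 = pos(y[3]), X2 = pos(y[4]), X3 = pos(y[5]);
    double F = monod(P, P_mu);
    double F2 = monod(P, P_mu2);
    double G = P_kcat * E * S / (P_KM + S);
    int variant = (int) P_var;
    double Q;

    ydot[0] = P_Deff * (P_S0 - S) - G;
    ydot[1] = P_sigma * G - ((X1 + X2) * F + X3 * F2) / P_gamma
              - P_Deff * P;

    switch (variant) {
    case 1: /* faster-growing cheater arising from the lasR cheater */
        Q = hill_q(X1);
        ydot[2] = P_eta * Q * X1 * F - P_Deff * E;
        ydot[3] = X1 * ((1.0 - Q) * F - P_Deff);
        ydot[4] = X2 * (F - P_Deff - P_alpha);
        ydot[5] = X3 * (F2 - P_Deff) + P_alpha * X2;
        break;
    case 2: /* faster-growing cheater arising from the WT cooperator */
        Q = hill_q(X1);
        ydot[2] = P_eta * Q * X1 * F - P_Deff * E;
        ydot[3] = X1 * ((1.0 - Q) * F - P_Deff - P_alpha);
        ydot[4] = X2 * (F - P_Deff);
        ydot[5] = X3 * (F2 - P_Deff) + P_alpha * X1;
        break;
    default: /* 3: faster-growing cooperator arising from the WT */
        Q = hill_q(X1 + X3);
        ydot[2] = P_eta * Q * (X1 * F + X3 * F2) - P_Deff * E;
        ydot[3] = X1 * ((1.0 - Q) * F - P_Deff - P_alpha);
        ydot[4] = X2 * (F - P_Deff);
        ydot[5] = X3 * ((1.0 - Q) * F2 - P_Deff) + P_alpha * X1;
        break;
    }
}
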