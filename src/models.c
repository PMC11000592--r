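/* Compiled right-hand sides for the five circuit topologies, evaluated by
 * deSolve's solvers.  The parameter vector handed over by the R side is a
 * fixed-length padded array (ND_NPAR doubles); per-topology layouts are
 * defined in R/model.R (as_solver_parms) and must stay in sync with the
 * index macros below.  Slot ND_CAP_IDX always carries the unboundedness
 * sentinel (nM); the delayed model freezes its derivatives once any state
 * exceeds it so that the R side can truncate and flag the trajectory.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define ND_NPAR 64
#define ND_CAP_IDX 60

static double parms[ND_NPAR];

void nd_initmod(void (*odeparms)(int *, double *))
{
    int n = ND_NPAR;
    odeparms(&n, parms);
}

/* (lo*x^h + hi*K^h) / (x^h + K^h); x clamped at 0 so that tiny negative
 * solver excursions cannot produce complex powers. */
static double hill(double x, double K, double h, double lo, double hi)
{
    double xh, Kh;
    if (x < 0.0) x = 0.0;
    xh = pow(x, h);
    Kh = pow(K, h);
    return (lo * xh + hi * Kh) / (xh + Kh);
}

/* concentrations entering mass-action binding fluxes are clamped at 0 so
 * that tiny negative solver excursions cannot feed back as sources */
static double pos(double x) { return x > 0.0 ? x : 0.0; }

/* Common termination root: crosses zero when any state reaches the cap. */
void nd_root(int *neq, double *t, double *y, int *ng, double *gout,
             double *out, int *ip)
{
    double m = y[0];
    for (int i = 1; i < *neq; i++)
        if (y[i] > m) m = y[i];
    gout[0] = parms[ND_CAP_IDX] - m;
}

/* ---- activator-repressor + activator-specific NanoDeg -------------------
 * state: A (activator), B (repressor), N (free NanoDeg), C (complex)
 * layout: 0 alpha1, 1 alpha2, 2 beta1, 3 beta2, 4 KA, 5 KB, 6 m, 7 n,
 *         8 k5, 9 k6, 10 deltaA, 11 deltaB, 12 pAT, 13 pBT,
 *         14 kN, 15 deltaN, 16 kon, 17 koff, 18 pNT
 */
void nd_ar(int *neq, double *t, double *y, double *ydot, double *yout, int *ip)
{
    double A = y[0], B = y[1], N = y[2], C = y[3];
    double act = hill(A, parms[4], parms[6], parms[0], parms[1]);
    double rep = hill(B, parms[5], parms[7], parms[2], parms[3]);
    double bind = parms[16] * pos(A) * pos(N) - parms[17] * C;

    ydot[0] = parms[12] * act * rep - parms[10] * A - bind;
    ydot[1] = parms[13] * hill(A, parms[4], parms[6], parms[8], parms[9])
              - parms[11] * B;
    ydot[2] = parms[18] * parms[14] - parms[15] * N - bind;
    ydot[3] = bind - parms[15] * C;
}

/* ---- Goodwin oscillator (DDE) + mature-repressor NanoDeg ----------------
 * state: A (nascent repressor), N, C; the mature repressor is A(t - tau).
 * layout: 0 beta1, 1 beta2, 2 KA, 3 m, 4 deltaA, 5 tau, 6 pAT,
 *         7 kN, 8 deltaN, 9 kon, 10 koff, 11 pNT,
 *         12..14 constant history (A, N, C) for t <= 0
 */
static void nd_lagvalue(double T, int *nr, int N, double *ytau)
{
    typedef void lagfun(double, int *, int, double *);
    static lagfun *fun = NULL;
    if (fun == NULL)
        fun = (lagfun *) R_GetCCallable("deSolve", "lagvalue");
    fun(T, nr, N, ytau);
}

void nd_goodwin(int *neq, double *t, double *y, double *ydot, double *yout,
                int *ip)
{
    double A = y[0], N = y[1], C = y[2];
    double tau = parms[5], cap = parms[ND_CAP_IDX];
    double Atau, bind;
    int idx = 0;

    if (y[0] > cap || y[1] > cap || y[2] > cap ||
        !R_FINITE(y[0]) || !R_FINITE(y[1]) || !R_FINITE(y[2])) {
        ydot[0] = ydot[1] = ydot[2] = 0.0; /* frozen: flagged unbounded in R */
        return;
    }
    if (*t > tau)
        nd_lagvalue(*t - tau, &idx, 1, &Atau);
    else
        Atau = parms[12];

    bind = parms[9] * pos(Atau) * pos(N) - parms[10] * C;
    ydot[0] = parms[6] * hill(Atau, parms[2], parms[3], parms[0], parms[1])
              - parms[4] * A - bind;
    ydot[1] = parms[11] * parms[7] - parms[8] * N - bind;
    ydot[2] = bind - parms[8] * C;
}

/* ---- repressilator with one common NanoDeg ------------------------------
 * state: A, B, C, N, TA, TB, TC
 * layout: 0..5 k1..k6, 6 KA, 7 KB, 8 KC, 9 m, 10 n, 11 r,
 *         12 deltaA, 13 deltaB, 14 deltaC, 15 pAT, 16 pBT, 17 pCT,
 *         18 kN, 19 deltaN, 20 kon, 21 koff, 22 pNT
 */
void nd_rep_common(int *neq, double *t, double *y, double *ydot, double *yout,
                   int *ip)
{
    double A = y[0], B = y[1], C = y[2], N = y[3];
    double TA = y[4], TB = y[5], TC = y[6];
    double kon = parms[20], koff = parms[21], dN = parms[19];
    double bA = kon * pos(A) * pos(N) - koff * TA;
    double bB = kon * pos(B) * pos(N) - koff * TB;
    double bC = kon * pos(C) * pos(N) - koff * TC;

    ydot[0] = parms[15] * hill(C, parms[8], parms[11], parms[0], parms[1])
              - parms[12] * A - bA;
    ydot[1] = parms[16] * hill(A, parms[6], parms[9], parms[2], parms[3])
              - parms[13] * B - bB;
    ydot[2] = parms[17] * hill(B, parms[7], parms[10], parms[4], parms[5])
              - parms[14] * C - bC;
    ydot[3] = parms[22] * parms[18] - dN * N - bA - bB - bC;
    ydot[4] = bA - dN * TA;
    ydot[5] = bB - dN * TB;
    ydot[6] = bC - dN * TC;
}

/* ---- repressilator with three individual NanoDegs -----------------------
 * state: A, B, C, NA, NB, NC, TA, TB, TC
 * layout: 0..5 k1..k6, 6 KA, 7 KB, 8 KC, 9 m, 10 n, 11 r,
 *         12 deltaA, 13 deltaB, 14 deltaC, 15 pAT, 16 pBT, 17 pCT,
 *         18 kNA, 19 kNB, 20 kNC, 21 deltaNA, 22 deltaNB, 23 deltaNC,
 *         24 pNTA, 25 pNTB, 26 pNTC, 27 kon, 28 koff
 */
void nd_rep_individual(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double A = y[0], B = y[1], C = y[2];
    double NA_ = y[3], NB = y[4], NC = y[5];
    double TA = y[6], TB = y[7], TC = y[8];
    double kon = parms[27], koff = parms[28];
    double bA = kon * pos(A) * pos(NA_) - koff * TA;
    double bB = kon * pos(B) * pos(NB) - koff * TB;
    double bC = kon * pos(C) * pos(NC) - koff * TC;

    ydot[0] = parms[15] * hill(C, parms[8], parms[11], parms[0], parms[1])
              - parms[12] * A - bA;
    ydot[1] = parms[16] * hill(A, parms[6], parms[9], parms[2], parms[3])
              - parms[13] * B - bB;
    ydot[2] = parms[17] * hill(B, parms[7], parms[10], parms[4], parms[5])
              - parms[14] * C - bC;
    ydot[3] = parms[24] * parms[18] - parms[21] * NA_ - bA;
    ydot[4] = parms[25] * parms[19] - parms[22] * NB - bB;
    ydot[5] = parms[26] * parms[20] - parms[23] * NC - bC;
    ydot[6] = bA - parms[21] * TA;
    ydot[7] = bB - parms[22] * TB;
    ydot[8] = bC - parms[23] * TC;
}

/* ---- mixed-mode repressilator (NanoDeg as third node) -------------------
 * state: A (constitutive repressor), B, N, C (NanoDeg:A complex)
 * layout: 0 k1, 1 k2, 2 k3, 3 k4, 4 k5, 5 KA, 6 KB, 7 m, 8 n,
 *         9 deltaA, 10 deltaB, 11 deltaN, 12 kon, 13 koff,
 *         14 pAT, 15 pBT, 16 pNT
 */
void nd_mixed(int *neq, double *t, double *y, double *ydot, double *yout,
              int *ip)
{
    double A = y[0], B = y[1], N = y[2], C = y[3];
    double bind = parms[12] * pos(A) * pos(N) - parms[13] * C;

    ydot[0] = parms[14] * parms[0] - parms[9] * A - bind;
    ydot[1] = parms[15] * hill(A, parms[5], parms[7], parms[1], parms[2])
              - parms[10] * B;
    ydot[2] = parms[16] * hill(B, parms[6], parms[8], parms[3], parms[4])
              - parms[11] * N - bind;
    ydot[3] = bind - parms[11] * C;
}
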