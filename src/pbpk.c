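/* Perfusion-limited PBPK model right-hand side for deSolve's compiled-model
 * interface. Fixed layout: 9 tissue compartments, venous blood, arterial
 * blood, and cumulative amount metabolized.
 *
 * State y:   [0..8] tissue concentrations C_T (mg/L)
 *            [9]    venous blood concentration (mg/L)
 *            [10]   arterial blood concentration (mg/L)
 *            [11]   cumulative amount metabolized (mg)
 * Parms:     [0..8]  tissue volumes V_T (L)
 *            [9..17] tissue flows Q_T (L/h)
 *            [18..26] partition coefficients P_T
 *            [27] venous blood volume (L)   [28] arterial blood volume (L)
 *            [29] total tissue flow (L/h)   [30] Vmax (mg/h)  [31] Km (mg/L)
 *            [32] iv input rate into venous blood (mg/h)
 *            [33] index of the metabolizing tissue (0-based)
 */
#include <R.h>
#include <R_ext/Rdynload.h>

#define FU_NT 9
#define FU_NPAR 34

static double parms[FU_NPAR];

void fupbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = FU_NPAR;
    odeparms(&n, parms);
}

void fupbpk_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double *V = parms, *Q = parms + FU_NT, *P = parms + 2 * FU_NT;
    const double Vven = parms[27], Vart = parms[28], Qtot = parms[29];
    const double Vmax = parms[30], Km = parms[31], rate = parms[32];
    const int imet = (int) parms[33];
    const double cv = y[FU_NT], ca = y[FU_NT + 1];
    double venous_in = 0.0;

    for (int i = 0; i < FU_NT; i++) {
        double cvt = y[i] / P[i];
        ydot[i] = Q[i] * (ca - cvt) / V[i];
        venous_in += Q[i] * cvt;
    }
    double cvl = y[imet] / P[imet];
    double ram = Vmax * cvl / (Km + cvl);
    ydot[imet] -= ram / V[imet];

    ydot[FU_NT] = (venous_in - Qtot * cv + rate) / Vven;
    ydot[FU_NT + 1] = Qtot * (cv - ca) / Vart;
    ydot[FU_NT + 2] = ram;
}

static const R_CMethodDef CEntries[] = {
    {"fupbpk_initmod", (DL_FUNC) &fupbpk_initmod, 1},
    {"fupbpk_derivs",  (DL_FUNC) &fupbpk_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_fupbpk(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, FALSE);
}
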