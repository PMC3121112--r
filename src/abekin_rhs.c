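/* Table-driven right-hand side for dY/dt = A * diag(EAC) * v(Y; P),
 * used through deSolve's compiled-code interface (func/initfunc/dllname).
 *
 * The model is packed into a flat double vector by pack_model_parms() on the
 * R side:
 *   parms[0] = n_species
 *   parms[1] = n_reactions
 *   then 9 slots per reaction j at offset 2 + 9*j:
 *     [0] rate-law kind code (1 mass action, 2 Michaelis-Menten with 1 or 2
 *         substrates, 3 substrate inhibition, 4 noncompetitive product
 *         inhibition, 5 essential activation)
 *     [1] substrate 1 index (1-based; 0 = none)
 *     [2] substrate 2 index (Michaelis-Menten only)
 *     [3] effector index (inhibitor/activator kinds)
 *     [4..7] numeric parameters p1..p4 (meaning depends on kind)
 *     [8] enzyme activity coefficient for the current time interval
 *   then the stoichiometric matrix, column-major, n_species x n_reactions.
 *
 * The vector is zero-padded to ABEKIN_PARMS_LEN so the initializer can
 * request a fixed length.
 */

#include <R.h>
#include <R_ext/Rdynload.h>

#define ABEKIN_PARMS_LEN 16384

static double abekin_parms[ABEKIN_PARMS_LEN];

void abekin_initmod(void (*odeparms)(int *, double *))
{
    int N = ABEKIN_PARMS_LEN;
    odeparms(&N, abekin_parms);
}

/* concentration lookup with clipping of small negative solver undershoot */
static double conc(const double *y, int idx1based)
{
    double v;
    if (idx1based <= 0)
        return 0.0;
    v = y[idx1based - 1];
    return v > 0.0 ? v : 0.0;
}

void abekin_deriv(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const double *p = abekin_parms;
    int ns = (int) p[0];
    int nr = (int) p[1];
    const double *stoich = p + 2 + 9 * nr;
    int i, j;

    for (i = 0; i < ns; i++)
        ydot[i] = 0.0;

    for (j = 0; j < nr; j++) {
        const double *r = p + 2 + 9 * j;
        int kind = (int) r[0];
        double s1 = conc(y, (int) r[1]);
        double s2 = conc(y, (int) r[2]);
        double ef = conc(y, (int) r[3]);
        double p1 = r[4], p2 = r[5], p3 = r[6], p4 = r[7];
        double eac = r[8];
        double v = 0.0;

        switch (kind) {
        case 1:                 /* mass action, first order: k * S */
            v = p1 * s1;
            break;
        case 2:                 /* irreversible MM, 1 or 2 substrates */
            v = p1 * s1 / (p2 + s1);
            if ((int) r[2] > 0)
                v *= s2 / (p3 + s2);
            break;
        case 3:                 /* MM with substrate inhibition */
            v = p1 * s1 / (p2 + s1 + s1 * s1 / p3);
            break;
        case 4:                 /* MM (1-2 substrates), noncompetitive
                                   product inhibition; Ki in p4 */
            v = p1 * s1 / (p2 + s1);
            if ((int) r[2] > 0)
                v *= s2 / (p3 + s2);
            v /= 1.0 + ef / p4;
            break;
        case 5:                 /* MM with essential activator */
            v = p1 * s1 / (p2 + s1) * ef / (p3 + ef);
            break;
        default:
            error("abekin_deriv: unknown rate-law kind code %d", kind);
        }

        v *= eac;
        if (v != 0.0) {
            const double *col = stoich + (size_t) j * ns;
            for (i = 0; i < ns; i++)
                ydot[i] += col[i] * v;
        }
    }
}

static const R_CMethodDef CEntries[] = {
    {"abekin_deriv",   (DL_FUNC) &abekin_deriv,   6},
    {"abekin_initmod", (DL_FUNC) &abekin_initmod, 1},
    {NULL, NULL, 0}
};

void R_init_abekin(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
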