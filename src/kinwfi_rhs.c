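/* Generic mass-action ODE right-hand side for deSolve.
 *
 * The parameter block (passed via deSolve's initfunc mechanism, padded to
 * PARMS_LEN on the R side) encodes an arbitrary network of integer-order
 * elementary steps:
 *
 *   [0] S  number of species
 *   [1] M  number of steps
 *   [2] mode: 0 = constant rate constants (isothermal),
 *             1 = Arrhenius constants under a piecewise-linear T(t)
 *   [3] P  number of temperature-profile knots (mode 1)
 *   [4 .. 4+S*M-1]        reactant-order matrix, column-major by step
 *   [.. +S*M]             net stoichiometry matrix, column-major by step
 *   then mode 0: k[M]
 *        mode 1: A[M], Ea[M] (J/mol), tknot[P] (s), Tknot[P] (K)
 *
 * Time is in seconds, concentrations in mol/L. Orders are small positive
 * integers (molecularity <= 2), so powers are unrolled multiplications.
 * Negative excursions of the solver are clamped to zero inside the rate
 * evaluation only.
 */

#include <math.h>

#define PARMS_LEN 1024
#define MAX_STEPS 64
#define RGAS 8.314

static double parms[PARMS_LEN];

void kinwfi_initmod(void (*odeparms)(int *, double *))
{
    int N = PARMS_LEN;
    odeparms(&N, parms);
}

void kinwfi_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    int S = (int) parms[0];
    int M = (int) parms[1];
    int mode = (int) parms[2];
    int P = (int) parms[3];
    const double *ord = parms + 4;
    const double *net = parms + 4 + (long) S * M;
    const double *tail = parms + 4 + 2L * S * M;
    double k[MAX_STEPS];
    int i, j, c;

    if (mode == 0) {
        for (j = 0; j < M; j++) k[j] = tail[j];
    } else {
        const double *A = tail, *Ea = tail + M;
        const double *tk = tail + 2 * M, *TK = tail + 2 * M + P;
        double T;
        if (*t <= tk[0]) T = TK[0];
        else if (*t >= tk[P - 1]) T = TK[P - 1];
        else {
            for (i = 1; i < P; i++) {
                if (*t <= tk[i]) break;
            }
            T = TK[i - 1] + (TK[i] - TK[i - 1]) *
                (*t - tk[i - 1]) / (tk[i] - tk[i - 1]);
        }
        for (j = 0; j < M; j++) k[j] = A[j] * exp(-Ea[j] / (RGAS * T));
    }

    for (i = 0; i < S; i++) ydot[i] = 0.0;
    for (j = 0; j < M; j++) {
        double rate = k[j];
        if (rate == 0.0) continue;
        for (i = 0; i < S; i++) {
            int o = (int) ord[i + (long) j * S];
            if (o > 0) {
                double yi = y[i] > 0.0 ? y[i] : 0.0;
                for (c = 0; c < o; c++) rate *= yi;
            }
        }
        for (i = 0; i < S; i++) {
            double n = net[i + (long) j * S];
            if (n != 0.0) ydot[i] += n * rate;
        }
    }
}
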