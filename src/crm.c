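/* Consumer-resource model right-hand side for deSolve.
 *
 * State: y[0] = A (nitrate, mM), y[1] = C~ (rescaled limiting nutrient, mM),
 *        y[2] = x~ (biomass activity, mM/day).
 * Parameters: gamma (1/day), K_A (mM), K_C (mM).
 *
 * Monod terms are evaluated on non-negative state; concentrations are floored
 * at zero inside the rate law so the stepper cannot be driven negative by a
 * slight overshoot at resource exhaustion.
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[3];
#define GAMMA parms[0]
#define K_A   parms[1]
#define K_C   parms[2]

void crm_initparms(void (*odeparms)(int *, double *))
{
    int n = 3;
    odeparms(&n, parms);
}

void crm_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double A = y[0] > 0 ? y[0] : 0;
    double C = y[1] > 0 ? y[1] : 0;
    double x = y[2] > 0 ? y[2] : 0;

    double mA = A / (A + K_A);
    double mC = C / (C + K_C);

    ydot[0] = -x * mA;
    ydot[1] = -x * mC;
    ydot[2] = GAMMA * x * mA * mC;
}
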