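/* Compiled right-hand side of the three-state coupled-trait ODE system,
 * called by deSolve. Parameter order must match ecto_simulate():
 * mu alpha beta gamma c1 c2 c3 K G A omega t0 forcing */
#include <R.h>
#include <math.h>

static double parms[13];
#define p_mu      parms[0]
#define p_alpha   parms[1]
#define p_beta    parms[2]
#define p_gamma   parms[3]
#define p_c1      parms[4]
#define p_c2      parms[5]
#define p_c3      parms[6]
#define p_K       parms[7]
#define p_G       parms[8]
#define p_A       parms[9]
#define p_omega   parms[10]
#define p_t0      parms[11]
#define p_forcing parms[12]

void ecto_initmod(void (*odeparms)(int *, double *))
{
    int n = 13;
    odeparms(&n, parms);
}

void ecto_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double N = y[0], P = y[1], E = y[2];
    double Eeff = E;
    if (p_forcing > 0.5)
        Eeff += p_A * sin(p_omega * (*t - p_t0));
    double emet = p_c1 * P + p_c2 * N + p_c3 * Eeff;
    double s = p_alpha * N + p_beta * p_beta * P;
    ydot[0] = p_mu * N - s * N;
    ydot[1] = p_mu * P - p_beta * P * emet / p_G;
    ydot[2] = p_gamma * E * N / (N + p_K);
}
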