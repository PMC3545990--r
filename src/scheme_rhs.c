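/* Compiled right-hand side of the binding-scheme ODEs for deSolve.
 *
 * State  y = (E_free, I_free, EI, EI_star, S, P)
 * Parms  p = (k_on, k_off, k_isom_f, k_isom_r, k_cat, K_m)
 *
 * The reporter reaction is a quasi-steady-state Michaelis-Menten flux;
 * the association term carries the competitive protection factor
 * K_m/(K_m + S) so the excess-inhibitor approach rate is
 * k_off + k_on * I / (1 + S/K_m).
 */
#include <R.h>

static double parms[6];
#define K_ON     parms[0]
#define K_OFF    parms[1]
#define K_ISOM_F parms[2]
#define K_ISOM_R parms[3]
#define K_CAT    parms[4]
#define K_M      parms[5]

void st_initparms(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

void st_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double E = y[0], I = y[1], EI = y[2], EIs = y[3], S = y[4];
    double protect = K_M / (K_M + S);
    double bind    = K_ON * E * I * protect;
    double unbind  = K_OFF * EI;
    double isom_f  = K_ISOM_F * EI;
    double isom_r  = K_ISOM_R * EIs;
    double v       = K_CAT * E * S / (K_M + S);

    ydot[0] = -bind + unbind;
    ydot[1] = -bind + unbind;
    ydot[2] =  bind - unbind - isom_f + isom_r;
    ydot[3] =  isom_f - isom_r;
    ydot[4] = -v;
    ydot[5] =  v;
}
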