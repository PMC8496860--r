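/* GAL regulatory network ODE right-hand side, compiled for deSolve.
 *
 * State (12): G1 G2 G3 G3s G80 G4 C83 C84 HXT Rtot gluc_in gal_in
 * Parms (47): the 45 kinetic constants in canonical package order,
 *             then glucex, galex (held constant over one integration).
 *
 * Mass-action ODEs are non-negative analytically; tiny numerical
 * undershoot from the integrator is clamped to zero before evaluation.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 47

static double parms[N_PARMS];

#define a1       parms[0]
#define ag1      parms[1]
#define a2       parms[2]
#define ag2      parms[3]
#define a3       parms[4]
#define ag3      parms[5]
#define a80      parms[6]
#define ag80     parms[7]
#define a4       parms[8]
#define ag4      parms[9]
#define a0HXT    parms[10]
#define aHXT     parms[11]
#define aR       parms[12]
#define KG1      parms[13]
#define KG2      parms[14]
#define KG3      parms[15]
#define KG80     parms[16]
#define KHXT     parms[17]
#define KR1      parms[18]
#define KR3      parms[19]
#define KR4      parms[20]
#define KRs      parms[21]
#define kf3      parms[22]
#define kr3      parms[23]
#define kf83     parms[24]
#define kr83     parms[25]
#define kf84     parms[26]
#define kr84     parms[27]
#define kG2      parms[28]
#define rG2      parms[29]
#define KGgluc   parms[30]
#define rcat     parms[31]
#define rHXT     parms[32]
#define KHXTgluc parms[33]
#define d_       parms[34]
#define dsugar   parms[35]
#define n1       parms[36]
#define n2       parms[37]
#define n3       parms[38]
#define n80      parms[39]
#define nHXT     parms[40]
#define nR1      parms[41]
#define nR3      parms[42]
#define nR4      parms[43]
#define nRs      parms[44]
#define glucex   parms[45]
#define galex    parms[46]

void gal_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* x^n / (x^n + K^n), safe at x = 0 */
static double hill_act(double x, double K, double n)
{
    double xn;
    if (x <= 0.0) return 0.0;
    xn = pow(x, n);
    return xn / (xn + pow(K, n));
}

/* K^n / (K^n + x^n) */
static double hill_rep(double x, double K, double n)
{
    double Kn = pow(K, n);
    if (x <= 0.0) return 1.0;
    return Kn / (Kn + pow(x, n));
}

void gal_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double G1, G2, G3, G3s, G80, G4, C83, C84, HXT, Rtot, gluc, gal;
    double Rs, bind3, bind83, bind84, up_gluc, up_gal;

    G1   = y[0]  > 0.0 ? y[0]  : 0.0;
    G2   = y[1]  > 0.0 ? y[1]  : 0.0;
    G3   = y[2]  > 0.0 ? y[2]  : 0.0;
    G3s  = y[3]  > 0.0 ? y[3]  : 0.0;
    G80  = y[4]  > 0.0 ? y[4]  : 0.0;
    G4   = y[5]  > 0.0 ? y[5]  : 0.0;
    C83  = y[6]  > 0.0 ? y[6]  : 0.0;
    C84  = y[7]  > 0.0 ? y[7]  : 0.0;
    HXT  = y[8]  > 0.0 ? y[8]  : 0.0;
    Rtot = y[9]  > 0.0 ? y[9]  : 0.0;
    gluc = y[10] > 0.0 ? y[10] : 0.0;
    gal  = y[11] > 0.0 ? y[11] : 0.0;

    /* glucose-bound active repressor (Mig1-like), algebraic */
    Rs = hill_act(gluc, KRs, nRs) * Rtot;

    bind3  = kf3  * gal * G3  - kr3  * G3s;
    bind83 = kf83 * G3s * G80 - kr83 * C83;
    bind84 = kf84 * G4  * G80 - kr84 * C84;

    /* competitive Michaelis uptake through Gal2p and the aggregate HXT */
    up_gluc = kG2 * G2 * glucex / (galex / rG2 + glucex + KGgluc) +
              rcat * kG2 * HXT * glucex / (galex / rHXT + glucex + KHXTgluc);
    up_gal  = kG2 * G2 * galex / (rG2 * glucex + galex + rG2 * KGgluc) +
              rcat * kG2 * HXT * galex / (rHXT * glucex + galex + rHXT * KHXTgluc);

    ydot[0]  = a1 + ag1 * hill_act(G4, KG1, n1) * hill_rep(Rs, KR1, nR1) - d_ * G1;
    ydot[1]  = a2 + ag2 * hill_act(G4, KG2, n2) - d_ * G2;
    ydot[2]  = a3 + ag3 * hill_act(G4, KG3, n3) * hill_rep(Rs, KR3, nR3)
               - bind3 - d_ * G3;
    ydot[3]  = bind3 - bind83 - d_ * G3s;
    ydot[4]  = a80 + ag80 * hill_act(G4, KG80, n80) - bind83 - bind84 - d_ * G80;
    ydot[5]  = a4 + ag4 * hill_rep(Rs, KR4, nR4) - bind84 - d_ * G4;
    ydot[6]  = bind83 - d_ * C83;
    ydot[7]  = bind84 - d_ * C84;
    ydot[8]  = a0HXT + aHXT * hill_rep(G4, KHXT, nHXT) - d_ * HXT;
    ydot[9]  = aR - d_ * Rtot;
    ydot[10] = up_gluc - dsugar * gluc;
    ydot[11] = up_gal - bind3 - dsugar * gal;
}
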