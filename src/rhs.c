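/* Mass-action right-hand side of the apoptosis-execution network.
 *
 * Units: concentrations in uM, time in minutes.  Species order must match
 * .species_names in R/network.R; parameter order must match .param_names.
 *
 * Compiled model interface for deSolve: initmod_apoptimer() caches the
 * parameter vector, derivs_apoptimer() evaluates dy/dt.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 24

static double parms[N_PARMS];

/* parameter indices */
#define K_ASM    parms[0]   /* APAF1 + CytC -> platform (uM^-1 min^-1) */
#define KON1     parms[1]   /* primary PC9 binding */
#define KOFF1    parms[2]
#define KON2     parms[3]   /* cooperative secondary PC9 binding */
#define KOFF2    parms[4]
#define KON_C9   parms[5]   /* weak C9 rebinding (molecular timer) */
#define KOFF_C9  parms[6]
#define K_AUTO   parms[7]   /* homodimer autocleavage PC9 -> C9-35/12 */
#define K_PC9    parms[8]   /* IETDase rate of PC9-apoptosome species */
#define K_C9     parms[9]   /* IETDase rate of C9-apoptosome */
#define K_DEVD   parms[10]  /* C3 cleavage of C3-substrate */
#define KON_X9   parms[11]  /* XIAP BIR3 : C9-35/12 */
#define KOFF_X9  parms[12]
#define KON_X3   parms[13]  /* XIAP BIR2 : C3 */
#define KOFF_X3  parms[14]
#define KON_SX   parms[15]  /* SMAC : XIAP */
#define KOFF_SX  parms[16]
#define ATP      parms[17]  /* uM, treated as constant modifier */
#define K_ATP    parms[18]  /* half-saturation of ATP in platform formation */
#define K_DEG    parms[19]  /* first-order degradation of free proteins */
#define S_APAF1  parms[20]  /* zeroth-order synthesis rates */
#define S_PC9    parms[21]
#define S_PC3    parms[22]
#define S_XIAP   parms[23]

/* species indices */
#define CYTC_M  0
#define SMAC_M  1
#define CYTC_C  2
#define SMAC_C  3
#define APAF1   4
#define APOP    5   /* assembled platform (carries one APAF1 + one CytC) */
#define PC9     6
#define A1      7   /* platform : PC9 (heterodimer, active) */
#define A2      8   /* platform : PC9 homodimer (active, autocleaves) */
#define C9      9   /* free C9-35/12 (inactive off the platform) */
#define AC9    10   /* platform : C9-35/12 (active) */
#define XIAP   11
#define XC9    12   /* XIAP : C9 */
#define AXC9   13   /* platform : C9 : XIAP (inactive) */
#define SX     14   /* SMAC : XIAP */
#define PC3    15
#define C3     16
#define XC3    17   /* XIAP : C3 */
#define SUB    18
#define CSUB   19

void initmod_apoptimer(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void derivs_apoptimer(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double atp_f = (ATP + K_ATP > 0.0) ? ATP / (ATP + K_ATP) : 0.0;

    double v_asm = K_ASM * y[APAF1] * y[CYTC_C] * atp_f;
    double v1f = KON1 * y[APOP] * y[PC9],  v1r = KOFF1 * y[A1];
    double v2f = KON2 * y[A1] * y[PC9],    v2r = KOFF2 * y[A2];
    double v_auto = K_AUTO * y[A2];        /* A2 -> AC9 + free C9 */
    double v5f = KON_C9 * y[APOP] * y[C9], v5r = KOFF_C9 * y[AC9];
    double v6f = KON_X9 * y[XIAP] * y[C9], v6r = KOFF_X9 * y[XC9];
    double v7f = KON_X9 * y[XIAP] * y[AC9], v7r = KOFF_X9 * y[AXC9];
    double v8f = KON_X3 * y[XIAP] * y[C3], v8r = KOFF_X3 * y[XC3];
    double v9f = KON_SX * y[SMAC_C] * y[XIAP], v9r = KOFF_SX * y[SX];
    double v_ietd = (K_PC9 * (y[A1] + 2.0 * y[A2]) + K_C9 * y[AC9]) * y[PC3];
    double v_devd = K_DEVD * y[C3] * y[SUB];

    ydot[CYTC_M] = 0.0;
    ydot[SMAC_M] = 0.0;
    ydot[CYTC_C] = -v_asm;
    ydot[SMAC_C] = -v9f + v9r;
    ydot[APAF1]  = -v_asm + S_APAF1 - K_DEG * y[APAF1];
    ydot[APOP]   = v_asm - v1f + v1r - v5f + v5r;
    ydot[PC9]    = -v1f + v1r - v2f + v2r + S_PC9 - K_DEG * y[PC9];
    ydot[A1]     = v1f - v1r - v2f + v2r;
    ydot[A2]     = v2f - v2r - v_auto;
    ydot[C9]     = v_auto - v5f + v5r - v6f + v6r - K_DEG * y[C9];
    ydot[AC9]    = v_auto + v5f - v5r - v7f + v7r;
    ydot[XIAP]   = -v6f + v6r - v7f + v7r - v8f + v8r - v9f + v9r
                   + S_XIAP - K_DEG * y[XIAP];
    ydot[XC9]    = v6f - v6r;
    ydot[AXC9]   = v7f - v7r;
    ydot[SX]     = v9f - v9r;
    ydot[PC3]    = -v_ietd + S_PC3 - K_DEG * y[PC3];
    ydot[C3]     = v_ietd - v8f + v8r - K_DEG * y[C3];
    ydot[XC3]    = v8f - v8r;
    ydot[SUB]    = -v_devd;
    ydot[CSUB]   = v_devd;
}

static const R_CMethodDef CEntries[] = {
    {"initmod_apoptimer", (DL_FUNC) &initmod_apoptimer, 1},
    {"derivs_apoptimer",  (DL_FUNC) &derivs_apoptimer,  6},
    {NULL, NULL, 0}
};

void R_init_apoptimer(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);  /* deSolve looks symbols up by name */
}
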