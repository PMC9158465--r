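/* Compiled right-hand side of the coupled volume/calcium ODE system,
 * in the deSolve compiled-model interface. Mirrors system_rhs() in R;
 * the R version is the reference implementation and the two are held
 * equal by tests.
 *
 * State: y = (V_os [L], Ca_cyt [nM], CaMb [nM], CaNb [nM]).
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 35

static double p[N_PARMS];

/* parameter slots; must match pack_parms() in R/simulate_fast.R */
#define V_b      p[0]
#define L_p      p[1]
#define cRT      p[2]   /* c_PC * R * T, MPa per umol/L */
#define Gly_i    p[3]
#define c_n_i    p[4]
#define V_os0    p[5]
#define V_zero   p[6]
#define epsl     p[7]
#define dil_d    p[8]
#define t_off    p[9]
#define t_m      p[10]
#define c_n_e0   p[11]
#define Ca_ex0   p[12]
#define v_Vcx1   p[13]
#define k_Vcx1   p[14]
#define v_Pmc1   p[15]
#define k_Pmc1   p[16]
#define v_Pmr1   p[17]
#define k_Pmr1   p[18]
#define k_MS     p[19]
#define k_Cch1   p[20]
#define P_MS     p[21]
#define g_MS     p[22]
#define km_plus  p[23]
#define km_minus p[24]
#define kn_plus  p[25]
#define kn_minus p[26]
#define CaM_t    p[27]
#define CaN_t    p[28]
#define kI_MS    p[29]
#define kI_Vcx1  p[30]
#define kI_Cch1  p[31]
#define v_IN     p[32]
#define k_IN     p[33]
#define buffered p[34]

void calshock_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

static double dilution(double t, double x0)
{
    if (t < t_off) return x0;
    double xinf = x0 / dil_d;
    return (x0 - xinf) * exp((t_off - t) / t_m) + xinf;
}

static double mm(double vmax, double km, double s)
{
    double den = km + s;
    return den == 0.0 ? 0.0 : vmax * s / den;
}

void calshock_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double Vos = y[0];
    double ca = y[1] > 0.0 ? y[1] : 0.0;
    double camb = y[2];
    double canb = y[3];
    if (camb < 0.0) camb = 0.0;
    if (camb > CaM_t) camb = CaM_t;
    if (canb < 0.0) canb = 0.0;
    if (canb > CaN_t) canb = CaN_t;

    double V = V_b + Vos;
    double A = cbrt(36.0 * M_PI) * pow(V, 2.0 / 3.0);
    double P = epsl * log(V / V_zero);
    if (P < 0.0) P = 0.0;
    double osm_e = dilution(*t, c_n_e0);
    double osm_i = Gly_i + c_n_i * V_os0 / Vos;
    ydot[0] = -L_p * A * (P + cRT * (osm_e - osm_i));

    double z = (P - P_MS) / g_MS;
    if (z > 700.0) z = 700.0;
    if (z < -700.0) z = -700.0;
    double p_open = 1.0 - 1.0 / (1.0 + exp(z));
    double ca_ex = dilution(*t, Ca_ex0);

    double j_in = mm(v_IN, k_IN, ca_ex);
    double j_cch1 = k_Cch1 * (ca_ex - ca) / (1.0 + kI_Cch1 * canb);
    double j_ms = p_open * k_MS * (ca_ex - ca) / (1.0 + kI_MS * camb);
    double j_pmr1 = mm(v_Pmr1, k_Pmr1, ca);
    double j_vcx1 = mm(v_Vcx1, k_Vcx1, ca) / (1.0 + kI_Vcx1 * canb);
    double j_pmc1 = mm(v_Pmc1, k_Pmc1, ca);

    double dcamb = km_plus * (CaM_t - camb) * ca * ca * ca -
        km_minus * camb;
    double dca = j_in + j_cch1 + j_ms - j_pmr1 - j_vcx1 - j_pmc1;
    if (buffered != 0.0) dca -= 3.0 * dcamb;

    ydot[1] = dca;
    ydot[2] = dcamb;
    ydot[3] = kn_plus * (CaN_t - canb) * camb - kn_minus * canb;
}

static const R_CMethodDef cMethods[] = {
    {"calshock_initmod", (DL_FUNC) &calshock_initmod, 1},
    {"calshock_derivs",  (DL_FUNC) &calshock_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_calshock(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
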