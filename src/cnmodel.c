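/* Compiled right-hand side of the diurnal C/N network for deSolve.
 *
 * Parameter vector (29 + 4*2401 doubles, set via cn_initmod):
 *   0..21  kinetic parameters in the package's canonical order
 *          (km_gdc, km_shmt, km_hpr, km_gs_nh4, km_gs_glu, km_gogat_gln,
 *           km_gogat_kg, km_nr, vmax_gdc, vmax_shmt, vmax_gogat,
 *           k_hp2bmexp, k_hp2mf, k_mf2cit, k_cit2mf, k_cit2kg,
 *           k_ser2aa, k_aa2bmexp, alpha, correct, f_gs_night, s_day)
 *   22 phi  23 rd  24 no3_cyt  25 light_hours  26 gate_carboxylates
 *   27 gate_eps  28 tissue volume (ml per g FW)
 *   then four driver curves (net CO2 exchange, NR, GS and HPR activity)
 *   sampled on the uniform grid t = 0, 0.01, ..., 24 h and linearly
 *   interpolated here.
 *
 * The light/dark switch is computed from t and light_hours; the R wrapper
 * restarts the integration at the transition so a segment never straddles
 * it. State order: gly ser hp mf cit kg glu gln aa nh4.
 */

#include <math.h>

#define N_HEAD 29
#define N_GRID 2401
#define DT_GRID 0.01

static double parms[N_HEAD + 4 * N_GRID];

void cn_initmod(void (*odeparms)(int *, double *))
{
    int N = N_HEAD + 4 * N_GRID;
    odeparms(&N, parms);
}

static double interp_driver(int which, double t)
{
    const double *a = parms + N_HEAD + which * N_GRID;
    double x = t / DT_GRID;
    int i = (int) x;
    if (i < 0) return a[0];
    if (i >= N_GRID - 1) return a[N_GRID - 1];
    double w = x - i;
    return a[i] * (1.0 - w) + a[i + 1] * w;
}

static double gate(double s, double eps)
{
    if (s < 0.0) s = 0.0;
    return s / (s + eps);
}

static double pos(double x) { return x > 0.0 ? x : 0.0; }

void cn_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const double *p = parms;
    double vol = p[28], eps = p[27];
    int light = *t < p[25];

    double gly = pos(y[0]), ser = pos(y[1]), hp = pos(y[2]);
    double mf = pos(y[3]), cit = pos(y[4]), kg = pos(y[5]);
    double glu = pos(y[6]), gln = pos(y[7]), aa = pos(y[8]);
    double nh4 = pos(y[9]);

    double a_net = interp_driver(0, *t);
    double v_o = 0.0;
    if (light && p[22] > 0.0)
        v_o = pos((a_net + p[23]) / (1.0 / p[22] - 0.5));
    double v_pr = (light ? v_o / 2.0 : 0.0) + p[18];

    double gly_c = gly / vol;
    double v_gdc = p[8] * gly_c / (p[0] + gly_c);
    double v_shmt = p[9] * gly_c / (p[1] + gly_c);
    if (v_shmt > v_gdc) v_shmt = v_gdc;

    double ser_c = ser / vol;
    double v_hpr = interp_driver(3, *t) * ser_c / (p[2] + ser_c);

    double v_nr = interp_driver(1, *t) * p[24] / (p[7] + p[24]);

    double nh4_c = nh4 / vol, glu_c = glu / vol;
    double vgs = interp_driver(2, *t) * (light ? 1.0 : p[20]);
    double v_gs = vgs * nh4_c / (p[3] + nh4_c) * glu_c / (p[4] + glu_c);

    double gln_c = gln / vol, kg_c = kg / vol;
    double v_gogat = p[10] * gln_c / (p[5] + gln_c) * kg_c / (p[6] + kg_c);

    double v_hp2bmexp = p[11] * hp;
    double v_hp2mf = p[12] * hp;
    int gate_cx = p[26] > 0.5;
    double v_mf2cit = p[13] * mf * ((gate_cx && light) ? 0.0 : 1.0);
    double v_cit2mf = p[14] * cit;
    double v_cit2kg = p[15] * cit * ((gate_cx && !light) ? 0.0 : 1.0);
    double v_ser2aa = p[16] * ser;
    double v_aa2bmexp = p[17] * aa;
    double v_ser2bm = 0.14 * v_aa2bmexp * gate(ser, eps);
    double v_glu2kg = pos(v_pr - v_hpr) * gate(glu, eps);
    double v_glu2aa = p[19] * v_nr * gate(glu, eps);
    double v_resp = p[23] / 4.0 * gate(mf, eps);
    double v_starch = light ? p[21] * gate(hp, eps)
                            : p[21] * p[25] / (24.0 - p[25]);

    double v_ps_in = (a_net + p[23] + v_gdc - 2.0 * v_pr) / 6.0;
    double starch_hp = light ? -v_starch : v_starch;

    ydot[0] = v_pr - v_gdc - v_shmt;
    ydot[1] = v_shmt - v_hpr - v_ser2aa - v_ser2bm;
    ydot[2] = v_ps_in + 0.5 * v_hpr - v_hp2bmexp - v_hp2mf + starch_hp;
    ydot[3] = 1.5 * v_hp2mf + 1.5 * v_cit2mf - 1.5 * v_mf2cit - v_resp;
    ydot[4] = v_mf2cit - v_cit2mf - v_cit2kg;
    ydot[5] = 1.2 * v_cit2kg + v_glu2kg - v_gogat;
    ydot[6] = 2.0 * v_gogat - v_gs - v_glu2kg - v_glu2aa;
    ydot[7] = v_gs - v_gogat;
    ydot[8] = v_ser2aa + v_glu2aa - v_aa2bmexp;
    ydot[9] = v_gdc + v_nr - v_gs;
}
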