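/* Compiled right-hand side and Jacobian of the three-variable
 * negative-feedback model, for use through deSolve's compiled-model
 * interface during fitting (the R closures in model.R are the reference
 * implementation; both are exercised against each other in the tests).
 *
 * Parameter vector layout (doubles, see pack_params() in R):
 *  0..6   k0..k6
 *  7      yT
 *  8..13  Kx, Kz, Kq, hq, Kf3, mf3
 *  14..17 kappa_y, mg, kappa_z, mH
 *  18     stimulus (k0 + external input, constant within a segment)
 *  19..25 flags: f1_mm, f3_hill, h_mm, input_inhibition, auto_y, auto_z,
 *         mass_conservation (0/1)
 */
#include <R.h>
#include <Rmath.h>

#define NPAR 26
static double p[NPAR];

void tl_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

void tl_derivs(int *neq, double *t, double *y_, double *ydot,
               double *yout, int *ip)
{
    double x = y_[0], y = y_[1], z = y_[2];
    double k1 = p[1], k2 = p[2], k3 = p[3], k4 = p[4], k5 = p[5], k6 = p[6];
    double yT = p[7], Kx = p[8], Kz = p[9], Kq = p[10], hq = p[11];
    double Kf3 = p[12], mf3 = p[13];
    double kap_y = p[14], mg = p[15], kap_z = p[16], mH = p[17];
    double stim = p[18];
    double q, f1, f3, h, g, H, G;

    q = (p[22] > 0.5) ? 1.0 / (1.0 + R_pow(z / Kq, hq)) : 1.0;
    f1 = (p[19] > 0.5) ? x / (Kx + x) : x;
    if (p[20] > 0.5) {
        double u = R_pow(z, mf3);
        f3 = u / (R_pow(Kf3, mf3) + u);
    } else {
        f3 = z;
    }
    h = (p[21] > 0.5) ? z / (Kz + z) : z;
    g = (p[23] > 0.5) ? 1.0 / (1.0 + R_pow(kap_y * y, mg)) : 1.0;
    H = (p[24] > 0.5) ? 1.0 / (1.0 + R_pow(kap_z * z, mH)) : 1.0;
    G = (p[25] > 0.5) ? (yT - y) * g : g;

    ydot[0] = stim * q - k1 * x - k2 * f1 * f3;
    ydot[1] = k3 * x * G - k4 * y;
    ydot[2] = k5 * y * H - k6 * h;
}

void tl_jac(int *neq, double *t, double *y_, int *ml, int *mu,
            double *pd, int *nrowpd, double *yout, int *ip)
{
    double x = y_[0], y = y_[1], z = y_[2];
    double k1 = p[1], k2 = p[2], k3 = p[3], k4 = p[4], k5 = p[5], k6 = p[6];
    double yT = p[7], Kx = p[8], Kz = p[9], Kq = p[10], hq = p[11];
    double Kf3 = p[12], mf3 = p[13];
    double kap_y = p[14], mg = p[15], kap_z = p[16], mH = p[17];
    double stim = p[18];
    int nr = *nrowpd;
    double q, dq, f1, df1, f3, df3, dh, g, dg, H, dH, G, dG;

    if (p[22] > 0.5) {
        double uq = R_pow(z / Kq, hq);
        q = 1.0 / (1.0 + uq);
        dq = (z > 0) ? -hq * uq / (z * (1.0 + uq) * (1.0 + uq))
                     : ((hq > 1) ? 0.0 : -1.0 / Kq);
    } else { q = 1.0; dq = 0.0; }
    if (p[19] > 0.5) { f1 = x / (Kx + x); df1 = Kx / ((Kx + x) * (Kx + x)); }
    else { f1 = x; df1 = 1.0; }
    if (p[20] > 0.5) {
        double Km = R_pow(Kf3, mf3), u = R_pow(z, mf3);
        f3 = u / (Km + u);
        df3 = (z > 0) ? mf3 * Km * u / (z * (Km + u) * (Km + u))
                      : ((mf3 > 1) ? 0.0 : 1.0 / Kf3);
    } else { f3 = z; df3 = 1.0; }
    dh = (p[21] > 0.5) ? Kz / ((Kz + z) * (Kz + z)) : 1.0;
    if (p[23] > 0.5) {
        double ug = R_pow(kap_y * y, mg);
        g = 1.0 / (1.0 + ug);
        dg = (y > 0) ? -mg * ug / (y * (1.0 + ug) * (1.0 + ug))
                     : ((mg > 1) ? 0.0 : -kap_y);
    } else { g = 1.0; dg = 0.0; }
    if (p[24] > 0.5) {
        double uH = R_pow(kap_z * z, mH);
        H = 1.0 / (1.0 + uH);
        dH = (z > 0) ? -mH * uH / (z * (1.0 + uH) * (1.0 + uH))
                     : ((mH > 1) ? 0.0 : -kap_z);
    } else { H = 1.0; dH = 0.0; }
    if (p[25] > 0.5) { G = (yT - y) * g; dG = -g + (yT - y) * dg; }
    else { G = g; dG = dg; }

    /* column-major: pd[i + j*nr] = d f_i / d y_j */
    pd[0 + 0 * nr] = -k1 - k2 * df1 * f3;
    pd[0 + 1 * nr] = 0.0;
    pd[0 + 2 * nr] = stim * dq - k2 * f1 * df3;
    pd[1 + 0 * nr] = k3 * G;
    pd[1 + 1 * nr] = k3 * x * dG - k4;
    pd[1 + 2 * nr] = 0.0;
    pd[2 + 0 * nr] = 0.0;
    pd[2 + 1 * nr] = k5 * H;
    pd[2 + 2 * nr] = k5 * y * dH - k6 * dh;
}
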