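/* Right-hand side of the extended MPDPDE system in the form expected by
 * deSolve's compiled-model interface.
 *
 * State layout: y = [nA, nB, Y(1..n), XA(1..n), XB(1..n)] on a uniform
 * radial grid r_k = k*dr, k = 1..n (separations in units of the molecular
 * reach L).  Parameters and grid are passed once per integration through
 * C_set_mpdpde_parms() and held in static storage; deSolve then calls
 * mpdpde_derivs without touching R.
 *
 * Packed parameter layout:
 *   P[0] = n, P[1] = dr, P[2] = (3/(2*pi))^(3/2)
 *   P[3..7]  = p1..p5
 *   P[8 + k]        = r_k          (k = 0..n-1)
 *   P[8 + n + k]    = w_k          (trapezoid weights on [r_1, r_max])
 *   P[8 + 2n + k]   = exp(-3 r_k^2 / 2)
 *
 * The bipolar double integrals exploit that on a uniform grid the limits
 * r_i + r_j and |r_i - r_j| fall exactly on grid nodes, so the inner
 * integral K(i,j) = G(min(r_i+r_j, r_max)) - G(|r_i-r_j|) needs only the
 * cumulative trapezoid G of s*(X(s)-1) from 0 (clamped above r_max, where
 * the correlation functions have relaxed to 1).
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define MPD_NMAX 512
#define MPD_PMAX (8 + 3 * MPD_NMAX)

static double P[MPD_PMAX];
static double GY[MPD_NMAX + 1], GXB[MPD_NMAX + 1];
static double WF[MPD_NMAX];   /* w * r * kern, inner-integral weights */
static int NEFF = 0;          /* nodes with non-negligible kernel mass */

SEXP C_set_mpdpde_parms(SEXP v)
{
    int m = LENGTH(v);
    if (m > MPD_PMAX)
        error("mpdpde parameter vector too long (grid limited to %d nodes)",
              MPD_NMAX);
    double *x = REAL(v);
    for (int i = 0; i < m; i++) P[i] = x[i];
    {
        int n = (int) P[0];
        const double *r = P + 8, *w = P + 8 + n, *kern = P + 8 + 2 * n;
        NEFF = n;
        for (int j = 0; j < n; j++) {
            WF[j] = w[j] * r[j] * kern[j];
            if (kern[j] >= 1e-12) NEFF = j + 1;
        }
    }
    return R_NilValue;
}

void mpdpde_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const int n = (int) P[0];
    const double dr = P[1], cpre = P[2];
    const double p1 = P[3], p2 = P[4], p3 = P[5], p4 = P[6], p5 = P[7];
    const double *r = P + 8, *w = P + 8 + n, *kern = P + 8 + 2 * n;

    const double nA = y[0], nB = y[1];
    const double *Y = y + 2, *XA = y + 2 + n, *XB = y + 2 + 2 * n;
    double *dY = ydot + 2, *dXA = ydot + 2 + n, *dXB = ydot + 2 + 2 * n;

    /* guarded density ratios (whole term vanishes with the numerator) */
    const double rAB = (nA > 1e-12) ? nB / nA : 0.0;  /* multiplies p2 */
    const double rBA = (nB > 1e-12) ? nA / nB : 0.0;  /* multiplies p1 */

    /* single radial integral in the nA equation and cumulative G arrays */
    double I1 = 0.0;
    GY[0] = 0.0; GXB[0] = 0.0;
    {
        double fy_prev = 0.0, fxb_prev = 0.0;  /* s*(X(s)-1) at s = 0 */
        for (int k = 0; k < n; k++) {
            I1 += w[k] * r[k] * r[k] * kern[k] * Y[k];
            double fy = r[k] * (Y[k] - 1.0);
            double fxb = r[k] * (XB[k] - 1.0);
            GY[k + 1] = GY[k] + 0.5 * (fy + fy_prev) * dr;
            GXB[k + 1] = GXB[k] + 0.5 * (fxb + fxb_prev) * dr;
            fy_prev = fy; fxb_prev = fxb;
        }
    }

    ydot[0] = -(p1 + p5) * nA + p2 * nB
              - 4.0 * M_PI * cpre * p3 * nA * nB * I1;
    ydot[1] = p1 * nA - p2 * nB;

    /* the inner integrand carries exp(-3r'^2/2): nodes beyond its support
     * (kernel < 1e-12) contribute nothing and are skipped */
    const int active = (p3 * nB > 0.0);
    for (int i = 0; i < n; i++) {
        double jxb = 0.0, jy = 0.0;
        if (active) {
            for (int j = 0; j < NEFF; j++) {
                int iu = i + j + 2;          /* node index of r_i + r_j */
                if (iu > n) iu = n;          /* G constant beyond r_max */
                int il = (i > j) ? i - j : j - i;  /* |r_i - r_j| */
                double f = WF[j] * Y[j];
                jxb += f * (GXB[iu] - GXB[il]);
                jy += f * (GY[iu] - GY[il]);
            }
        }
        dY[i] = p1 * rBA * (XA[i] - Y[i]) + p2 * rAB * (XB[i] - Y[i])
                - cpre * p4 * kern[i] * Y[i]
                - 2.0 * M_PI * cpre * p3 * nB * Y[i] / r[i] * jxb;
        dXA[i] = 2.0 * p2 * rAB * (Y[i] - XA[i])
                 - 4.0 * M_PI * cpre * p3 * nB * XA[i] / r[i] * jy;
        dXB[i] = 2.0 * p1 * rBA * (Y[i] - XB[i]);
    }
}

/* Fixed-step classical RK4 integration of the same system, marching exactly
 * onto the requested output times.  Used by the fitting stack: a fixed-grid
 * solution is a smooth function of the parameters (no adaptive step-size
 * control flow), so finite-difference Jacobians in the least-squares polish
 * are clean at machine precision.  At t >= tswitch the analyte inputs are
 * switched off (p1 = p5 = 0) to model the end of the injection.
 * Returns cbind(nA, nB) at the output times; non-finite states abort. */

static void mpd_rhs_p(const double *y, double *ydot, double p1, double p5)
{
    double save1 = P[3], save5 = P[7];
    int neq = 2 + 3 * (int) P[0];
    double t = 0.0;
    P[3] = p1; P[7] = p5;
    mpdpde_derivs(&neq, &t, (double *) y, ydot, NULL, NULL);
    P[3] = save1; P[7] = save5;
}

SEXP C_mpdpde_rk4(SEXP times_, SEXP dt_, SEXP tswitch_)
{
    const int n = (int) P[0];
    const int neq = 2 + 3 * n;
    const int nt = LENGTH(times_);
    const double *tout = REAL(times_);
    const double dt = REAL(dt_)[0];
    const double tswitch = REAL(tswitch_)[0];
    const double p1_on = P[3], p5_on = P[7];

    SEXP ans = PROTECT(allocMatrix(REALSXP, nt, 2));
    double *out = REAL(ans);

    double *y = (double *) R_alloc(neq, sizeof(double));
    double *k1 = (double *) R_alloc(neq, sizeof(double));
    double *k2 = (double *) R_alloc(neq, sizeof(double));
    double *k3 = (double *) R_alloc(neq, sizeof(double));
    double *k4 = (double *) R_alloc(neq, sizeof(double));
    double *tmp = (double *) R_alloc(neq, sizeof(double));

    y[0] = 1.0; y[1] = 0.0;
    for (int i = 2; i < neq; i++) y[i] = 1.0;

    double t = 0.0;
    int io = 0;
    if (nt > 0 && tout[0] <= 1e-12) {
        out[0] = y[0]; out[nt] = y[1]; io = 1;
    }
    while (io < nt) {
        double t_next = tout[io];
        while (t < t_next - 1e-12) {
            double h = dt;
            if (t + h > t_next) h = t_next - t;
            /* do not step across the injection switch */
            if (t < tswitch - 1e-12 && t + h > tswitch) h = tswitch - t;
            double p1 = (t >= tswitch - 1e-12) ? 0.0 : p1_on;
            double p5 = (t >= tswitch - 1e-12) ? 0.0 : p5_on;
            mpd_rhs_p(y, k1, p1, p5);
            for (int i = 0; i < neq; i++) tmp[i] = y[i] + 0.5 * h * k1[i];
            mpd_rhs_p(tmp, k2, p1, p5);
            for (int i = 0; i < neq; i++) tmp[i] = y[i] + 0.5 * h * k2[i];
            mpd_rhs_p(tmp, k3, p1, p5);
            for (int i = 0; i < neq; i++) tmp[i] = y[i] + h * k3[i];
            mpd_rhs_p(tmp, k4, p1, p5);
            for (int i = 0; i < neq; i++)
                y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
            t += h;
            /* states decay exponentially into the subnormal range where
             * x86 arithmetic slows dramatically; anything below 1e-14
             * (sites or correlation) is physically zero */
            for (int i = 0; i < neq; i++)
                if (y[i] < 1e-14 && y[i] > -1e-14) y[i] = 0.0;
            if (!R_FINITE(y[0]) || !R_FINITE(y[1])) {
                UNPROTECT(1);
                error("RK4 integration diverged at t = %g", t);
            }
        }
        out[io] = y[0]; out[nt + io] = y[1];
        io++;
    }
    UNPROTECT(1);
    return ans;
}
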