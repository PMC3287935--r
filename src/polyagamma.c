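/* Polya-Gamma PG(1, z) sampler, Devroye-type exact rejection scheme
 * (Devroye 2009; Polson, Scott & Windle 2013).  PG(1,c) = J*(1, c/2)/4
 * where J* is the tilted Jacobi-theta variable; the J* density is a
 * piecewise mixture of a truncated inverse-Gaussian body and an
 * exponential tail, accepted through the alternating partial sums of
 * its series expansion.  Uses R's RNG: callers must hold GetRNGstate().
 */
#include <R.h>
#include <Rmath.h>
#include "spikegene.h"

#define PG_TRUNC 0.64

/* series coefficients a_n(x) of the J*(1,z=0) density */
static double pg_acoef(int n, double x)
{
    double h = n + 0.5;
    if (x <= PG_TRUNC)
        return M_PI * h * pow(2.0 / (M_PI * x), 1.5) * exp(-2.0 * h * h / x);
    return M_PI * h * exp(-0.5 * h * h * M_PI * M_PI * x);
}

/* X ~ inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, t]; z >= 0 */
static double pg_rtigauss(double z, double t)
{
    double x;
    if (z < 1.0 / t) {
        /* mu > t: sample the z = 0 body x^{-3/2} exp(-1/(2x)) on (0,t]
         * by Devroye's two-exponential trick, then exp(-z^2 x / 2) tilt */
        for (;;) {
            double e1, e2;
            do {
                e1 = exp_rand();
                e2 = exp_rand();
            } while (e1 * e1 > 2.0 * e2 / t);
            x = t / ((1.0 + t * e1) * (1.0 + t * e1));
            if (unif_rand() <= exp(-0.5 * z * z * x))
                return x;
        }
    } else {
        /* mu <= t: ordinary IG draws (Michael-Schucany-Haas) until <= t */
        double mu = 1.0 / z;
        for (;;) {
            double y = norm_rand();
            y *= y;
            x = mu + 0.5 * mu * mu * y -
                0.5 * mu * sqrt(4.0 * mu * y + mu * mu * y * y);
            if (unif_rand() > mu / (mu + x))
                x = mu * mu / x;
            if (x <= t)
                return x;
        }
    }
}

/* log P(IG(1/z, 1) <= t), stable for large z */
static double pg_ltigauss_mass(double z, double t)
{
    double rt = 1.0 / sqrt(t);
    double a = pnorm(rt * (t * z - 1.0), 0.0, 1.0, 1, 0);
    double lb = 2.0 * z + pnorm(-rt * (t * z + 1.0), 0.0, 1.0, 1, 1);
    /* log(a + exp(lb)) */
    if (a <= 0.0)
        return lb;
    return log(a) + log1p(exp(lb - log(a)));
}

double spikegene_rpg1(double c)
{
    double z = 0.5 * fabs(c);
    double t = PG_TRUNC;
    double K = 0.125 * M_PI * M_PI + 0.5 * z * z;
    double logp = log(M_PI / (2.0 * K)) - K * t;           /* tail piece */
    double logq = M_LN2 - z + pg_ltigauss_mass(z, t);      /* body piece */
    double ptail = 1.0 / (1.0 + exp(logq - logp));

    for (;;) {
        double x;
        if (unif_rand() < ptail)
            x = t + exp_rand() / K;
        else
            x = pg_rtigauss(z, t);

        double s = pg_acoef(0, x);
        double y = unif_rand() * s;
        int n = 0;
        for (;;) {
            n++;
            if (n & 1) {
                s -= pg_acoef(n, x);
                if (y <= s)
                    return 0.25 * x;
            } else {
                s += pg_acoef(n, x);
                if (y > s)
                    break;      /* reject, restart outer loop */
            }
        }
    }
}

/* .Call: vector of PG(1, z_i) draws */
SEXP C_rpg(SEXP n_, SEXP z_)
{
    int n = asInteger(n_);
    int nz = LENGTH(z_);
    double *z = REAL(z_);
    SEXP out = PROTECT(allocVector(REALSXP, n));
    double *o = REAL(out);
    GetRNGstate();
    for (int i = 0; i < n; i++)
        o[i] = spikegene_rpg1(z[i % nz]);
    PutRNGstate();
    UNPROTECT(1);
    return out;
}
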