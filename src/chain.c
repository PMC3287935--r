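/* MH-within-Gibbs sweep for the spike-and-slab liability model.
 *
 * Model: y_i ~ Bernoulli(logit^-1(eta_i)), eta = X beta + Z (w o u),
 * u_j | w_j=1 ~ N(0, sigma2_u), P(w_j=1) = lambda, lambda ~ Beta(c,d),
 * sigma2_u ~ Scaled-Inv-Chisq(nu, s2), beta flat.  Polya-Gamma
 * augmentation (omega_i ~ PG(1, eta_i)) makes every conditional
 * Gaussian or standard, so beta and (w_j,u_j) admit exact draws; the
 * paper-style plug-in MH update for (w_j,u_j) and the prior-proposal
 * MH update for lambda are kept as alternative modes.
 *
 * Design columns are stored as base value + sparse deviations, so a
 * (w_j,u_j) update costs O(#carriers of SNP j) rather than O(n); with
 * the rare-skewed MAF spectra this code targets, that is the
 * difference between minutes and hours per chain.
 */
#include <R.h>
#include <Rmath.h>
#include "spikegene.h"

typedef struct {
    double base;    /* modal column value */
    int nnz;        /* deviating entries */
    int *idx;
    double *sval;   /* z[idx] - base */
} spcol;

/* modal value of a column (at most a handful of distinct values in
 * practice; sort-and-scan keeps it exact for arbitrary input) */
static double col_mode(const double *z, int n, double *work)
{
    memcpy(work, z, n * sizeof(double));
    R_rsort(work, n);
    double best = work[0], cur = work[0];
    int bestc = 1, curc = 1;
    for (int i = 1; i < n; i++) {
        if (work[i] == cur) {
            curc++;
        } else {
            if (curc > bestc) { bestc = curc; best = cur; }
            cur = work[i];
            curc = 1;
        }
    }
    if (curc > bestc) best = cur;
    return best;
}

/* lower-triangular Cholesky in place; returns 0 on success */
static int chol_lower(double *A, int p)
{
    for (int j = 0; j < p; j++) {
        double d = A[j + j * p];
        for (int k = 0; k < j; k++) d -= A[j + k * p] * A[j + k * p];
        if (d <= 0.0) return 1;
        d = sqrt(d);
        A[j + j * p] = d;
        for (int i = j + 1; i < p; i++) {
            double s = A[i + j * p];
            for (int k = 0; k < j; k++) s -= A[i + k * p] * A[j + k * p];
            A[i + j * p] = s / d;
        }
    }
    return 0;
}

static void solve_lower(const double *L, double *b, int p)     /* L x = b */
{
    for (int i = 0; i < p; i++) {
        double s = b[i];
        for (int k = 0; k < i; k++) s -= L[i + k * p] * b[k];
        b[i] = s / L[i + i * p];
    }
}

static void solve_upper_t(const double *L, double *b, int p)   /* L' x = b */
{
    for (int i = p - 1; i >= 0; i--) {
        double s = b[i];
        for (int k = i + 1; k < p; k++) s -= L[k + i * p] * b[k];
        b[i] = s / L[i + i * p];
    }
}

SEXP C_run_chain(SEXP y_, SEXP X_, SEXP Z_, SEXP prior_, SEXP config_,
                 SEXP init_, SEXP modes_)
{
    const int *y = INTEGER(y_);
    const double *X = REAL(X_);
    const double *Z = REAL(Z_);
    const int n = nrows(X_), p = ncols(X_), m = ncols(Z_);
    if (nrows(Z_) != n || LENGTH(y_) != n)
        error("dimension mismatch between y, X and Z");

    const double lc = REAL(prior_)[0], ld = REAL(prior_)[1];
    const double nu = REAL(prior_)[2], s2 = REAL(prior_)[3];

    const int n_iter = INTEGER(config_)[0];
    const int burn = INTEGER(config_)[1];
    const int thin = INTEGER(config_)[2];
    const int S = (n_iter - burn) / thin;
    if (S < 1) error("MCMC schedule leaves no stored draws");

    const int wu_mode = INTEGER(modes_)[0];      /* 0 marginal, 1 mh_plugin */
    const int lam_mode = INTEGER(modes_)[1];     /* 0 gibbs, 1 mh, 2 fixed  */
    const int sig_mode = INTEGER(modes_)[2];     /* 0 gibbs, 2 fixed        */
    const int scan = INTEGER(modes_)[3];         /* 0 fixed, 1 random       */

    /* state from init list: beta, u, w, lambda, sigma2 */
    double *beta = (double *) R_alloc(p, sizeof(double));
    double *u = (double *) R_alloc(m, sizeof(double));
    int *w = (int *) R_alloc(m, sizeof(int));
    memcpy(beta, REAL(VECTOR_ELT(init_, 0)), p * sizeof(double));
    memcpy(u, REAL(VECTOR_ELT(init_, 1)), m * sizeof(double));
    memcpy(w, INTEGER(VECTOR_ELT(init_, 2)), m * sizeof(int));
    double lam = asReal(VECTOR_ELT(init_, 3));
    double sig2 = asReal(VECTOR_ELT(init_, 4));

    /* sparse columns */
    spcol *col = (spcol *) R_alloc(m, sizeof(spcol));
    double *work = (double *) R_alloc(n, sizeof(double));
    for (int j = 0; j < m; j++) {
        const double *zj = Z + (size_t) j * n;
        double b = col_mode(zj, n, work);
        int nnz = 0;
        for (int i = 0; i < n; i++) if (zj[i] != b) nnz++;
        col[j].base = b;
        col[j].nnz = nnz;
        col[j].idx = (int *) R_alloc(nnz > 0 ? nnz : 1, sizeof(int));
        col[j].sval = (double *) R_alloc(nnz > 0 ? nnz : 1, sizeof(double));
        int k = 0;
        for (int i = 0; i < n; i++)
            if (zj[i] != b) { col[j].idx[k] = i; col[j].sval[k] = zj[i] - b; k++; }
    }

    double *om = (double *) R_alloc(n, sizeof(double));
    double *hh = (double *) R_alloc(n, sizeof(double));  /* X beta + sparse genetic */
    double *kappa = (double *) R_alloc(n, sizeof(double));
    double Skappa = 0.0;
    for (int i = 0; i < n; i++) { kappa[i] = y[i] - 0.5; Skappa += kappa[i]; }

    double *A = (double *) R_alloc(p * p, sizeof(double));
    double *rhs = (double *) R_alloc(p, sizeof(double));
    double *zdraw = (double *) R_alloc(p, sizeof(double));
    int *order = (int *) R_alloc(m, sizeof(int));
    for (int j = 0; j < m; j++) order[j] = j;

    SEXP out_lam = PROTECT(allocVector(REALSXP, S));
    SEXP out_sig = PROTECT(allocVector(REALSXP, S));
    SEXP out_beta = PROTECT(allocMatrix(REALSXP, S, p));
    SEXP out_w = PROTECT(allocMatrix(INTSXP, S, m));
    SEXP out_u = PROTECT(allocMatrix(REALSXP, S, m));
    SEXP out_acc = PROTECT(allocVector(REALSXP, 4)); /* wu prop/acc, lam prop/acc */
    double *acc = REAL(out_acc);
    acc[0] = acc[1] = acc[2] = acc[3] = 0.0;

    GetRNGstate();
    int stored = 0;
    for (int iter = 1; iter <= n_iter; iter++) {
        /* rebuild genetic predictor from scratch (kills float drift) */
        double B = 0.0;
        for (int i = 0; i < n; i++) {
            double s = 0.0;
            for (int k = 0; k < p; k++) s += X[i + (size_t) k * n] * beta[k];
            hh[i] = s;
        }
        for (int j = 0; j < m; j++) {
            if (!w[j] || u[j] == 0.0) continue;
            B += col[j].base * u[j];
            for (int k = 0; k < col[j].nnz; k++)
                hh[col[j].idx[k]] += col[j].sval[k] * u[j];
        }

        /* -- omega | eta : Polya-Gamma -- */
        for (int i = 0; i < n; i++)
            om[i] = spikegene_rpg1(hh[i] + B);

        /* -- beta | rest : MVN -- */
        for (int j = 0; j < p; j++) {
            for (int k = j; k < p; k++) {
                double s = 0.0;
                const double *xj = X + (size_t) j * n, *xk = X + (size_t) k * n;
                for (int i = 0; i < n; i++) s += xj[i] * om[i] * xk[i];
                A[k + j * p] = s;
                A[j + k * p] = s;
            }
        }
        for (int k = 0; k < p; k++) {
            double s = 0.0;
            const double *xk = X + (size_t) k * n;
            for (int i = 0; i < n; i++) {
                double g = hh[i] + B;       /* still includes X beta ... */
                double xb = 0.0;
                for (int q = 0; q < p; q++) xb += X[i + (size_t) q * n] * beta[q];
                s += xk[i] * (kappa[i] - om[i] * (g - xb));
            }
            rhs[k] = s;
        }
        if (chol_lower(A, p)) {
            PutRNGstate();
            error("singular precision matrix in beta update");
        }
        solve_lower(A, rhs, p);
        solve_upper_t(A, rhs, p);           /* rhs = conditional mean */
        for (int k = 0; k < p; k++) zdraw[k] = norm_rand();
        solve_upper_t(A, zdraw, p);
        /* update hh for new beta: hh += X (beta_new - beta_old) */
        for (int k = 0; k < p; k++) {
            double bn = rhs[k] + zdraw[k];
            double db = bn - beta[k];
            beta[k] = bn;
            if (db != 0.0) {
                const double *xk = X + (size_t) k * n;
                for (int i = 0; i < n; i++) hh[i] += xk[i] * db;
            }
        }

        /* scalars for the sparse dot products */
        double Som = 0.0, Soh = 0.0;
        for (int i = 0; i < n; i++) { Som += om[i]; Soh += om[i] * hh[i]; }

        /* -- (w_j, u_j) for every SNP -- */
        if (scan == 1) {            /* Fisher-Yates */
            for (int j = m - 1; j > 0; j--) {
                int k = (int) (unif_rand() * (j + 1));
                if (k > j) k = j;
                int t = order[j]; order[j] = order[k]; order[k] = t;
            }
        }
        for (int jj = 0; jj < m; jj++) {
            int j = order[jj];
            const spcol *cj = &col[j];
            double Sc = Skappa - Soh - B * Som;
            double d1 = cj->base * Sc;
            double d2 = cj->base * cj->base * Som;
            for (int k = 0; k < cj->nnz; k++) {
                int i = cj->idx[k];
                double s = cj->sval[k];
                d1 += s * (kappa[i] - om[i] * (hh[i] + B));
                d2 += om[i] * s * (2.0 * cj->base + s);
            }
            double cur = w[j] ? u[j] : 0.0;
            double s1 = d1 + cur * d2;      /* z_j'(kappa - Omega eta_{-j}) */
            double v = 1.0 / (d2 + 1.0 / sig2);
            double mc = v * s1;

            int wn; double un;
            if (wu_mode == 0) {
                double logodds = log(lam) - log1p(-lam)
                    + 0.5 * log(v / sig2) + 0.5 * mc * mc / v;
                double pi1 = 1.0 / (1.0 + exp(-logodds));
                wn = unif_rand() < pi1;
                un = wn ? mc + sqrt(v) * norm_rand() : 0.0;
                acc[0] += 1.0; acc[1] += 1.0;
            } else {
                int wp = unif_rand() < 0.5;
                double up = wp ? mc : 0.0;  /* plug-in conditional mean */
                double lt_p = up * s1 - 0.5 * up * up * d2
                    + (wp ? log(lam) + dnorm(up, 0.0, sqrt(sig2), 1) : log1p(-lam));
                double lt_c = cur * s1 - 0.5 * cur * cur * d2
                    + (w[j] ? log(lam) + dnorm(cur, 0.0, sqrt(sig2), 1) : log1p(-lam));
                double lq_f = wp ? dnorm(up, mc, sqrt(v), 1) : 0.0;
                double lq_r = w[j] ? dnorm(cur, mc, sqrt(v), 1) : 0.0;
                double loga = lt_p - lt_c + lq_r - lq_f;
                acc[0] += 1.0;
                if (log(unif_rand()) < loga) {
                    acc[1] += 1.0;
                    wn = wp; un = up;
                } else {
                    wn = w[j]; un = cur;
                }
            }

            double delta = (wn ? un : 0.0) - cur;
            if (delta != 0.0) {
                B += cj->base * delta;
                for (int k = 0; k < cj->nnz; k++) {
                    int i = cj->idx[k];
                    hh[i] += cj->sval[k] * delta;
                    Soh += om[i] * cj->sval[k] * delta;
                }
            }
            w[j] = wn;
            u[j] = wn ? un : 0.0;
        }

        /* -- lambda -- */
        int kact = 0;
        for (int j = 0; j < m; j++) kact += w[j];
        if (lam_mode == 0) {
            lam = rbeta(lc + kact, ld + m - kact);
        } else if (lam_mode == 1) {
            double prop = rbeta(lc, ld);
            double loga = kact * (log(prop) - log(lam))
                + (m - kact) * (log1p(-prop) - log1p(-lam));
            acc[2] += 1.0;
            if (log(unif_rand()) < loga) { lam = prop; acc[3] += 1.0; }
        }
        if (lam < 1e-12) lam = 1e-12;
        if (lam > 1.0 - 1e-12) lam = 1.0 - 1e-12;

        /* -- sigma2_u -- */
        if (sig_mode == 0) {
            double ssq = 0.0;
            for (int j = 0; j < m; j++) if (w[j]) ssq += u[j] * u[j];
            sig2 = (nu * s2 + ssq) / rchisq(nu + kact);
        }

        if (iter > burn && (iter - burn) % thin == 0) {
            REAL(out_lam)[stored] = lam;
            REAL(out_sig)[stored] = sig2;
            for (int k = 0; k < p; k++)
                REAL(out_beta)[stored + (size_t) k * S] = beta[k];
            for (int j = 0; j < m; j++) {
                INTEGER(out_w)[stored + (size_t) j * S] = w[j];
                REAL(out_u)[stored + (size_t) j * S] = u[j];
            }
            stored++;
        }
        if ((iter & 1023) == 0) R_CheckUserInterrupt();
    }
    PutRNGstate();

    SEXP out = PROTECT(allocVector(VECSXP, 6));
    SET_VECTOR_ELT(out, 0, out_lam);
    SET_VECTOR_ELT(out, 1, out_sig);
    SET_VECTOR_ELT(out, 2, out_beta);
    SET_VECTOR_ELT(out, 3, out_w);
    SET_VECTOR_ELT(out, 4, out_u);
    SET_VECTOR_ELT(out, 5, out_acc);
    SEXP nm = PROTECT(allocVector(STRSXP, 6));
    const char *names[] = {"lambda", "sigma2", "beta", "w", "u", "accept"};
    for (int k = 0; k < 6; k++) SET_STRING_ELT(nm, k, mkChar(names[k]));
    setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(8);
    return out;
}
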