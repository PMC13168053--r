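/* Mass-action ODE kernels for the ERK-cascade networks.
 *
 * The network is staged once per simulation via C_set_network(); deSolve's
 * lsoda then calls cascade_derivs()/cascade_jac() through the compiled-model
 * interface.  Flux convention: flux_r = k_r * y[re1_r] * y[re2_r] (re2 < 0
 * for unimolecular reactions); stoichiometry is stored in CSR triplets, so
 * A + A -> B has flux k*A^2 and consumes two A per event.
 *
 * C_rk4() is a self-contained fixed-step Runge-Kutta 4 integrator used as an
 * independent cross-check of the adaptive solver; it takes the network
 * arrays as arguments and shares no state with the staged network.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>
#include <string.h>

static int g_nspec = 0, g_nreac = 0;
static double *g_k = NULL;
static int *g_re1 = NULL, *g_re2 = NULL, *g_sptr = NULL, *g_sidx = NULL;
static double *g_sval = NULL;
static int g_cap_reac = 0, g_cap_trip = 0;

static void ensure_capacity(int nreac, int ntrip)
{
    if (nreac > g_cap_reac) {
        g_k = (double *) R_Realloc(g_k, nreac, double);
        g_re1 = (int *) R_Realloc(g_re1, nreac, int);
        g_re2 = (int *) R_Realloc(g_re2, nreac, int);
        g_sptr = (int *) R_Realloc(g_sptr, nreac + 1, int);
        g_cap_reac = nreac;
    }
    if (ntrip > g_cap_trip) {
        g_sidx = (int *) R_Realloc(g_sidx, ntrip, int);
        g_sval = (double *) R_Realloc(g_sval, ntrip, double);
        g_cap_trip = ntrip;
    }
}

SEXP C_set_network(SEXP nspec_, SEXP re1_, SEXP re2_, SEXP sptr_, SEXP sidx_,
                   SEXP sval_, SEXP k_)
{
    int nreac = LENGTH(re1_);
    int ntrip = LENGTH(sidx_);
    ensure_capacity(nreac, ntrip);
    g_nspec = INTEGER(nspec_)[0];
    g_nreac = nreac;
    memcpy(g_re1, INTEGER(re1_), nreac * sizeof(int));
    memcpy(g_re2, INTEGER(re2_), nreac * sizeof(int));
    memcpy(g_sptr, INTEGER(sptr_), (nreac + 1) * sizeof(int));
    memcpy(g_sidx, INTEGER(sidx_), ntrip * sizeof(int));
    memcpy(g_sval, REAL(sval_), ntrip * sizeof(double));
    memcpy(g_k, REAL(k_), nreac * sizeof(double));
    return R_NilValue;
}

/* deSolve compiled-model derivative: ydot = S %*% flux(y) */
void cascade_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int r, j;
    for (j = 0; j < *neq; j++) ydot[j] = 0.0;
    for (r = 0; r < g_nreac; r++) {
        double flux = g_k[r] * y[g_re1[r]];
        if (g_re2[r] >= 0) flux *= y[g_re2[r]];
        for (j = g_sptr[r]; j < g_sptr[r + 1]; j++)
            ydot[g_sidx[j]] += g_sval[j] * flux;
    }
}

/* analytic full Jacobian of the mass-action system */
void cascade_jac(int *neq, double *t, double *y, int *ml, int *mu,
                 double *pd, int *nrowpd, double *yout, int *ip)
{
    int r, j, n = *neq, nr = *nrowpd;
    memset(pd, 0, (size_t) n * nr * sizeof(double));
    for (r = 0; r < g_nreac; r++) {
        int i1 = g_re1[r], i2 = g_re2[r];
        /* d flux / d y[i1], and if bimolecular d flux / d y[i2] */
        double d1 = g_k[r] * (i2 >= 0 ? y[i2] : 1.0);
        for (j = g_sptr[r]; j < g_sptr[r + 1]; j++)
            pd[g_sidx[j] + (size_t) nr * i1] += g_sval[j] * d1;
        if (i2 >= 0) {
            double d2 = g_k[r] * y[i1];
            for (j = g_sptr[r]; j < g_sptr[r + 1]; j++)
                pd[g_sidx[j] + (size_t) nr * i2] += g_sval[j] * d2;
        }
    }
}

/* Independent fixed-step RK4 integrator over [0, max(times)].
 * times must be (near-)integer multiples of dt. */
static void rhs_raw(int n, int nreac, const int *re1, const int *re2,
                    const int *sptr, const int *sidx, const double *sval,
                    const double *k, const double *y, double *ydot)
{
    int r, j;
    for (j = 0; j < n; j++) ydot[j] = 0.0;
    for (r = 0; r < nreac; r++) {
        double flux = k[r] * y[re1[r]];
        if (re2[r] >= 0) flux *= y[re2[r]];
        for (j = sptr[r]; j < sptr[r + 1]; j++)
            ydot[sidx[j]] += sval[j] * flux;
    }
}

SEXP C_rk4(SEXP y0_, SEXP re1_, SEXP re2_, SEXP sptr_, SEXP sidx_, SEXP sval_,
           SEXP k_, SEXP dt_, SEXP times_)
{
    int n = LENGTH(y0_), nreac = LENGTH(re1_), nt = LENGTH(times_);
    const int *re1 = INTEGER(re1_), *re2 = INTEGER(re2_);
    const int *sptr = INTEGER(sptr_), *sidx = INTEGER(sidx_);
    const double *sval = REAL(sval_), *k = REAL(k_);
    double dt = REAL(dt_)[0];
    const double *times = REAL(times_);

    SEXP out_ = PROTECT(allocMatrix(REALSXP, n, nt));
    double *out = REAL(out_);

    double *y = (double *) R_alloc(n, sizeof(double));
    double *yt = (double *) R_alloc(n, sizeof(double));
    double *k1 = (double *) R_alloc(n, sizeof(double));
    double *k2 = (double *) R_alloc(n, sizeof(double));
    double *k3 = (double *) R_alloc(n, sizeof(double));
    double *k4 = (double *) R_alloc(n, sizeof(double));
    memcpy(y, REAL(y0_), n * sizeof(double));

    long nsteps = lround(times[nt - 1] / dt);
    long *rec = (long *) R_alloc(nt, sizeof(long));
    int ti;
    for (ti = 0; ti < nt; ti++) rec[ti] = lround(times[ti] / dt);

    int next = 0, j;
    long s;
    for (ti = 0; ti < nt && rec[ti] == 0; ti++) {
        memcpy(out + (size_t) ti * n, y, n * sizeof(double));
        next = ti + 1;
    }
    for (s = 1; s <= nsteps; s++) {
        rhs_raw(n, nreac, re1, re2, sptr, sidx, sval, k, y, k1);
        for (j = 0; j < n; j++) yt[j] = y[j] + 0.5 * dt * k1[j];
        rhs_raw(n, nreac, re1, re2, sptr, sidx, sval, k, yt, k2);
        for (j = 0; j < n; j++) yt[j] = y[j] + 0.5 * dt * k2[j];
        rhs_raw(n, nreac, re1, re2, sptr, sidx, sval, k, yt, k3);
        for (j = 0; j < n; j++) yt[j] = y[j] + dt * k3[j];
        rhs_raw(n, nreac, re1, re2, sptr, sidx, sval, k, yt, k4);
        for (j = 0; j < n; j++)
            y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
        while (next < nt && rec[next] == s) {
            memcpy(out + (size_t) next * n, y, n * sizeof(double));
            next++;
        }
        if ((s & 0xFFFFF) == 0) R_CheckUserInterrupt();
    }
    UNPROTECT(1);
    return out_;
}

static const R_CallMethodDef call_entries[] = {
    {"C_set_network", (DL_FUNC) &C_set_network, 7},
    {"C_rk4", (DL_FUNC) &C_rk4, 9},
    {NULL, NULL, 0}
};

void R_init_cascadefit(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    /* keep dynamic lookup available for deSolve's symbol resolution */
    R_useDynamicSymbols(dll, TRUE);
}
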