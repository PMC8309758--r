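/* Direct-form II transposed IIR filter, single forward pass.
   Coefficients must be normalized so a[0] == 1 (as returned by the usual
   Butterworth designs).  Used by the zero-phase band-pass, which runs this
   forward and backward over a reflect-padded signal. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP accelalign_iir(SEXP b_, SEXP a_, SEXP x_)
{
    int nb = LENGTH(b_), na = LENGTH(a_);
    R_xlen_t n = XLENGTH(x_);
    double *b = REAL(b_), *a = REAL(a_), *x = REAL(x_);
    SEXP y_ = PROTECT(allocVector(REALSXP, n));
    double *y = REAL(y_);
    int nz = (nb > na ? nb : na) - 1;
    double *z = (double *) R_alloc(nz, sizeof(double));
    for (int j = 0; j < nz; j++) z[j] = 0.0;
    for (R_xlen_t i = 0; i < n; i++) {
        double xi = x[i];
        double yi = b[0] * xi + z[0];
        if (yi > -1e-30 && yi < 1e-30) yi = 0.0;  /* pre-feedback flush */
        for (int j = 0; j < nz - 1; j++) {
            z[j] = z[j + 1];
            if (j + 1 < nb) z[j] += b[j + 1] * xi;
            if (j + 1 < na) z[j] -= a[j + 1] * yi;
        }
        z[nz - 1] = 0.0;
        if (nz < nb) z[nz - 1] += b[nz] * xi;
        if (nz < na) z[nz - 1] -= a[nz] * yi;
        y[i] = yi;
    }
    UNPROTECT(1);
    return y_;
}

/* Zero-phase pass: forward filter, then the same filter run backward over
   the forward result.  Both passes start from zero state; the caller
   supplies a reflect-padded signal and trims the pads afterwards. */
SEXP accelalign_filtfilt(SEXP b_, SEXP a_, SEXP x_)
{
    int nb = LENGTH(b_), na = LENGTH(a_);
    R_xlen_t n = XLENGTH(x_);
    double *b = REAL(b_), *a = REAL(a_), *x = REAL(x_);
    SEXP y_ = PROTECT(allocVector(REALSXP, n));
    double *y = REAL(y_);
    int nz = (nb > na ? nb : na) - 1;
    double *z = (double *) R_alloc(nz, sizeof(double));
    int j;
    for (j = 0; j < nz; j++) z[j] = 0.0;
    for (R_xlen_t i = 0; i < n; i++) {
        double xi = x[i];
        double yi = b[0] * xi + z[0];
        /* flush-to-zero far below signal scale BEFORE feedback: long zero
           runs in the input otherwise decay into subnormals and stall the
           FPU */
        if (yi > -1e-30 && yi < 1e-30) yi = 0.0;
        for (j = 0; j < nz - 1; j++) {
            z[j] = z[j + 1];
            if (j + 1 < nb) z[j] += b[j + 1] * xi;
            if (j + 1 < na) z[j] -= a[j + 1] * yi;
        }
        z[nz - 1] = 0.0;
        if (nz < nb) z[nz - 1] += b[nz] * xi;
        if (nz < na) z[nz - 1] -= a[nz] * yi;
        y[i] = yi;
    }
    for (j = 0; j < nz; j++) z[j] = 0.0;
    for (R_xlen_t i = n - 1; i >= 0; i--) {
        double xi = y[i];
        double yi = b[0] * xi + z[0];
        /* flush-to-zero far below signal scale BEFORE feedback: long zero
           runs in the input otherwise decay into subnormals and stall the
           FPU */
        if (yi > -1e-30 && yi < 1e-30) yi = 0.0;
        for (j = 0; j < nz - 1; j++) {
            z[j] = z[j + 1];
            if (j + 1 < nb) z[j] += b[j + 1] * xi;
            if (j + 1 < na) z[j] -= a[j + 1] * yi;
        }
        z[nz - 1] = 0.0;
        if (nz < nb) z[nz - 1] += b[nz] * xi;
        if (nz < na) z[nz - 1] -= a[nz] * yi;
        y[i] = yi;
    }
    UNPROTECT(1);
    return y_;
}

/* Per-sample Euclidean norm minus one over an n x 3 column-major matrix. */
SEXP accelalign_enmo(SEXP m_)
{
    R_xlen_t n = XLENGTH(m_) / 3;
    double *m = REAL(m_);
    SEXP e_ = PROTECT(allocVector(REALSXP, n));
    double *e = REAL(e_);
    double *xc = m, *yc = m + n, *zc = m + 2 * n;
    for (R_xlen_t i = 0; i < n; i++)
        e[i] = sqrt(xc[i] * xc[i] + yc[i] * yc[i] + zc[i] * zc[i]) - 1.0;
    UNPROTECT(1);
    return e_;
}

static const R_CallMethodDef CallEntries[] = {
    {"accelalign_iir", (DL_FUNC) &accelalign_iir, 3},
    {"accelalign_filtfilt", (DL_FUNC) &accelalign_filtfilt, 3},
    {"accelalign_enmo", (DL_FUNC) &accelalign_enmo, 1},
    {NULL, NULL, 0}
};

void R_init_accelalign(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
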