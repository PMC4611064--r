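/* Cascaded second-order-section (biquad) IIR filtering, direct form II
 * transposed.  Hot path of the filter bank: called once per channel, band
 * and trial.  sos: n_sections x 6 matrix (b0 b1 b2 a0 a1 a2), a0 == 1. */

#include <R.h>
#include <Rinternals.h>

SEXP C_sosfilt(SEXP sos_, SEXP gain_, SEXP x_)
{
    const double *sos = REAL(sos_);
    const int nsec = Rf_nrows(sos_);
    const double gain = Rf_asReal(gain_);
    const R_xlen_t n = XLENGTH(x_);
    const double *x = REAL(x_);

    SEXP y_ = PROTECT(Rf_allocVector(REALSXP, n));
    double *y = REAL(y_);
    for (R_xlen_t i = 0; i < n; i++) y[i] = x[i] * gain;

    for (int s = 0; s < nsec; s++) {
        const double b0 = sos[s], b1 = sos[s + nsec], b2 = sos[s + 2 * nsec];
        const double a1 = sos[s + 4 * nsec], a2 = sos[s + 5 * nsec];
        double z1 = 0.0, z2 = 0.0;
        for (R_xlen_t i = 0; i < n; i++) {
            const double xi = y[i];
            const double yi = b0 * xi + z1;
            z1 = b1 * xi - a1 * yi + z2;
            z2 = b2 * xi - a2 * yi;
            y[i] = yi;
        }
    }
    UNPROTECT(1);
    return y_;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_sosfilt", (DL_FUNC) &C_sosfilt, 3},
    {NULL, NULL, 0}
};

void R_init_fbcsp(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
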