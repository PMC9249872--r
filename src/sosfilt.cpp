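#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct-form II transposed biquad cascade with steady-state initial
// conditions (per-section lfilter_zi), applied forward and backward over an
// odd-reflection-padded series. High-order narrow-band IIR filters are
// numerically unusable in a single direct-form recursion at double
// precision; second-order sections keep every stage well conditioned.

static void sos_pass(const NumericMatrix &sos, std::vector<double> &x) {
    const int nsec = sos.nrow();
    const int n = (int)x.size();
    for (int s = 0; s < nsec; ++s) {
        const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
        const double a1 = sos(s, 4), a2 = sos(s, 5);
        // steady-state unit-step state: y_s = H(1), z1 = y_s - b0, z2 = b2 - a2*y_s
        const double den = 1.0 + a1 + a2;
        double zi1 = 0.0, zi2 = 0.0;
        if (den != 0.0) {
            const double ys = (b0 + b1 + b2) / den;
            zi1 = ys - b0;
            zi2 = b2 - a2 * ys;
        }
        double z1 = zi1 * x[0], z2 = zi2 * x[0];
        for (int i = 0; i < n; ++i) {
            const double xi = x[i];
            const double yi = b0 * xi + z1;
            z1 = b1 * xi + z2 - a1 * yi;
            z2 = b2 * xi - a2 * yi;
            x[i] = yi;
        }
    }
}

// [[Rcpp::export(name = ".sos_filtfilt_mat")]]
NumericMatrix sos_filtfilt_mat(NumericMatrix sos, double g, NumericMatrix x,
                               int pad) {
    const int n = x.nrow(), ncol = x.ncol();
    if (n < 2) stop("need at least 2 samples");
    if (pad >= n) pad = n - 1;
    if (pad < 0) pad = 0;
    const int m = n + 2 * pad;
    NumericMatrix out(n, ncol);
    std::vector<double> xe(m);
    for (int j = 0; j < ncol; ++j) {
        // odd reflection about both end points
        for (int i = 0; i < pad; ++i)
            xe[i] = 2.0 * x(0, j) - x(pad - i, j);
        for (int i = 0; i < n; ++i)
            xe[pad + i] = x(i, j);
        for (int i = 0; i < pad; ++i)
            xe[pad + n + i] = 2.0 * x(n - 1, j) - x(n - 2 - i, j);
        // the overall gain belongs to each pass: filtfilt realizes |H|^2
        for (int i = 0; i < m; ++i) xe[i] *= g;
        sos_pass(sos, xe);
        std::reverse(xe.begin(), xe.end());
        for (int i = 0; i < m; ++i) xe[i] *= g;
        sos_pass(sos, xe);
        std::reverse(xe.begin(), xe.end());
        for (int i = 0; i < n; ++i) out(i, j) = xe[pad + i];
    }
    return out;
}
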