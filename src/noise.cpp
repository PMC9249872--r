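#include <Rcpp.h>
using namespace Rcpp;

// Sensor-noise addition and 8-bit quantization fused into one pass (uses
// R's RNG, so results follow the caller's seed).
// [[Rcpp::export(name = ".noise_quantize_cpp")]]
NumericVector noise_quantize_cpp(NumericVector x, double sd, bool quantize) {
    const R_xlen_t n = x.size();
    NumericVector out(no_init(n));
    RNGScope scope;
    if (sd > 0) {
        for (R_xlen_t i = 0; i < n; ++i) out[i] = x[i] + R::norm_rand() * sd;
    } else {
        for (R_xlen_t i = 0; i < n; ++i) out[i] = x[i];
    }
    if (quantize) {
        for (R_xlen_t i = 0; i < n; ++i) {
            double v = std::nearbyint(out[i]);
            if (v < 0.0) v = 0.0;
            if (v > 255.0) v = 255.0;
            out[i] = v;
        }
    }
    return out;
}
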