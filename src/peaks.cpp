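#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Local maxima with plateau handling (plateau reported at its midpoint).
static std::vector<int> local_maxima(const std::vector<double> &x) {
    std::vector<int> out;
    const int n = (int)x.size();
    int i = 1;
    while (i < n - 1) {
        if (x[i] > x[i - 1]) {
            if (x[i] > x[i + 1]) {
                out.push_back(i);
                i += 2;
                continue;
            }
            if (x[i] == x[i + 1]) {
                int j = i + 1;
                while (j < n - 1 && x[j] == x[i]) ++j;
                if (x[j] < x[i]) out.push_back((i + j - 1) / 2);
                i = j;
                continue;
            }
        }
        ++i;
    }
    return out;
}

// Topographic prominence: lowest contour line enclosing only this peak.
static double prominence_at(const std::vector<double> &x, int p) {
    const int n = (int)x.size();
    double lmin = x[p], rmin = x[p];
    for (int j = p - 1; j >= 0; --j) {
        if (x[j] > x[p]) break;
        if (x[j] < lmin) lmin = x[j];
    }
    for (int j = p + 1; j < n; ++j) {
        if (x[j] > x[p]) break;
        if (x[j] < rmin) rmin = x[j];
    }
    return x[p] - std::max(lmin, rmin);
}

// prominence filter, then minimum-distance filter keeping higher peaks first
static std::vector<int> select_peaks(const std::vector<double> &x,
                                     int min_dist, double prom) {
    std::vector<int> cand = local_maxima(x);
    std::vector<int> keep;
    for (int p : cand)
        if (prominence_at(x, p) >= prom) keep.push_back(p);
    if (min_dist > 1 && keep.size() > 1) {
        std::vector<int> order(keep.size());
        for (size_t k = 0; k < keep.size(); ++k) order[k] = (int)k;
        std::sort(order.begin(), order.end(), [&](int a, int b) {
            return x[keep[a]] > x[keep[b]];
        });
        std::vector<bool> removed(keep.size(), false);
        for (int k : order) {
            if (removed[k]) continue;
            for (size_t j = 0; j < keep.size(); ++j) {
                if ((int)j == k || removed[j]) continue;
                if (std::abs(keep[j] - keep[k]) < min_dist) removed[j] = true;
            }
        }
        std::vector<int> out;
        for (size_t k = 0; k < keep.size(); ++k)
            if (!removed[k]) out.push_back(keep[k]);
        keep = out;
    }
    return keep;
}

// [[Rcpp::export(name = ".find_peaks_cpp")]]
IntegerVector find_peaks_cpp(NumericVector x, int min_dist, double prom) {
    std::vector<double> v(x.begin(), x.end());
    std::vector<int> p = select_peaks(v, min_dist, prom);
    IntegerVector out(p.size());
    for (size_t i = 0; i < p.size(); ++i) out[i] = p[i] + 1;  // 1-based
    return out;
}

// Per-pixel peak/trough pairing over a band-passed matrix (T x npix).
// Detection runs on the min-max normalized series; reported intensities are
// band-passed values with the pixel's temporal mean restored (dc).
// [[Rcpp::export(name = ".pulse_stack_cpp")]]
List pulse_stack_cpp(NumericMatrix bp, NumericVector dc, int min_dist,
                     double prom, int npulse) {
    const int T = bp.nrow(), npx = bp.ncol();
    NumericMatrix imax(npulse, npx), imin(npulse, npx);
    IntegerVector npairs(npx);
    std::vector<double> v(T), neg(T);
    for (int j = 0; j < npx; ++j) {
        double lo = bp(0, j), hi = bp(0, j);
        for (int i = 0; i < T; ++i) {
            const double z = bp(i, j);
            if (z < lo) lo = z;
            if (z > hi) hi = z;
        }
        if (!(hi > lo)) { npairs[j] = 0; continue; }
        const double scale = 1.0 / (hi - lo);
        for (int i = 0; i < T; ++i) {
            v[i] = (bp(i, j) - lo) * scale;
            neg[i] = 1.0 - v[i];
        }
        std::vector<int> pk = select_peaks(v, min_dist, prom);
        std::vector<int> tr = select_peaks(neg, min_dist, prom);
        int ti = 0, filled = 0, total = 0;
        for (size_t k = 0; k < pk.size(); ++k) {
            while (ti < (int)tr.size() && tr[ti] <= pk[k]) ++ti;
            if (ti >= (int)tr.size()) break;  // trailing unmatched peak
            const double pv = bp(pk[k], j) + dc[j];
            const double tv = bp(tr[ti], j) + dc[j];
            ++ti;
            // a valid cardiac pair has Imax >= Imin >= 0; noise-driven
            // inversions are not pulse events
            if (!(pv >= tv && tv >= 0)) continue;
            ++total;
            if (filled < npulse) {
                imax(filled, j) = pv;
                imin(filled, j) = tv;
                ++filled;
            }
        }
        npairs[j] = total;
    }
    return List::create(_["imax"] = imax, _["imin"] = imin,
                        _["npairs"] = npairs);
}
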