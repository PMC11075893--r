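#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Hartigan & Hartigan dip statistic: the minimum over unimodal distribution
// functions G of sup |F_n - G|, by the iterative modal-interval algorithm on
// the sorted sample. Working in colony... observation counts: the greatest
// convex minorant (GCM) is fitted to the lower corners of the empirical cdf
// and the least concave majorant (LCM) to the upper corners, each restricted
// to the current modal interval [low, high]. The largest separation between
// the two fitted curves dictates where the modal interval shrinks; the
// deviations of the empirical cdf from the GCM below the modal interval and
// from the LCM above it accumulate into the dip. The final dip is half the
// largest required separation, scaled by n. Correctness is asserted in the
// test suite against an independent exhaustive band-feasibility oracle.
//
// x: sorted, 1-indexed internally (x[1..n]).
static double dip_core(const std::vector<double>& xs) {
    const int n = (int)xs.size();
    if (n < 2) return 0.0;
    // 1-indexed copy
    std::vector<double> x(n + 1);
    for (int i = 1; i <= n; ++i) x[i] = xs[i - 1];
    if (x[n] == x[1] || n < 4) return 0.5 / n;

    std::vector<int> mn(n + 1), mj(n + 1), gcm(n + 2), lcm(n + 2);

    // mn[j]: previous GCM touch point for the prefix ending at j
    // (lower convex hull of the points (x_i, i), slopes as counts per x)
    mn[1] = 1;
    for (int j = 2; j <= n; ++j) {
        mn[j] = j - 1;
        for (;;) {
            int mnj = mn[j], mnmnj = mn[mnj];
            if (mnj == 1 ||
                (x[j] - x[mnj]) * (mnj - mnmnj) <
                (x[mnj] - x[mnmnj]) * (j - mnj)) break;
            mn[j] = mnmnj;
        }
    }
    // mj[k]: next LCM touch point for the suffix starting at k
    mj[n] = n;
    for (int k = n - 1; k >= 1; --k) {
        mj[k] = k + 1;
        for (;;) {
            int mjk = mj[k], mjmjk = mj[mjk];
            if (mjk == n ||
                (x[k] - x[mjk]) * (mjk - mjmjk) <
                (x[mjk] - x[mjmjk]) * (k - mjk)) break;
            mj[k] = mjmjk;
        }
    }

    int low = 1, high = n;
    double dip = 1.0;  // in counts; 1 count <=> the 1/(2n) floor

    for (;;) {
        // GCM touch points on [low, high], stored high -> low
        int l_gcm = 1;
        gcm[1] = high;
        while (gcm[l_gcm] > low) { gcm[l_gcm + 1] = mn[gcm[l_gcm]]; ++l_gcm; }
        // LCM touch points, stored low -> high
        int l_lcm = 1;
        lcm[1] = low;
        while (lcm[l_lcm] < high) { lcm[l_lcm + 1] = mj[lcm[l_lcm]]; ++l_lcm; }

        double d;
        int ig = l_gcm, ih = l_lcm;
        if (l_gcm != 2 || l_lcm != 2) {
            // largest separation of the LCM curve (upper corners) above the
            // GCM curve (lower corners), scanned low -> high over the union
            // of touch points
            int ix = l_gcm - 1, iv = 2;
            d = 0.0;
            do {
                int gcmix = gcm[ix], lcmiv = lcm[iv];
                double dx;
                if (gcmix > lcmiv) {
                    // next event: LCM touch point inside GCM segment
                    int gcmi1 = gcm[ix + 1];
                    dx = (lcmiv - gcmi1 + 1) -
                         (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) /
                             (x[gcmix] - x[gcmi1]);
                    ++iv;
                    if (dx >= d) { d = dx; ig = ix + 1; ih = iv - 1; }
                } else {
                    // next event: GCM touch point inside LCM segment
                    int lcmiv1 = lcm[iv - 1];
                    dx = (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
                             (x[lcmiv] - x[lcmiv1]) -
                         (gcmix - 1 - lcmiv1);
                    --ix;
                    if (dx >= d) { d = dx; ig = ix + 1; ih = iv; }
                }
                if (ix < 1) ix = 1;
                if (iv > l_lcm) iv = l_lcm;
            } while (gcm[ix] != lcm[iv]);
        } else {
            d = 1.0;  // modal interval is a single chord
        }

        if (d < dip) break;

        // deviation of the empirical cdf above the GCM between the old and
        // new lower ends of the modal interval
        double dip_l = 0.0;
        for (int j = ig; j < l_gcm; ++j) {
            double max_t = 1.0;
            int jb = gcm[j + 1], je = gcm[j];
            if (je - jb > 1 && x[je] != x[jb]) {
                double C = (je - jb) / (x[je] - x[jb]);
                for (int jj = jb; jj <= je; ++jj) {
                    double t = (jj - jb + 1) - (x[jj] - x[jb]) * C;
                    if (max_t < t) max_t = t;
                }
            }
            if (dip_l < max_t) dip_l = max_t;
        }
        // deviation of the empirical cdf below the LCM between the new and
        // old upper ends
        double dip_u = 0.0;
        for (int j = ih; j < l_lcm; ++j) {
            double max_t = 1.0;
            int jb = lcm[j], je = lcm[j + 1];
            if (je - jb > 1 && x[je] != x[jb]) {
                double C = (je - jb) / (x[je] - x[jb]);
                for (int jj = jb; jj <= je; ++jj) {
                    double t = (x[jj] - x[jb]) * C - (jj - jb - 1);
                    if (max_t < t) max_t = t;
                }
            }
            if (dip_u < max_t) dip_u = max_t;
        }

        double dip_new = (dip_u > dip_l) ? dip_u : dip_l;
        if (dip < dip_new) dip = dip_new;

        if (low == gcm[ig] && high == lcm[ih]) break;  // no progress: done
        low = gcm[ig];
        high = lcm[ih];
    }
    return dip / (2.0 * n);
}

// [[Rcpp::export(name = ".dip_cpp")]]
double dip_cpp(NumericVector x) {
    const int n = x.size();
    if (n < 2) stop("dip statistic requires at least 2 observations");
    std::vector<double> xs(x.begin(), x.end());
    for (int i = 0; i < n; ++i)
        if (!R_finite(xs[i])) stop("dip statistic requires finite values");
    std::sort(xs.begin(), xs.end());
    return dip_core(xs);
}

// Monte-Carlo null dips: n_null samples of size n from Uniform(0,1),
// drawn from R's RNG stream so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".dip_null_cpp")]]
NumericVector dip_null_cpp(int n, int n_null) {
    NumericVector out(n_null);
    std::vector<double> u(n);
    for (int r = 0; r < n_null; ++r) {
        for (int i = 0; i < n; ++i) u[i] = unif_rand();
        std::sort(u.begin(), u.end());
        out[r] = dip_core(u);
    }
    return out;
}
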