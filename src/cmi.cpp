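#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Plug-in conditional mutual information I(X;Y|Z) in bits from a flat count
// vector indexed cnt[z*nx*2 + x*2 + y].  Zero-probability cells contribute 0
// (no smoothing); tiny negative rounding is clamped to zero.
static double cmi_from_counts(const std::vector<int>& cnt, int nz, int nx, double n) {
    std::vector<double> m_zx((size_t)nz * nx, 0.0);
    std::vector<double> m_zy((size_t)nz * 2, 0.0);
    std::vector<double> m_z(nz, 0.0);
    for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x)
            for (int y = 0; y < 2; ++y) {
                double c = cnt[(size_t)z * nx * 2 + x * 2 + y];
                m_zx[(size_t)z * nx + x] += c;
                m_zy[(size_t)z * 2 + y] += c;
                m_z[z] += c;
            }
    double v = 0.0;
    for (int z = 0; z < nz; ++z) {
        if (m_z[z] <= 0) continue;
        for (int x = 0; x < nx; ++x) {
            double mzx = m_zx[(size_t)z * nx + x];
            if (mzx <= 0) continue;
            for (int y = 0; y < 2; ++y) {
                double c = cnt[(size_t)z * nx * 2 + x * 2 + y];
                if (c <= 0) continue;
                double mzy = m_zy[(size_t)z * 2 + y];
                // p(z,x,y) * log2( p(z,x,y) p(z) / (p(z,x) p(z,y)) ); n cancels
                v += (c / n) * std::log2(c * m_z[z] / (mzx * mzy));
            }
        }
    }
    return v < 0.0 ? 0.0 : v;
}

static void tabulate3(const IntegerVector& x, const IntegerVector& y,
                      const IntegerVector& z, int nx, std::vector<int>& cnt) {
    std::fill(cnt.begin(), cnt.end(), 0);
    R_xlen_t n = x.size();
    for (R_xlen_t i = 0; i < n; ++i)
        ++cnt[(size_t)z[i] * nx * 2 + x[i] * 2 + y[i]];
}

// [[Rcpp::export]]
double cmi_labels_cpp(IntegerVector x, IntegerVector y, IntegerVector z,
                      int nx, int nz) {
    if (x.size() != y.size() || x.size() != z.size())
        stop("label vectors differ in length");
    std::vector<int> cnt((size_t)nz * nx * 2, 0);
    tabulate3(x, y, z, nx, cnt);
    return cmi_from_counts(cnt, nz, nx, (double)x.size());
}

// xorshift64* PRNG, seeded from R's RNG once per call so results remain
// reproducible via set.seed() while avoiding the per-draw overhead of
// unif_rand() inside the shuffle loop.
static inline uint64_t xorshift64star(uint64_t& s) {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 2685821657736338717ULL;
}

// Permutation test: shuffle the expression bin labels across genes (keeping
// membership y and degree bins z fixed), recompute the CMI each time, and
// count how often the permuted CMI strictly exceeds the observed one.
// [[Rcpp::export]]
int perm_exceed_cpp(IntegerVector x, IntegerVector y, IntegerVector z,
                    int nx, int nz, int n_perm) {
    R_xlen_t n = x.size();
    if (y.size() != n || z.size() != n) stop("label vectors differ in length");
    if (n_perm < 1) stop("n_perm must be >= 1");
    std::vector<int> cnt((size_t)nz * nx * 2, 0);
    tabulate3(x, y, z, nx, cnt);
    double observed = cmi_from_counts(cnt, nz, nx, (double)n);

    uint64_t state = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
                     (uint64_t)(unif_rand() * 4294967296.0) ^ 0x9E3779B97F4A7C15ULL;
    if (state == 0) state = 0x9E3779B97F4A7C15ULL;

    std::vector<int> xs(n);
    for (R_xlen_t i = 0; i < n; ++i) xs[i] = x[i];
    int exceed = 0;
    for (int b = 0; b < n_perm; ++b) {
        // Fisher-Yates reshuffle of the current arrangement
        for (R_xlen_t i = n - 1; i > 0; --i) {
            R_xlen_t j = (R_xlen_t)(xorshift64star(state) % (uint64_t)(i + 1));
            std::swap(xs[i], xs[j]);
        }
        std::fill(cnt.begin(), cnt.end(), 0);
        for (R_xlen_t i = 0; i < n; ++i)
            ++cnt[(size_t)z[i] * nx * 2 + xs[i] * 2 + y[i]];
        if (cmi_from_counts(cnt, nz, nx, (double)n) > observed) ++exceed;
    }
    return exceed;
}
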