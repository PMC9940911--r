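#ifndef RLDDM_H
#define RLDDM_H

#include <cmath>
#include <algorithm>
#include <limits>
#include <random>

// Truncation error for the WFPT series (both expansions).
static const double WFPT_ERR = 1e-7;

// Density (not log) of the scaled first-passage time w = u / a^2 at the
// lower boundary for a unit-drift-free process started at relative z.
// Small-time and large-time series with the accuracy-based switch.
inline double wfpt_f0(double w, double z) {
    if (!(w > 0.0)) return 0.0;
    // number of terms needed for each expansion
    double ks, kl;
    if (2.0 * std::sqrt(2.0 * M_PI * w) * WFPT_ERR < 1.0) {
        ks = 2.0 + std::sqrt(-2.0 * w * std::log(2.0 * std::sqrt(2.0 * M_PI * w) * WFPT_ERR));
        ks = std::max(ks, std::sqrt(w) + 1.0);
    } else {
        ks = 2.0;
    }
    if (M_PI * w * WFPT_ERR < 1.0) {
        kl = std::sqrt(-2.0 * std::log(M_PI * w * WFPT_ERR) / (M_PI * M_PI * w));
        kl = std::max(kl, 1.0 / (M_PI * std::sqrt(w)));
    } else {
        kl = 1.0 / (M_PI * std::sqrt(w));
    }
    double f = 0.0;
    if (ks < kl) {  // small-time expansion
        int K = static_cast<int>(std::ceil(ks));
        for (int k = -((K - 1) / 2); k <= ((K - 1) / 2) + (1 - K % 2); ++k) {
            double zz = z + 2.0 * k;
            f += zz * std::exp(-zz * zz / (2.0 * w));
        }
        f /= std::sqrt(2.0 * M_PI * w * w * w);
    } else {        // large-time expansion
        int K = static_cast<int>(std::ceil(kl));
        for (int k = 1; k <= K; ++k) {
            f += k * std::exp(-k * k * M_PI * M_PI * w / 2.0) * std::sin(k * M_PI * z);
        }
        f *= M_PI;
    }
    return f;
}

// Log-density of the first-passage time dt (in seconds, including the
// non-decision time t) at one boundary of a diffusion with drift v,
// separation a, relative start z (distance z*a from the lower boundary)
// and diffusion coefficient 1.  upper = true evaluates the density of
// terminating at the upper boundary.
inline double wfpt_logpdf_scalar(double dt, bool upper, double v, double a,
                                 double z, double t) {
    if (!(a > 0.0) || !(z > 0.0) || !(z < 1.0) || !std::isfinite(v) || !(t >= 0.0))
        return std::numeric_limits<double>::quiet_NaN();
    double u = dt - t;
    if (!(u > 0.0)) return -std::numeric_limits<double>::infinity();
    // upper boundary = lower boundary of the sign-flipped process
    double vv = upper ? -v : v;
    double zz = upper ? 1.0 - z : z;
    double f0 = wfpt_f0(u / (a * a), zz);
    if (f0 < 1e-290) f0 = 1e-290;  // far-tail underflow guard
    return -2.0 * std::log(a) - vv * a * zz - vv * vv * u / 2.0 + std::log(f0);
}

// Analytic probability of absorption at the upper boundary.
inline double choice_prob_upper(double v, double a, double z) {
    double x = -2.0 * v * a;
    if (std::fabs(x) < 1e-10) return z;
    return std::expm1(x * z) / std::expm1(x);
}

// Delta-rule update with separate rates for positive/negative prediction
// errors; outcome R in {0,1}.
inline double q_update(double q, double r, double a_pos, double a_neg) {
    double pe = r - q;
    return q + (pe > 0.0 ? a_pos : a_neg) * pe;
}

inline double squash(double raw) { return 1.0 / (1.0 + std::exp(-raw)); }

// Euler-Maruyama first-passage simulation with an optional
// continuity correction (boundaries shifted inward by 0.5826*sqrt(step))
// that removes the O(sqrt(step)) discretisation bias.
// Returns decision time (without non-decision time); hit_upper set by ref.
// Returns a negative value when the 'cap' is exceeded (censored).
template <class RNG>
inline double fpt_euler(double v, double a, double z, double step, double cap,
                        bool correct, RNG& rng, std::normal_distribution<double>& norm,
                        bool& hit_upper) {
    double delta = correct ? 0.5826 * std::sqrt(step) : 0.0;
    double lo = delta, hi = a - delta;
    double x = z * a;
    if (!(lo < hi) || x <= lo || x >= hi) { lo = 0.0; hi = a; }  // step too coarse
    double sq = std::sqrt(step);
    long nmax = static_cast<long>(cap / step) + 1;
    for (long i = 1; i <= nmax; ++i) {
        x += v * step + sq * norm(rng);
        if (x >= hi) { hit_upper = true; return i * step; }
        if (x <= lo) { hit_upper = false; return i * step; }
    }
    hit_upper = x >= a / 2.0;
    return -1.0;  // censored
}

#endif
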