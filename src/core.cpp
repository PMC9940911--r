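#include <Rcpp.h>
#include "rlddm.h"
using namespace Rcpp;

// [[Rcpp::export(name = ".wfpt_logpdf_cpp")]]
NumericVector wfpt_logpdf_cpp(NumericVector dt, LogicalVector upper, double v,
                              double a, double z, double t) {
    int n = dt.size();
    if (upper.size() != n) stop("dt and upper must have equal length");
    NumericVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = wfpt_logpdf_scalar(dt[i], upper[i], v, a, z, t);
    return out;
}

// [[Rcpp::export(name = ".choice_prob_cpp")]]
double choice_prob_cpp(double v, double a, double z) {
    return choice_prob_upper(v, a, z);
}

// [[Rcpp::export(name = ".simulate_ddm_cpp")]]
List simulate_ddm_cpp(int n, double v, double a, double z, double t,
                      double step, double cap, bool correct, int seed) {
    std::mt19937_64 rng(static_cast<uint64_t>(seed));
    std::normal_distribution<double> norm(0.0, 1.0);
    NumericVector dt(n);
    LogicalVector up(n), censored(n);
    for (int i = 0; i < n; ++i) {
        bool hu = false;
        double fpt = fpt_euler(v, a, z, step, cap, correct, rng, norm, hu);
        if (fpt < 0.0) {
            censored[i] = true;
            dt[i] = NA_REAL;
        } else {
            dt[i] = fpt + t;
        }
        up[i] = hu;
    }
    return List::create(_["dt"] = dt, _["upper"] = up, _["censored"] = censored);
}

// Closed generative loop for one subject x condition: drift from the
// current Q difference -> simulated choice/DT -> outcome drawn from the
// schedule -> Q update.  Omissions (independent Bernoulli, or DT beyond
// the response window) carry no outcome and trigger no update.
// p_reward: n_trials x 2 matrix (prob of reward for options A and B).
// [[Rcpp::export(name = ".generate_dataset_cpp")]]
List generate_dataset_cpp(NumericMatrix p_reward, double a, double m,
                          double ap_raw, double an_raw, double t, double z,
                          double omission_rate, double response_window,
                          double q0a, double q0b,
                          double step, double cap, int seed) {
    int n = p_reward.nrow();
    std::mt19937_64 rng(static_cast<uint64_t>(seed));
    std::normal_distribution<double> norm(0.0, 1.0);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    double ap = squash(ap_raw), an = squash(an_raw);
    IntegerVector choice(n);      // 1 = A (upper), 0 = B, NA = omitted
    IntegerVector outcome(n);
    NumericVector dt(n), qa(n), qb(n);
    LogicalVector omitted(n);
    double QA = q0a, QB = q0b;
    for (int i = 0; i < n; ++i) {
        qa[i] = QA; qb[i] = QB;
        bool omit = unif(rng) < omission_rate;
        double v = m * (QA - QB);
        bool hu = false;
        double fpt = omit ? -1.0 : fpt_euler(v, a, z, step, cap, true, rng, norm, hu);
        double dtot = fpt + t;
        if (omit || fpt < 0.0 || dtot > response_window) {
            omitted[i] = true;
            choice[i] = NA_INTEGER; outcome[i] = NA_INTEGER; dt[i] = NA_REAL;
            continue;
        }
        int ch = hu ? 1 : 0;
        double p = hu ? p_reward(i, 0) : p_reward(i, 1);
        int r = unif(rng) < p ? 1 : 0;
        choice[i] = ch; outcome[i] = r; dt[i] = dtot;
        if (ch == 1) QA = q_update(QA, r, ap, an); else QB = q_update(QB, r, ap, an);
    }
    return List::create(_["choice"] = choice, _["outcome"] = outcome,
                        _["dt"] = dt, _["omitted"] = omitted,
                        _["q_a"] = qa, _["q_b"] = qb);
}

// Joint log-likelihood of one subject x condition dataset (responded
// trials only) under the RLDDM: Q trajectory from the delta rule, drift
// v_t = m * (Q_A - Q_B) using pre-update values, WFPT density at the
// boundary matching the choice (upper = A).
// [[Rcpp::export(name = ".loglik_dataset_cpp")]]
double loglik_dataset_cpp(IntegerVector choice, IntegerVector outcome,
                          NumericVector dt, double a, double m,
                          double ap_raw, double an_raw, double t, double z,
                          double q0a, double q0b) {
    int n = choice.size();
    double ap = squash(ap_raw), an = squash(an_raw);
    double QA = q0a, QB = q0b, ll = 0.0;
    for (int i = 0; i < n; ++i) {
        double v = m * (QA - QB);
        bool up = choice[i] == 1;
        double lp = wfpt_logpdf_scalar(dt[i], up, v, a, z, t);
        if (!std::isfinite(lp)) return -std::numeric_limits<double>::infinity();
        ll += lp;
        double r = static_cast<double>(outcome[i]);
        if (up) QA = q_update(QA, r, ap, an); else QB = q_update(QB, r, ap, an);
    }
    return ll;
}
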