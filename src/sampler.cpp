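#include <Rcpp.h>
#include "rlddm.h"
using namespace Rcpp;

// Hierarchical RLDDM sampler: adaptive Metropolis-within-Gibbs.
//
// Structure: one "dataset" = one subject x condition block of responded
// trials.  Condition-dependent subject parameters (a, m, alpha+ raw,
// alpha- raw) are normal around condition-specific group means; the
// non-decision time t and the start point (logit scale) are shared across
// conditions within a subject, normal around a single group mean.  Group
// means get conjugate Gibbs updates; group sds have half-normal priors and
// are updated by random-walk Metropolis on the log scale.  Subject-level
// parameters are updated by random-walk Metropolis with proposal scales
// adapted during burn-in (target acceptance 0.44).

struct Data {
    std::vector<std::vector<int> > choice, outcome;
    std::vector<std::vector<double> > dt;
    std::vector<int> subj, cond;   // 0-based
    int D, S, C;
    double q0a, q0b;
};

static double loglik_d(const Data& dat, int d, double a, double m,
                       double ap_raw, double an_raw, double t, double zr) {
    double z = squash(zr);
    double ap = squash(ap_raw), an = squash(an_raw);
    double QA = dat.q0a, QB = dat.q0b, ll = 0.0;
    const std::vector<int>& ch = dat.choice[d];
    const std::vector<int>& oc = dat.outcome[d];
    const std::vector<double>& rt = dat.dt[d];
    for (size_t i = 0; i < ch.size(); ++i) {
        double v = m * (QA - QB);
        bool up = ch[i] == 1;
        double lp = wfpt_logpdf_scalar(rt[i], up, v, a, z, t);
        if (!std::isfinite(lp)) return -std::numeric_limits<double>::infinity();
        ll += lp;
        double r = static_cast<double>(oc[i]);
        if (up) QA = q_update(QA, r, ap, an); else QB = q_update(QB, r, ap, an);
    }
    return ll;
}

static inline double dnorm_log(double x, double mu, double sd) {
    double zz = (x - mu) / sd;
    return -0.5 * zz * zz - std::log(sd) - 0.5 * std::log(2.0 * M_PI);
}

// [[Rcpp::export(name = ".rlddm_mcmc_cpp")]]
List rlddm_mcmc_cpp(List choice, List outcome, List dt,
                    IntegerVector subj, IntegerVector cond,
                    int n_subjects, int n_conds, bool single_rate,
                    double q0a, double q0b, List priors,
                    int chains, int burn, int draws, int seed) {
    Data dat;
    dat.D = choice.size(); dat.S = n_subjects; dat.C = n_conds;
    dat.q0a = q0a; dat.q0b = q0b;
    for (int d = 0; d < dat.D; ++d) {
        dat.choice.push_back(as<std::vector<int> >(choice[d]));
        dat.outcome.push_back(as<std::vector<int> >(outcome[d]));
        dat.dt.push_back(as<std::vector<double> >(dt[d]));
        dat.subj.push_back(subj[d]);
        dat.cond.push_back(cond[d]);
    }
    const int D = dat.D, S = dat.S, C = dat.C;
    // per-subject smallest observed dt: upper bound on t
    std::vector<double> min_dt(S, 1e9);
    for (int d = 0; d < D; ++d)
        for (size_t i = 0; i < dat.dt[d].size(); ++i)
            min_dt[dat.subj[d]] = std::min(min_dt[dat.subj[d]], dat.dt[d][i]);

    // prior hyperparameters, order: a, m, ap, an, t, zr
    NumericVector mu0 = priors["mu0"], sd0 = priors["sd0"], sscale = priors["sigma_scale"];

    const int NP = 4;                    // condition-dependent params per dataset
    const int T = chains * draws;
    NumericVector theta_dr(static_cast<R_xlen_t>(T) * D * NP);
    NumericVector shared_dr(static_cast<R_xlen_t>(T) * S * 2);
    NumericVector mu_dr(static_cast<R_xlen_t>(T) * NP * C);
    NumericVector sig_dr(static_cast<R_xlen_t>(T) * NP * C);
    NumericVector sg_dr(static_cast<R_xlen_t>(T) * 4);   // mu_t, sig_t, mu_z, sig_z
    NumericVector dev_dr(T);
    IntegerVector chain_id(T);

    int keep = 0;
    for (int ch = 0; ch < chains; ++ch) {
        std::mt19937_64 rng(static_cast<uint64_t>(seed) + 100003u * (ch + 1));
        std::normal_distribution<double> norm(0.0, 1.0);
        std::uniform_real_distribution<double> unif(0.0, 1.0);

        // --- initial values (chain-jittered) ---
        std::vector<std::vector<double> > theta(D, std::vector<double>(NP));
        std::vector<double> t_s(S), zr_s(S);
        for (int d = 0; d < D; ++d) {
            theta[d][0] = std::max(0.3, 1.5 + 0.2 * norm(rng));   // a
            theta[d][1] = 2.0 + 0.5 * norm(rng);                  // m
            theta[d][2] = 0.0 + 0.4 * norm(rng);                  // alpha+ raw
            theta[d][3] = single_rate ? theta[d][2] : -1.0 + 0.4 * norm(rng);
        }
        for (int s = 0; s < S; ++s) {
            t_s[s] = std::min(0.5 * min_dt[s], 0.4 + 0.05 * norm(rng));
            if (t_s[s] <= 0.0 || t_s[s] >= min_dt[s]) t_s[s] = 0.5 * min_dt[s];
            zr_s[s] = 0.2 * norm(rng);
        }
        std::vector<std::vector<double> > mu(NP, std::vector<double>(C)),
                                          sig(NP, std::vector<double>(C, 0.5));
        for (int p = 0; p < NP; ++p)
            for (int c = 0; c < C; ++c) {
                double mn = 0.0; int n = 0;
                for (int d = 0; d < D; ++d) if (dat.cond[d] == c) { mn += theta[d][p]; ++n; }
                mu[p][c] = n ? mn / n : mu0[p];
            }
        double mu_t = 0.0, mu_z = 0.0, sig_t = 0.2, sig_z = 0.5;
        for (int s = 0; s < S; ++s) { mu_t += t_s[s] / S; mu_z += zr_s[s] / S; }

        std::vector<double> ll(D);
        for (int d = 0; d < D; ++d)
            ll[d] = loglik_d(dat, d, theta[d][0], theta[d][1], theta[d][2],
                             theta[d][3], t_s[dat.subj[d]], zr_s[dat.subj[d]]);

        // proposal log-sds and acceptance counters
        std::vector<std::vector<double> > lsd(D, std::vector<double>(NP, std::log(0.15)));
        std::vector<std::vector<int> > acc(D, std::vector<int>(NP, 0));
        std::vector<double> lsd_t(S, std::log(0.03)), lsd_z(S, std::log(0.15));
        std::vector<int> acc_t(S, 0), acc_z(S, 0);
        std::vector<std::vector<double> > lsd_sig(NP, std::vector<double>(C, std::log(0.3)));
        std::vector<std::vector<int> > acc_sig(NP, std::vector<int>(C, 0));
        double lsd_sig_t = std::log(0.3), lsd_sig_z = std::log(0.3);
        int acc_sig_t = 0, acc_sig_z = 0;
        const int ADAPT = 50;
        int batch = 0;

        int total = burn + draws;
        for (int it = 0; it < total; ++it) {
            // ---- subject x condition parameters ----
            for (int d = 0; d < D; ++d) {
                int s = dat.subj[d], c = dat.cond[d];
                int npar = single_rate ? 3 : 4;
                for (int p = 0; p < npar; ++p) {
                    double cur = theta[d][p];
                    double prop = cur + std::exp(lsd[d][p]) * norm(rng);
                    if (p == 0 && prop <= 1e-3) continue;   // a > 0
                    double an_cur = theta[d][3], an_prop = an_cur;
                    if (single_rate && p == 2) an_prop = prop;
                    double llp = loglik_d(dat, d,
                                          p == 0 ? prop : theta[d][0],
                                          p == 1 ? prop : theta[d][1],
                                          p == 2 ? prop : theta[d][2],
                                          p == 3 ? prop : an_prop,
                                          t_s[s], zr_s[s]);
                    double lr = llp - ll[d]
                        + dnorm_log(prop, mu[p][c], sig[p][c])
                        - dnorm_log(cur, mu[p][c], sig[p][c]);
                    if (std::log(unif(rng)) < lr) {
                        theta[d][p] = prop;
                        if (single_rate && p == 2) theta[d][3] = prop;
                        ll[d] = llp;
                        ++acc[d][p];
                    }
                }
            }
            // ---- shared subject parameters (t, z) ----
            for (int s = 0; s < S; ++s) {
                // t
                double prop = t_s[s] + std::exp(lsd_t[s]) * norm(rng);
                if (prop > 0.0 && prop < min_dt[s]) {
                    double dll = 0.0; std::vector<std::pair<int,double> > nl;
                    bool ok = true;
                    for (int d = 0; d < D && ok; ++d) if (dat.subj[d] == s) {
                        double llp = loglik_d(dat, d, theta[d][0], theta[d][1],
                                              theta[d][2], theta[d][3], prop, zr_s[s]);
                        if (!std::isfinite(llp)) ok = false;
                        nl.push_back(std::make_pair(d, llp));
                        dll += llp - ll[d];
                    }
                    if (ok) {
                        double lr = dll + dnorm_log(prop, mu_t, sig_t)
                                        - dnorm_log(t_s[s], mu_t, sig_t);
                        if (std::log(unif(rng)) < lr) {
                            t_s[s] = prop;
                            for (size_t k = 0; k < nl.size(); ++k) ll[nl[k].first] = nl[k].second;
                            ++acc_t[s];
                        }
                    }
                }
                // z (logit scale)
                prop = zr_s[s] + std::exp(lsd_z[s]) * norm(rng);
                {
                    double dll = 0.0; std::vector<std::pair<int,double> > nl;
                    bool ok = true;
                    for (int d = 0; d < D && ok; ++d) if (dat.subj[d] == s) {
                        double llp = loglik_d(dat, d, theta[d][0], theta[d][1],
                                              theta[d][2], theta[d][3], t_s[s], prop);
                        if (!std::isfinite(llp)) ok = false;
                        nl.push_back(std::make_pair(d, llp));
                        dll += llp - ll[d];
                    }
                    if (ok) {
                        double lr = dll + dnorm_log(prop, mu_z, sig_z)
                                        - dnorm_log(zr_s[s], mu_z, sig_z);
                        if (std::log(unif(rng)) < lr) {
                            zr_s[s] = prop;
                            for (size_t k = 0; k < nl.size(); ++k) ll[nl[k].first] = nl[k].second;
                            ++acc_z[s];
                        }
                    }
                }
            }
            // ---- group means: conjugate Gibbs ----
            int npar = single_rate ? 3 : 4;
            for (int p = 0; p < npar; ++p)
                for (int c = 0; c < C; ++c) {
                    double sx = 0.0; int n = 0;
                    for (int d = 0; d < D; ++d) if (dat.cond[d] == c) { sx += theta[d][p]; ++n; }
                    double prec = n / (sig[p][c] * sig[p][c]) + 1.0 / (sd0[p] * sd0[p]);
                    double mean = (sx / (sig[p][c] * sig[p][c]) + mu0[p] / (sd0[p] * sd0[p])) / prec;
                    mu[p][c] = mean + norm(rng) / std::sqrt(prec);
                }
            if (single_rate) for (int c = 0; c < C; ++c) { mu[3][c] = mu[2][c]; sig[3][c] = sig[2][c]; }
            {   // t and z group means
                double sx = 0.0;
                for (int s = 0; s < S; ++s) sx += t_s[s];
                double prec = S / (sig_t * sig_t) + 1.0 / (sd0[4] * sd0[4]);
                mu_t = (sx / (sig_t * sig_t) + mu0[4] / (sd0[4] * sd0[4])) / prec
                       + norm(rng) / std::sqrt(prec);
                sx = 0.0;
                for (int s = 0; s < S; ++s) sx += zr_s[s];
                prec = S / (sig_z * sig_z) + 1.0 / (sd0[5] * sd0[5]);
                mu_z = (sx / (sig_z * sig_z) + mu0[5] / (sd0[5] * sd0[5])) / prec
                       + norm(rng) / std::sqrt(prec);
            }
            // ---- group sds: MH on log scale, half-normal prior ----
            for (int p = 0; p < npar; ++p)
                for (int c = 0; c < C; ++c) {
                    double cur = sig[p][c];
                    double prop = cur * std::exp(std::exp(lsd_sig[p][c]) * norm(rng));
                    double lr = 0.0;
                    for (int d = 0; d < D; ++d) if (dat.cond[d] == c)
                        lr += dnorm_log(theta[d][p], mu[p][c], prop)
                            - dnorm_log(theta[d][p], mu[p][c], cur);
                    lr += dnorm_log(prop, 0.0, sscale[p]) - dnorm_log(cur, 0.0, sscale[p]);
                    lr += std::log(prop) - std::log(cur);   // Jacobian
                    if (std::log(unif(rng)) < lr) { sig[p][c] = prop; ++acc_sig[p][c]; }
                }
            if (single_rate) for (int c = 0; c < C; ++c) sig[3][c] = sig[2][c];
            {   // sig_t
                double cur = sig_t;
                double prop = cur * std::exp(std::exp(lsd_sig_t) * norm(rng));
                double lr = 0.0;
                for (int s = 0; s < S; ++s)
                    lr += dnorm_log(t_s[s], mu_t, prop) - dnorm_log(t_s[s], mu_t, cur);
                lr += dnorm_log(prop, 0.0, sscale[4]) - dnorm_log(cur, 0.0, sscale[4]);
                lr += std::log(prop) - std::log(cur);
                if (std::log(unif(rng)) < lr) { sig_t = prop; ++acc_sig_t; }
                // sig_z
                cur = sig_z;
                prop = cur * std::exp(std::exp(lsd_sig_z) * norm(rng));
                lr = 0.0;
                for (int s = 0; s < S; ++s)
                    lr += dnorm_log(zr_s[s], mu_z, prop) - dnorm_log(zr_s[s], mu_z, cur);
                lr += dnorm_log(prop, 0.0, sscale[5]) - dnorm_log(cur, 0.0, sscale[5]);
                lr += std::log(prop) - std::log(cur);
                if (std::log(unif(rng)) < lr) { sig_z = prop; ++acc_sig_z; }
            }
            // ---- proposal adaptation during burn-in ----
            if (it < burn && (it + 1) % ADAPT == 0) {
                ++batch;
                double gain = 1.0 / std::sqrt(static_cast<double>(batch));
                for (int d = 0; d < D; ++d)
                    for (int p = 0; p < NP; ++p) {
                        lsd[d][p] += gain * (acc[d][p] / (double)ADAPT - 0.44);
                        acc[d][p] = 0;
                    }
                for (int s = 0; s < S; ++s) {
                    lsd_t[s] += gain * (acc_t[s] / (double)ADAPT - 0.44); acc_t[s] = 0;
                    lsd_z[s] += gain * (acc_z[s] / (double)ADAPT - 0.44); acc_z[s] = 0;
                }
                for (int p = 0; p < NP; ++p)
                    for (int c = 0; c < C; ++c) {
                        lsd_sig[p][c] += gain * (acc_sig[p][c] / (double)ADAPT - 0.44);
                        acc_sig[p][c] = 0;
                    }
                lsd_sig_t += gain * (acc_sig_t / (double)ADAPT - 0.44); acc_sig_t = 0;
                lsd_sig_z += gain * (acc_sig_z / (double)ADAPT - 0.44); acc_sig_z = 0;
            }
            // ---- store ----
            if (it >= burn) {
                R_xlen_t k = keep;
                for (int d = 0; d < D; ++d)
                    for (int p = 0; p < NP; ++p)
                        theta_dr[k + (R_xlen_t)T * (d + (R_xlen_t)D * p)] = theta[d][p];
                for (int s = 0; s < S; ++s) {
                    shared_dr[k + (R_xlen_t)T * (s + (R_xlen_t)S * 0)] = t_s[s];
                    shared_dr[k + (R_xlen_t)T * (s + (R_xlen_t)S * 1)] = zr_s[s];
                }
                for (int p = 0; p < NP; ++p)
                    for (int c = 0; c < C; ++c) {
                        mu_dr[k + (R_xlen_t)T * (p + (R_xlen_t)NP * c)] = mu[p][c];
                        sig_dr[k + (R_xlen_t)T * (p + (R_xlen_t)NP * c)] = sig[p][c];
                    }
                sg_dr[k + (R_xlen_t)T * 0] = mu_t;
                sg_dr[k + (R_xlen_t)T * 1] = sig_t;
                sg_dr[k + (R_xlen_t)T * 2] = mu_z;
                sg_dr[k + (R_xlen_t)T * 3] = sig_z;
                double dev = 0.0;
                for (int d = 0; d < D; ++d) dev += ll[d];
                dev_dr[keep] = -2.0 * dev;
                chain_id[keep] = ch + 1;
                ++keep;
            }
        }
        Rcpp::checkUserInterrupt();
    }
    theta_dr.attr("dim") = IntegerVector::create(T, D, NP);
    shared_dr.attr("dim") = IntegerVector::create(T, S, 2);
    mu_dr.attr("dim") = IntegerVector::create(T, NP, C);
    sig_dr.attr("dim") = IntegerVector::create(T, NP, C);
    sg_dr.attr("dim") = IntegerVector::create(T, 4);
    return List::create(_["theta"] = theta_dr, _["shared"] = shared_dr,
                        _["mu"] = mu_dr, _["sigma"] = sig_dr,
                        _["shared_group"] = sg_dr, _["deviance"] = dev_dr,
                        _["chain"] = chain_id);
}
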