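# Fixtures and independent oracles shared across test files.

# Naive delta-rule replay, written as a plain loop independent of the
# package's implementation: returns pre-choice Q values per trial.
naive_q_oracle <- function(trials, alpha_pos, alpha_neg, q0 = c(0.5, 0.5)) {
  qa <- q0[1]; qb <- q0[2]
  out <- matrix(NA_real_, nrow(trials), 2)
  for (i in seq_len(nrow(trials))) {
    out[i, ] <- c(qa, qb)
    if (isTRUE(trials$omitted[i])) next
    r <- trials$outcome[i]
    if (trials$choice[i] == "A") {
      if (r - qa > 0) qa <- qa + alpha_pos * (r - qa) else qa <- qa + alpha_neg * (r - qa)
    } else {
      if (r - qb > 0) qb <- qb + alpha_pos * (r - qb) else qb <- qb + alpha_neg * (r - qb)
    }
  }
  out
}

# Random single-subject trial table (not generated by the package's
# simulator; choices/outcomes/DTs are arbitrary draws).
random_trials <- function(n = 120, omission_rate = 0.05, subject = 1,
                          condition = "X") {
  omitted <- runif(n) < omission_rate
  data.frame(
    subject = subject, condition = condition,
    session = rep(seq_len(3), length.out = n)[order(rep(seq_len(3), length.out = n))],
    trial = seq_len(n),
    choice = ifelse(omitted, NA, sample(c("A", "B"), n, replace = TRUE)),
    outcome = ifelse(omitted, NA, rbinom(n, 1, 0.5)),
    dt_s = ifelse(omitted, NA, runif(n, 0.4, 2.5)),
    omitted = omitted,
    stringsAsFactors = FALSE
  )
}

# Kolmogorov-Smirnov distance between simulated trials and the WFPT
# density, on the signed decision-time axis (lower-boundary times negative).
# The theoretical CDF comes from trapezoid integration of the density.
wfpt_ks <- function(sim, v, a, z, t, tmax = 15) {
  sim <- sim[!sim$censored, ]
  x <- sort(ifelse(sim$boundary == "upper", sim$dt, -sim$dt))
  grid <- seq(t + 1e-4, tmax, length.out = 8000)
  h <- diff(grid[1:2])
  du <- exp(wfpt_logpdf(grid, "upper", v, a, z, t))
  dl <- exp(wfpt_logpdf(grid, "lower", v, a, z, t))
  p_low <- sum(dl) * h
  Fg <- approxfun(c(-rev(grid), grid),
                  c(rev(p_low - cumsum(dl) * h), p_low + cumsum(du) * h),
                  rule = 2)
  max(abs(Fg(x) - (seq_along(x) - 0.5) / length(x)))
}

# Small two-condition cohort for fast fits.
tiny_cohort_data <- function(n_subjects = 6, seed = 42) {
  sch <- make_schedule()
  coh <- sample_cohort(cohort_spec(n_subjects = n_subjects), seed = seed)
  list(schedule = sch, cohort = coh,
       trials = generate_cohort_data(coh, sch, seed = seed + 1))
}
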