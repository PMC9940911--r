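test_that("the WFPT density is symmetric, normalised, and guards impossible times", {
  # symmetry at zero drift and unbiased start
  dts <- seq(0.35, 5, 0.05)
  expect_equal(wfpt_logpdf(dts, "upper", v = 0, a = 1.8, z = 0.5, t = 0.3),
               wfpt_logpdf(dts, "lower", v = 0, a = 1.8, z = 0.5, t = 0.3))

  # quadrature oracle: both boundaries integrate to 1
  f <- function(dt, b) exp(wfpt_logpdf(dt, b, v = 1, a = 2, z = 0.5, t = 0.3))
  total <- integrate(f, 0.3, 80, b = "upper", rel.tol = 1e-9)$value +
    integrate(f, 0.3, 80, b = "lower", rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-4)

  # boundary-relabelling invariance: flip v and z, swap boundaries
  expect_equal(wfpt_logpdf(dts, "upper", v = 1.3, a = 2, z = 0.4, t = 0.3),
               wfpt_logpdf(dts, "lower", v = -1.3, a = 2, z = 0.6, t = 0.3))

  expect_identical(wfpt_logpdf(0.2, "upper", v = 1, a = 2, z = 0.5, t = 0.3), -Inf)
  expect_error(wfpt_logpdf(1, "upper", v = 1, a = -1, z = 0.5, t = 0.3), "positive")
})

test_that("the analytic choice probability matches its closed form and limits", {
  expect_equal(choice_probability(0, 2, 0.5), 0.5)
  expect_equal(choice_probability(2, 1.78, 0.5), 1 / (1 + exp(-1.78 * 2)),
               tolerance = 1e-10)
  expect_equal(choice_probability(1, 2, 1 - 1e-12), 1, tolerance = 1e-6)
  # monotone in v and z
  expect_true(all(diff(choice_probability(seq(-3, 3, 0.25), 1.8, 0.5)) > 0))
  zs <- seq(0.05, 0.95, 0.05)
  expect_true(all(diff(vapply(zs, function(z) choice_probability(0.5, 1.8, z), 0)) > 0))
  # sign-flip invariance
  expect_equal(choice_probability(1.2, 2, 0.35),
               1 - choice_probability(-1.2, 2, 0.65), tolerance = 1e-12)
  # quadrature cross-check of the hit probability
  f <- function(dt) exp(wfpt_logpdf(dt, "upper", v = 1, a = 2, z = 0.5, t = 0))
  expect_equal(integrate(f, 0, 80, rel.tol = 1e-9)$value,
               choice_probability(1, 2, 0.5), tolerance = 1e-5)
})

test_that("the Euler simulator agrees with the analytic choice probability and density", {
  n <- 2e4
  sim <- simulate_ddm(n, v = 1.5, a = 1.8, z = 0.5, t = 0.3, seed = 7)
  expect_identical(sim, simulate_ddm(n, v = 1.5, a = 1.8, z = 0.5, t = 0.3, seed = 7))
  p <- choice_probability(1.5, 1.8, 0.5)
  expect_lt(abs(mean(sim$boundary == "upper") - p), 3 * sqrt(p * (1 - p) / n))
  expect_true(all(sim$dt[!sim$censored] > 0.3))
  expect_lt(wfpt_ks(sim, 1.5, 1.8, 0.5, 0.3), 0.015)

  # drift dominance and DT monotonicity in |v|
  fast <- simulate_ddm(500, v = 20, a = 1.8, z = 0.5, t = 0, seed = 8)
  expect_true(all(fast$boundary == "upper"))
  mean_dt <- vapply(c(0, 1.5, 3, 6), function(v)
    mean(simulate_ddm(3000, v, a = 1.8, z = 0.5, t = 0, seed = 9)$dt, na.rm = TRUE), 0)
  expect_true(all(diff(mean_dt) < 0))
})

test_that("the dataset log-likelihood is finite on valid data and matches the WFPT sum", {
  fx <- tiny_cohort_data(n_subjects = 2, seed = 11)
  d <- fx$trials[fx$trials$subject == 1 & fx$trials$condition == "ON", ]
  p <- as.list(fx$cohort[fx$cohort$subject == 1 & fx$cohort$condition == "ON", ])
  ll <- rlddm_loglik(d, p)
  expect_true(is.finite(ll))
  # manual replay: trajectory drift + per-trial WFPT terms
  resp <- d[!d$omitted, ]
  traj <- compute_q_trajectory(resp, p)
  manual <- sum(vapply(seq_len(nrow(resp)), function(i)
    wfpt_logpdf(resp$dt_s[i], ifelse(resp$choice[i] == "A", "upper", "lower"),
                v = traj$drift[i], a = p$a, z = p$z, t = p$t), 0))
  expect_equal(ll, manual, tolerance = 1e-10)
  # dt at or below t makes the dataset impossible
  p$t <- min(resp$dt_s) + 0.01
  expect_identical(rlddm_loglik(d, p), -Inf)
})
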