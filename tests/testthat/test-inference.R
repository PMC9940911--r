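test_that("fits are deterministic under a seed and respect the model variant", {
  fx <- tiny_cohort_data(n_subjects = 3, seed = 51)
  f1 <- suppressWarnings(fit_rlddm(fx$trials, chains = 2, burn = 150, draws = 150, seed = 77))
  f2 <- suppressWarnings(fit_rlddm(fx$trials, chains = 2, burn = 150, draws = 150, seed = 77))
  expect_identical(summary(f1), summary(f2))
  expect_identical(coef(f1), coef(f2))

  fs <- suppressWarnings(fit_rlddm(fx$trials, rlddm_model(variant = "single"),
                                   chains = 1, burn = 100, draws = 100, seed = 78))
  expect_identical(fs$theta[, , 3], fs$theta[, , 4])  # alpha+ == alpha-
  expect_false("alpha_neg_raw" %in% summary(fs)$parameter)
})

test_that("trial windows select the right likelihood and reject empty windows", {
  fx <- tiny_cohort_data(n_subjects = 2, seed = 52)
  fpost <- suppressWarnings(fit_rlddm(fx$trials, rlddm_model(window = "post"),
                                      chains = 1, burn = 60, draws = 60, seed = 5))
  trials_seen <- unlist(lapply(fpost$data, function(d) d$trial))
  expect_true(all(trials_seen >= 61 & trials_seen <= 120))
  fpre <- suppressWarnings(fit_rlddm(fx$trials, rlddm_model(window = "pre"),
                                     chains = 1, burn = 60, draws = 60, seed = 5))
  expect_true(all(unlist(lapply(fpre$data, function(d) d$trial)) <= 60))
  expect_error(fit_rlddm(fx$trials[fx$trials$trial <= 60, ],
                         rlddm_model(window = "post"), chains = 1,
                         burn = 50, draws = 50), "window")
})

test_that("the model deviance equals the summed WFPT likelihood at a point", {
  fx <- tiny_cohort_data(n_subjects = 2, seed = 53)
  fit <- suppressWarnings(fit_rlddm(fx$trials, chains = 1, burn = 100, draws = 100, seed = 6))
  est <- coef(fit)
  manual <- 0
  for (i in seq_len(nrow(est))) {
    d <- fx$trials[fx$trials$subject == est$subject[i] &
                     fx$trials$condition == est$condition[i], ]
    manual <- manual + rlddm_loglik(d, as.list(est[i, ]))
  }
  dic <- compute_dic(fit)
  expect_equal(dic$deviance_at_mean, -2 * manual, tolerance = 1e-8)
  expect_equal(dic$dic, 2 * dic$mean_deviance - dic$deviance_at_mean,
               tolerance = 1e-10)
})

test_that("HDIs match analytic quantiles, nest, and cover their mass", {
  set.seed(99)
  x <- rnorm(1e5)
  h95 <- hdi(x, 0.95)
  expect_equal(h95, c(-1.96, 1.96), tolerance = 0.05)
  h85 <- hdi(x, 0.85)
  expect_gt(h85[1], h95[1]); expect_lt(h85[2], h95[2])
  # empirical mass matches the requested mass (unimodal oracle)
  for (mass in c(0.5, 0.85, 0.95)) {
    y <- rgamma(5e4, shape = 3)
    h <- hdi(y, mass)
    expect_equal(mean(y >= h[1] & y <= h[2]), mass, tolerance = 0.01)
    # the narrowest interval is no wider than the central quantile interval
    q <- quantile(y, c((1 - mass) / 2, 1 - (1 - mass) / 2), names = FALSE)
    expect_lte(diff(h), diff(q) + 1e-9)
  }
})

test_that("duplicated chains give an R-hat of one; diverged chains do not", {
  set.seed(4)
  x <- rnorm(2000)
  expect_equal(gelman_rubin(c(x, x), rep(1:2, each = 2000)), 1, tolerance = 0.02)
  y <- c(rnorm(2000), rnorm(2000, 5))
  expect_gt(gelman_rubin(y, rep(1:2, each = 2000)), 1.5)
})

test_that("posterior contrasts summarise condition differences correctly", {
  # synthetic fit carrying known group-mean draws
  set.seed(12)
  dr <- rnorm(1e4, 0, 1)
  mu <- array(0, c(1e4, 4, 2),
              dimnames = list(NULL, c("a", "m", "alpha_pos_raw", "alpha_neg_raw"),
                              c("OFF", "ON")))
  mu[, "m", "ON"] <- dr
  mu[, "m", "OFF"] <- 0
  fake <- structure(list(mu = mu, conditions = c("OFF", "ON")),
                    class = "rlddm_fit")
  ct <- posterior_contrast(fake, "m", "ON", "OFF")
  expect_equal(ct$m_diff, mean(dr))
  expect_equal(ct$hdi95, c(-1.96, 1.96), tolerance = 0.08)
  expect_false(ct$significant)
  # nesting
  expect_gt(ct$hdi85[1], ct$hdi95[1]); expect_lt(ct$hdi85[2], ct$hdi95[2])
  # self-contrast is exactly zero
  self <- posterior_contrast(fake, "m", "ON", "ON")
  expect_equal(self$m_diff, 0)
  expect_true(all(self$hdi95 == 0))
  # translation equivariance
  mu2 <- mu; mu2[, "m", "ON"] <- dr + 3
  fake2 <- structure(list(mu = mu2, conditions = c("OFF", "ON")), class = "rlddm_fit")
  expect_equal(posterior_contrast(fake2, "m", "ON", "OFF")$m_diff, ct$m_diff + 3)
  expect_error(posterior_contrast(fake, "nope", "ON", "OFF"), "unknown")
})

test_that("DIC reduces to the point deviance for a degenerate posterior and matches a conjugate oracle", {
  d0 <- dic_from_deviance(rep(42, 100), 42)
  expect_equal(d0$p_d, 0)
  expect_equal(d0$dic, 42)

  # conjugate normal-mean toy model: y_i ~ N(theta, 1), flat-ish prior.
  # Posterior is N(ybar, 1/n); E[deviance] = D(ybar) + 1, so pD ~ 1 and
  # DIC ~ D(ybar) + 2.
  set.seed(8)
  n <- 50
  y <- rnorm(n, 2, 1)
  theta <- rnorm(2e5, mean(y), sqrt(1 / n))
  dev <- vapply(theta, function(th) sum((y - th)^2) + n * log(2 * pi), 0)
  dev_mean <- sum((y - mean(y))^2) + n * log(2 * pi)
  dic <- dic_from_deviance(dev, dev_mean)
  expect_equal(dic$p_d, 1, tolerance = 0.05)
  expect_equal(dic$dic, dev_mean + 2, tolerance = 0.1)
})
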