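test_that("the logistic squash maps the estimation scale onto valid rates", {
  expect_equal(squash_rate(0), 0.5)
  # independent hand computation of the published-scale example
  expect_equal(squash_rate(-2.65), 1 / (1 + exp(2.65)), tolerance = 1e-12)
  expect_equal(squash_rate(50), 1, tolerance = 1e-12)
  expect_true(all(diff(squash_rate(seq(-5, 5, 0.1))) > 0))
  expect_error(squash_rate(Inf), "finite")
})

test_that("the delta rule updates with the sign-matched learning rate", {
  expect_equal(update_q(0.5, 1, alpha_pos = 0.5, alpha_neg = 0.1), 0.75)
  expect_equal(update_q(0.8, 0, alpha_pos = 0.5, alpha_neg = 0.05), 0.76)
  expect_equal(update_q(1.0, 1, 0.3, 0.3), 1.0)  # zero prediction error
  expect_error(update_q(0.5, 2, 0.3), "outcome")
})

test_that("trajectories match a brute-force oracle and handle omissions", {
  set.seed(101)
  for (rep in 1:5) {
    tr <- random_trials(120)
    ap_raw <- rnorm(1); an_raw <- rnorm(1)
    traj <- compute_q_trajectory(tr, list(m = 2.5, alpha_pos_raw = ap_raw,
                                          alpha_neg_raw = an_raw))
    oracle <- naive_q_oracle(tr, plogis(ap_raw), plogis(an_raw))
    expect_equal(traj$q_a, oracle[, 1], tolerance = 1e-12)
    expect_equal(traj$q_b, oracle[, 2], tolerance = 1e-12)
    expect_equal(traj$drift, 2.5 * (oracle[, 1] - oracle[, 2]), tolerance = 1e-12)
    expect_true(all(traj$q_a >= 0 & traj$q_a <= 1))
  }

  # all omitted: constant at q0
  tr <- random_trials(10, omission_rate = 1)
  traj <- compute_q_trajectory(tr, list(m = 1, alpha_pos_raw = 0, alpha_neg_raw = 0),
                               q0 = c(0.3, 0.7))
  expect_equal(traj$q_a, rep(0.3, 10))
  expect_equal(traj$q_b, rep(0.7, 10))

  # single trial, hand arithmetic: q0 0.5, alpha+ 0.3, win on A -> 0.65
  tr1 <- data.frame(subject = 1, condition = "X", session = 1, trial = 1:2,
                    choice = c("A", "A"), outcome = c(1L, 1L), dt_s = 1,
                    omitted = FALSE)
  traj1 <- compute_q_trajectory(tr1, list(m = 1, alpha_pos_raw = qlogis(0.3),
                                          alpha_neg_raw = 0))
  expect_equal(traj1$q_a[2], 0.65)
  expect_equal(traj1$q_b[2], 0.5)

  # full-step update: chosen Q equals the last outcome of that option
  tr <- random_trials(60, omission_rate = 0)
  traj <- compute_q_trajectory(tr, list(m = 1, alpha_pos_raw = 40, alpha_neg_raw = 40))
  for (i in 2:60) {
    prev <- max(which(tr$choice[1:(i - 1)] == tr$choice[i] | FALSE, arr.ind = TRUE), -1)
    prevA <- which(tr$choice[1:(i - 1)] == "A")
    if (tr$choice[i] == "A" && length(prevA))
      expect_equal(traj$q_a[i], tr$outcome[max(prevA)], tolerance = 1e-10)
  }

  expect_error(compute_q_trajectory(tr[c(2, 1), ], list(m = 1, alpha_pos_raw = 0,
                                                        alpha_neg_raw = 0)),
               "increasing")
})

test_that("exploratory classification uses strict inequality and excludes omissions", {
  tr <- data.frame(subject = 1, condition = "X", session = 1, trial = 1:4,
                   choice = c("A", "B", "A", NA),
                   outcome = c(0L, 1L, 1L, NA), dt_s = c(1, 1, 1, NA),
                   omitted = c(FALSE, FALSE, FALSE, TRUE))
  traj <- data.frame(trial = 1:4,
                     q_a = c(0.3, 0.5, 0.5, 0.6),
                     q_b = c(0.7, 0.5, 0.2, 0.4),
                     drift = 0, pe = 0)
  flags <- classify_exploratory(tr, traj)
  expect_identical(flags, c(TRUE, FALSE, FALSE, NA))  # lower, tie, higher, omitted
  expect_error(classify_exploratory(tr, traj[1:3, ]), "aligned")

  # 6 exploratory flags out of 40 responses -> 0.15
  expect_equal(pexplore(c(rep(TRUE, 6), rep(FALSE, 34))), 0.15)
})
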