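test_that("omission filtering reports counts and preserves trial indices", {
  set.seed(71)
  tr <- random_trials(120, omission_rate = 0)
  f0 <- filter_omissions(tr)
  expect_identical(f0$trials, tr)
  expect_equal(f0$n_omitted, 0L)

  tr$omitted[c(3, 40, 41, 80, 100, 101, 102, 119)] <- TRUE
  tr$choice[tr$omitted] <- NA; tr$outcome[tr$omitted] <- NA; tr$dt_s[tr$omitted] <- NA
  f8 <- filter_omissions(tr)
  expect_equal(f8$n_omitted, 8L)
  expect_equal(nrow(f8$trials), 112L)
  expect_identical(f8$trials$trial, setdiff(1:120, c(3, 40, 41, 80, 100, 101, 102, 119)))

  all_om <- random_trials(5, omission_rate = 1)
  expect_warning(fa <- filter_omissions(all_om), "omitted")
  expect_equal(nrow(fa$trials), 0L)
})

test_that("session summaries compute response-based ratios", {
  set.seed(72)
  tr <- random_trials(120, omission_rate = 0.1)
  traj <- compute_q_trajectory(tr, list(m = 2, alpha_pos_raw = 0, alpha_neg_raw = -1))
  ss <- session_summary(tr, traj)
  expect_equal(ss$session, 1:3)
  expect_equal(sum(ss$n_responses), sum(!tr$omitted))
  expect_true(all(ss$p_explore >= 0 & ss$p_explore <= 1))
  expect_true(all(ss$rewards <= ss$n_responses))
  # hand check of session 1
  flags <- classify_exploratory(tr, traj)
  i <- tr$session == 1 & !tr$omitted
  expect_equal(ss$p_explore[1], mean(flags[i]))
  expect_equal(ss$rewards[1], sum(tr$outcome[i]))
})

test_that("binned statistics stay anchored to the absolute trial grid", {
  set.seed(73)
  tr <- random_trials(120, omission_rate = 0)
  # knock out every response in bin 4 (trials 31-40)
  tr$omitted[31:40] <- TRUE
  tr$choice[31:40] <- NA; tr$outcome[31:40] <- NA; tr$dt_s[31:40] <- NA
  traj <- compute_q_trajectory(tr, list(m = 2, alpha_pos_raw = 0, alpha_neg_raw = -1))
  bs <- binned_stats(tr, traj, bin_width = 10)
  expect_equal(nrow(bs), 12L)
  expect_equal(bs$n_responses[4], 0L)
  expect_true(is.na(bs$p_explore[4]) && is.na(bs$p_reward[4]))
  # a bin with 6 rewards over 10 responses
  b1 <- tr$trial <= 10
  expect_equal(bs$p_reward[1], mean(tr$outcome[b1]))
  expect_error(binned_stats(tr, traj, bin_width = 7), "divide")

  # aggregation consistency: response-weighted bin means equal the
  # response-weighted session means at the task level
  flags <- classify_exploratory(tr, traj)
  task_pe <- mean(flags, na.rm = TRUE)
  ok <- bs$n_responses > 0
  expect_equal(sum(bs$p_explore[ok] * bs$n_responses[ok]) / sum(bs$n_responses[ok]),
               task_pe, tolerance = 1e-12)
  ss <- session_summary(tr, traj)
  expect_equal(sum(ss$p_explore * ss$n_responses) / sum(ss$n_responses),
               task_pe, tolerance = 1e-12)
})

test_that("stimulation-induced exploration contrasts follow their definitions", {
  on <- data.frame(session = 1:3, p_explore = c(0.2, 0.44, 0.1))
  off <- data.frame(session = 1:3, p_explore = c(0.1, 0.1, 0.1))
  expect_equal(delta_pexplore(on, off, "max_session"), 0.34)
  expect_equal(delta_pexplore(on, on, "max_session"), 0)
  off2 <- data.frame(session = 1:3, p_explore = c(0.1, 0.24, -0.2))
  expect_equal(delta_pexplore(on, off2, "whole_task"), 0.2)
  expect_error(delta_pexplore(on, off[1:2, ], "max_session"), "sessions")
})
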