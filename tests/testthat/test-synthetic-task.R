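test_that("schedule encodes the reversal design with an exact probability swap", {
  sch <- make_schedule(0.8, 40, 3, 60)
  expect_s3_class(sch, "task_schedule")
  expect_equal(sch$n_trials, 120L)
  expect_equal(as.vector(table(sch$session)), c(40L, 40L, 40L))
  expect_equal(unname(sch$p_reward[1:60, "A"]), rep(0.8, 60))
  expect_equal(unname(sch$p_reward[61:120, "A"]), rep(0.2, 60))
  # exact swap: A before reversal equals B after, elementwise
  expect_identical(unname(sch$p_reward[60, "A"]), unname(sch$p_reward[61, "B"]))
  expect_equal(unname(sch$p_reward[, "A"]), rev(unname(sch$p_reward[, "B"])))
  # degenerate deterministic design is allowed
  det <- make_schedule(1.0, 10, 1, 5)
  expect_equal(unname(det$p_reward[1:5, "A"]), rep(1, 5))
  expect_error(make_schedule(0.8, 40, 3, 120), "strictly inside")
  expect_error(make_schedule(0.4), "p_high")
})

test_that("cohort sampling is reproducible, respects zero-variance limits, and matches its group means", {
  spec <- cohort_spec(n_subjects = 18)
  expect_identical(sample_cohort(spec, seed = 5), sample_cohort(spec, seed = 5))

  sds0 <- default_group_sds(); sds0[] <- 0
  degenerate <- sample_cohort(cohort_spec(n_subjects = 4, group_sds = sds0), seed = 1)
  on <- degenerate[degenerate$condition == "ON", ]
  expect_true(all(on$a == default_group_means()$ON[["a"]]))
  expect_true(all(on$m == default_group_means()$ON[["m"]]))

  # law of large numbers on the estimation scale
  sds <- default_group_sds(); sds[] <- 0.3
  big <- sample_cohort(cohort_spec(n_subjects = 1000, conditions = "OFF",
                                   group_means = default_group_means()["OFF"],
                                   group_sds = sds), seed = 2)
  se <- 0.3 / sqrt(1000)
  gm <- default_group_means()$OFF
  for (p in c("a", "m", "alpha_pos_raw", "alpha_neg_raw"))
    expect_lt(abs(mean(big[[p]]) - gm[[p]]), 3 * se)
})

test_that("the generative loop conserves records, keeps DTs above t, and omits correctly", {
  sch <- make_schedule()
  coh <- sample_cohort(cohort_spec(n_subjects = 4), seed = 3)
  dat <- generate_cohort_data(coh, sch, omission_rate = 0.05, seed = 9)
  expect_equal(nrow(dat), 4 * 2 * sch$n_trials)
  expect_identical(generate_cohort_data(coh, sch, omission_rate = 0.05, seed = 9), dat)
  # omitted trials carry nothing
  om <- dat[dat$omitted, ]
  expect_true(all(is.na(om$choice)) && all(is.na(om$outcome)) && all(is.na(om$dt_s)))
  # responded DTs exceed the subject's non-decision time and fit the window
  key <- paste(dat$subject, dat$condition)
  tmap <- coh$t[match(key, paste(coh$subject, coh$condition))]
  resp <- !dat$omitted
  expect_true(all(dat$dt_s[resp] > tmap[resp]))
  expect_true(all(dat$dt_s[resp] <= 3))
})

test_that("omission fraction converges to the Bernoulli rate without a deadline", {
  sch <- make_schedule()
  coh <- sample_cohort(cohort_spec(n_subjects = 42, conditions = c("ON", "OFF")),
                       seed = 21)
  dat <- generate_cohort_data(coh, sch, omission_rate = 0.05,
                              response_window = Inf, seed = 22)
  n <- nrow(dat)
  expect_gte(n, 1e4)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(dat$omitted) - 0.05), 3 * se)
})

test_that("a frozen learner keeps constant values and a value-blind agent splits choices", {
  sch <- make_schedule()
  frozen <- data.frame(subject = 1, condition = "X", a = 1.8, m = 3,
                       alpha_pos_raw = -40, alpha_neg_raw = -40, t = 0.3, z = 0.5)
  dat <- generate_cohort_data(frozen, sch, omission_rate = 0, seed = 4)
  traj <- compute_q_trajectory(dat, as.list(frozen))
  expect_equal(traj$q_a, rep(0.5, 120))
  expect_equal(traj$drift, rep(0, 120))

  blind <- data.frame(subject = 1:20, condition = "X", a = 1.8, m = 0,
                      alpha_pos_raw = 0, alpha_neg_raw = -1, t = 0.3, z = 0.5)
  dat <- generate_cohort_data(blind, sch, omission_rate = 0, seed = 5)
  pa <- mean(dat$choice == "A", na.rm = TRUE)
  expect_lt(abs(pa - 0.5), 3 * sqrt(0.25 / sum(!dat$omitted)))
})

test_that("a perfect exploiter earns the scheduled pre-reversal reward rate", {
  sch <- make_schedule()
  # frozen values pinned at (1, 0) with a large scaling: always chooses A
  exploiter <- data.frame(subject = 1:10, condition = "X", a = 1.8, m = 50,
                          alpha_pos_raw = -40, alpha_neg_raw = -40, t = 0.3, z = 0.5)
  dat <- generate_cohort_data(exploiter, sch, omission_rate = 0, seed = 6,
                              q0 = c(1, 0))
  pre <- dat[dat$trial <= 60 & !dat$omitted, ]
  expect_true(all(pre$choice == "A"))
  se <- sqrt(0.8 * 0.2 / nrow(pre))
  expect_lt(abs(mean(pre$outcome) - 0.8), 3 * se)
})

test_that("synthetic voxel cohorts carry the planted correlation structure", {
  # null construction: correlations centred at zero
  null <- synth_voxel_cohort(20, c(8, 8, 8), effect_size = 0, seed = 31)
  r0 <- as.vector(voxelwise_rmap(null$maps, null$behaviour))
  expect_lt(abs(mean(r0)), 0.02)

  planted <- synth_voxel_cohort(20, c(8, 8, 8), effect_size = 0.9,
                                noise_sd = 0.5, seed = 32)
  r <- voxelwise_rmap(planted$maps, planted$behaviour)
  expect_gt(mean(r[planted$mask]), 0.7)

  two <- synth_voxel_cohort(2, c(4, 4, 4), effect_size = 0, seed = 33)
  expect_warning(r2 <- voxelwise_rmap(two$maps, two$behaviour), "degenerate")
  expect_true(all(abs(abs(as.vector(r2)) - 1) < 1e-8))

  empty <- array(FALSE, c(4, 4, 4))
  expect_error(synth_voxel_cohort(5, c(4, 4, 4), effect_mask = empty,
                                  effect_size = 0.5), "empty")
})
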