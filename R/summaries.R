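#' Remove omitted trials
#'
#' Drops trials without a response, preserving the original trial indices
#' (downstream binning stays anchored to the task's trial grid).
#'
#' @param trials a trial table (any number of subjects/conditions).
#' @return list with `trials` (cleaned table) and `n_omitted`.
#' @export
filter_omissions <- function(trials) {
  stopifnot(all(c("omitted") %in% names(trials)))
  keep <- !trials$omitted
  if (!any(keep)) warning("all trials are omitted; returning an empty table",
                          call. = FALSE)
  list(trials = trials[keep, , drop = FALSE], n_omitted = sum(!keep))
}

#' Per-session behavioural summary
#'
#' Rewards won, mean decision time and the probability of exploring
#' (exploratory choices divided by responded choices) for each session of a
#' single subject x condition dataset.
#'
#' @param trials single-dataset trial table (with omitted rows retained).
#' @param traj matching [compute_q_trajectory()] output.
#' @return data.frame with `session`, `n_responses`, `rewards`, `mean_dt`,
#'   `p_explore`.
#' @export
session_summary <- function(trials, traj) {
  .assert_single_dataset(trials)
  flags <- classify_exploratory(trials, traj)
  resp <- !trials$omitted
  out <- lapply(sort(unique(trials$session)), function(s) {
    i <- trials$session == s
    r <- i & resp
    data.frame(session = s,
               n_responses = sum(r),
               rewards = sum(trials$outcome[r]),
               mean_dt = if (any(r)) mean(trials$dt_s[r]) else NA_real_,
               p_explore = if (any(r)) mean(flags[r]) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Binned exploration and reward statistics
#'
#' P(Explore) and P(Reward) in fixed-width bins anchored to the absolute
#' trial grid (omissions reduce denominators but never shift bins). With the
#' default 120-trial task and width 10 the reversal boundary falls exactly
#' between bins 6 and 7.
#'
#' @param trials single-dataset trial table (with omitted rows retained).
#' @param traj matching trajectory.
#' @param bin_width trials per bin (must divide the trial count).
#' @return data.frame with `bin`, `n_responses`, `p_explore`, `p_reward`
#'   (`NA` for bins without responses).
#' @export
binned_stats <- function(trials, traj, bin_width = 10) {
  .assert_single_dataset(trials)
  n_trials <- max(trials$trial)
  if (n_trials %% bin_width != 0)
    stop("`bin_width` must divide the trial count", call. = FALSE)
  flags <- classify_exploratory(trials, traj)
  bin <- ceiling(trials$trial / bin_width)
  resp <- !trials$omitted
  out <- lapply(seq_len(n_trials / bin_width), function(b) {
    r <- bin == b & resp
    data.frame(bin = b,
               n_responses = sum(r),
               p_explore = if (any(r)) mean(flags[r]) else NA_real_,
               p_reward = if (any(r)) mean(trials$outcome[r]) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Stimulation-induced change in exploration
#'
#' Contrast of P(Explore) between two conditions of the same subject:
#' either the maximum within-session increase (the regressor used for the
#' connectivity analysis) or the mean difference across sessions.
#'
#' @param on_summary,off_summary [session_summary()] tables for the two
#'   conditions, over the same session structure.
#' @param mode `"max_session"` or `"whole_task"`.
#' @return scalar difference (ON minus OFF).
#' @export
delta_pexplore <- function(on_summary, off_summary,
                           mode = c("max_session", "whole_task")) {
  mode <- match.arg(mode)
  if (!identical(on_summary$session, off_summary$session))
    stop("condition summaries cover different sessions", call. = FALSE)
  d <- on_summary$p_explore - off_summary$p_explore
  switch(mode, max_session = max(d), whole_task = mean(d))
}

#' Cohort-level P(Explore) from parameters
#'
#' Convenience wrapper: classifies exploratory choices for every subject x
#' condition of a trial table using the supplied parameters, and returns
#' per-dataset P(Explore).
#'
#' @param trials multi-subject trial table.
#' @param params parameter table (as from [sample_cohort()] or
#'   `coef(fit)`), matched by subject and condition.
#' @param q0 initial expected values.
#' @return data.frame `subject`, `condition`, `p_explore`, `n_responses`.
#' @export
cohort_pexplore <- function(trials, params, q0 = c(0.5, 0.5)) {
  key <- interaction(trials$subject, trials$condition, drop = TRUE)
  out <- lapply(split(trials, key), function(d) {
    d <- d[order(d$trial), , drop = FALSE]
    p <- params[params$subject == d$subject[1] &
                params$condition == d$condition[1], ]
    if (nrow(p) != 1L) stop("no unique parameter row for a dataset", call. = FALSE)
    traj <- compute_q_trajectory(d, as.list(p), q0)
    flags <- classify_exploratory(d, traj)
    data.frame(subject = d$subject[1], condition = d$condition[1],
               p_explore = pexplore(flags), n_responses = sum(!d$omitted))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
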