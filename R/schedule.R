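#' Build a two-armed reversal-learning task schedule
#'
#' Constructs per-trial reward probabilities for two independent options
#' ("arms") A and B. Option A pays with probability `p_high` up to and
#' including `reversal_trial`, and with `1 - p_high` afterwards; option B is
#' mirrored, so the contingencies swap exactly at the reversal. The default
#' design is three 40-trial sessions with an 80%:20% contingency reversing
#' after trial 60.
#'
#' @param p_high reward probability of the initially better option;
#'   must satisfy `0.5 < p_high <= 1`.
#' @param trials_per_session number of trials per session (default 40).
#' @param n_sessions number of sessions (default 3).
#' @param reversal_trial 1-based index of the last trial before the swap
#'   (default 60); the reversal takes effect from trial `reversal_trial + 1`.
#' @return an object of class `task_schedule`: a list with `n_trials`,
#'   `session` (per-trial session index), `p_reward` (`n_trials` x 2 matrix,
#'   columns `A` and `B`), `reversal_trial`, `trials_per_session`,
#'   `n_sessions`.
#' @examples
#' sch <- make_schedule()
#' sch$p_reward[59:62, ]
#' @export
make_schedule <- function(p_high = 0.8, trials_per_session = 40,
                          n_sessions = 3, reversal_trial = 60) {
  stopifnot(length(p_high) == 1L, length(reversal_trial) == 1L)
  if (!(p_high > 0.5 && p_high <= 1))
    stop("`p_high` must satisfy 0.5 < p_high <= 1", call. = FALSE)
  n_trials <- as.integer(trials_per_session * n_sessions)
  if (!(reversal_trial >= 1 && reversal_trial < n_trials))
    stop("`reversal_trial` must lie strictly inside the trial range",
         call. = FALSE)
  pre <- seq_len(n_trials) <= reversal_trial
  p_reward <- cbind(A = ifelse(pre, p_high, 1 - p_high),
                    B = ifelse(pre, 1 - p_high, p_high))
  structure(list(
    n_trials = n_trials,
    session = rep(seq_len(n_sessions), each = trials_per_session),
    p_reward = p_reward,
    reversal_trial = as.integer(reversal_trial),
    trials_per_session = as.integer(trials_per_session),
    n_sessions = as.integer(n_sessions)
  ), class = "task_schedule")
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("Reversal-learning schedule: %d sessions x %d trials, reversal after trial %d\n",
              x$n_sessions, x$trials_per_session, x$reversal_trial))
  cat(sprintf("Option A reward probability: %.2f (trials 1-%d), %.2f (trials %d-%d)\n",
              x$p_reward[1, "A"], x$reversal_trial,
              x$p_reward[x$n_trials, "A"], x$reversal_trial + 1L, x$n_trials))
  invisible(x)
}
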