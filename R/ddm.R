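#' Wiener first-passage-time log-density
#'
#' Joint log-density of terminating at a given boundary at decision time
#' `dt` (seconds, including the non-decision time) for a diffusion with
#' drift `v`, boundary separation `a`, relative start point `z` and
#' diffusion coefficient fixed at 1. Evaluated by the small-time /
#' large-time series with an accuracy-based switch (truncation error
#' 1e-7). `dt <= t` is an impossible observation and returns `-Inf`;
#' invalid parameters return `NaN`.
#'
#' @param dt decision times (seconds).
#' @param boundary `"upper"` or `"lower"` (recycled to `length(dt)`).
#' @param v drift rate (evidence/s).
#' @param a boundary separation (> 0).
#' @param z relative start point in (0, 1).
#' @param t non-decision time (seconds, >= 0).
#' @return vector of log-densities.
#' @export
wfpt_logpdf <- function(dt, boundary = "upper", v, a, z = 0.5, t = 0) {
  boundary <- match.arg(boundary, c("upper", "lower"), several.ok = TRUE)
  if (!(a > 0)) stop("`a` must be positive", call. = FALSE)
  if (!(z > 0 && z < 1)) stop("`z` must lie in (0, 1)", call. = FALSE)
  if (!(t >= 0)) stop("`t` must be non-negative", call. = FALSE)
  up <- rep_len(boundary == "upper", length(dt))
  .wfpt_logpdf_cpp(as.numeric(dt), up, v, a, z, t)
}

#' Analytic probability of reaching the upper boundary
#'
#' Closed-form absorption probability of the diffusion at the upper
#' boundary; strictly increasing in both `v` and `z`.
#'
#' @inheritParams wfpt_logpdf
#' @return probability in `[0, 1]` (vectorised over `v`).
#' @examples
#' choice_probability(0, 2)               # 0.5
#' choice_probability(2, 1.78, 0.5)       # ~0.972
#' @export
choice_probability <- function(v, a, z = 0.5) {
  if (!(a > 0)) stop("`a` must be positive", call. = FALSE)
  if (!all(z > 0 & z < 1)) stop("`z` must lie in (0, 1)", call. = FALSE)
  vapply(v, .choice_prob_cpp, 0, a = a, z = z)
}

#' Simulate diffusion trials by the Euler-Maruyama method
#'
#' Forward-simulates the accumulation path with Gaussian increments until a
#' boundary is hit. A continuity correction (boundaries shifted inward by
#' `0.5826 * sqrt(step)`) removes the leading-order discretisation bias of
#' discrete boundary monitoring. Paths that survive past `cap` seconds are
#' flagged censored.
#'
#' @inheritParams wfpt_logpdf
#' @param n number of trials.
#' @param step Euler time step (seconds, default 1e-4).
#' @param cap hard time cap (seconds, default 10).
#' @param correct apply the boundary continuity correction (default TRUE).
#' @param seed integer seed or `NULL`.
#' @return data.frame with `dt` (seconds, `NA` when censored), `boundary`
#'   (`"upper"`/`"lower"`), `censored`.
#' @export
simulate_ddm <- function(n, v, a, z = 0.5, t = 0, step = 1e-4, cap = 10,
                         correct = TRUE, seed = NULL) {
  stopifnot(n >= 1, a > 0, z > 0, z < 1, t >= 0, step > 0, cap > step)
  sim <- .simulate_ddm_cpp(as.integer(n), v, a, z, t, step, cap, correct,
                           .with_seed(.resolve_seed(seed),
                                      sample.int(.Machine$integer.max, 1L)))
  data.frame(dt = sim$dt,
             boundary = ifelse(sim$upper, "upper", "lower"),
             censored = sim$censored,
             stringsAsFactors = FALSE)
}

#' Simulate a single diffusion trial
#'
#' @inheritParams simulate_ddm
#' @return list with `boundary`, `dt` and `censored`.
#' @export
simulate_trial <- function(v, a, z = 0.5, t = 0, step = 1e-4, cap = 10,
                           seed = NULL) {
  out <- simulate_ddm(1L, v, a, z, t, step, cap, seed = seed)
  list(boundary = out$boundary, dt = out$dt, censored = out$censored)
}

#' RLDDM log-likelihood of a single dataset
#'
#' Sum of the WFPT log-densities across the responded trials of one subject
#' x condition, with the trial-wise drift obtained by replaying the delta
#' rule (`v_t = m * (Q_A - Q_B)` with pre-update values; the upper boundary
#' codes option A).
#'
#' @param trials responded trials of one subject x condition, ordered.
#' @param params named list/vector with `a`, `m`, `alpha_pos_raw`,
#'   `alpha_neg_raw`, `t` and `z` (or `z_raw`).
#' @param q0 initial expected values.
#' @return scalar log-likelihood (`-Inf` when any `dt <= t`).
#' @export
rlddm_loglik <- function(trials, params, q0 = c(0.5, 0.5)) {
  trials <- trials[!trials$omitted, , drop = FALSE]
  .assert_single_dataset(trials)
  z <- if (!is.null(params[["z"]])) params[["z"]] else plogis(params[["z_raw"]])
  .loglik_dataset_cpp(as.integer(trials$choice == "A"),
                      as.integer(trials$outcome),
                      as.numeric(trials$dt_s),
                      params[["a"]], params[["m"]],
                      params[["alpha_pos_raw"]], params[["alpha_neg_raw"]],
                      params[["t"]], z, q0[1], q0[2])
}
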