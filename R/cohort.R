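#' Default group-level parameter locations
#'
#' Group means of the RLDDM parameters on the estimation scale for the three
#' study conditions: stimulation ON, stimulation OFF, and healthy controls
#' (HC). Learning rates are on the unbounded scale and squashed through the
#' logistic function at use time; `z_raw` is the logit of the relative start
#' point (0 = unbiased).
#'
#' @return named list of named numeric vectors, one per condition, with
#'   entries `a`, `m`, `alpha_pos_raw`, `alpha_neg_raw`, `t`, `z_raw`.
#' @export
default_group_means <- function() {
  list(
    ON  = c(a = 1.78, m = 3.40, alpha_pos_raw = 0.22, alpha_neg_raw = -2.65,
            t = 0.57, z_raw = 0),
    OFF = c(a = 1.96, m = 4.51, alpha_pos_raw = -0.85, alpha_neg_raw = -2.97,
            t = 0.57, z_raw = 0),
    HC  = c(a = 1.96, m = 2.80, alpha_pos_raw = -0.85, alpha_neg_raw = -1.65,
            t = 0.42, z_raw = 0)
  )
}

#' Default group-level parameter spreads
#'
#' Between-subject standard deviations on the estimation scale.
#'
#' @return named numeric vector.
#' @export
default_group_sds <- function() {
  c(a = 0.25, m = 1.0, alpha_pos_raw = 0.75, alpha_neg_raw = 0.75,
    t = 0.08, z_raw = 0.25)
}

.param_names <- c("a", "m", "alpha_pos_raw", "alpha_neg_raw", "t", "z_raw")

#' Specify a synthetic cohort
#'
#' Describes the hierarchical structure from which subject-level RLDDM
#' parameters are drawn: condition-specific group means with common
#' between-subject spreads. Non-decision time `t` and the start point
#' `z_raw` are shared within a subject across conditions (they are sampled
#' once per subject, from the average of the condition means).
#'
#' @param n_subjects number of subjects.
#' @param conditions character vector of condition labels.
#' @param group_means named list (one element per condition) of named
#'   numeric vectors with entries `a`, `m`, `alpha_pos_raw`,
#'   `alpha_neg_raw`, `t`, `z_raw`.
#' @param group_sds named numeric vector of between-subject sds (>= 0).
#' @param omission_rate per-trial probability of an omission in `[0, 0.1]`.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 18,
                        conditions = c("ON", "OFF"),
                        group_means = default_group_means()[conditions],
                        group_sds = default_group_sds(),
                        omission_rate = 0.015) {
  stopifnot(n_subjects >= 1, length(conditions) >= 1)
  if (!setequal(names(group_means), conditions))
    stop("`group_means` must have one element per condition", call. = FALSE)
  for (cn in conditions) {
    gm <- group_means[[cn]]
    if (!all(.param_names %in% names(gm)) || !all(is.finite(gm)))
      stop("group means must be finite and include ", paste(.param_names, collapse = ", "),
           call. = FALSE)
  }
  if (!all(.param_names %in% names(group_sds)) || !all(is.finite(group_sds)) ||
      any(group_sds < 0))
    stop("group sds must be finite, non-negative and named", call. = FALSE)
  if (!(omission_rate >= 0 && omission_rate <= 0.1))
    stop("`omission_rate` must lie in [0, 0.1]", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 conditions = conditions,
                 group_means = lapply(group_means, function(g) g[.param_names]),
                 group_sds = group_sds[.param_names],
                 omission_rate = omission_rate),
            class = "cohort_spec")
}

.rtrunc_norm <- function(n, mean, sd, lower) {
  if (sd == 0) {
    if (any(mean <= lower)) stop("degenerate draw below bound", call. = FALSE)
    return(rep(mean, n))
  }
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x <= lower)
    guard <- guard + 1L
    if (guard > 1000L) stop("truncated sampling failed to converge", call. = FALSE)
  }
  x
}

#' Sample subject-level parameters for a cohort
#'
#' Draws each subject's RLDDM parameters from the group distributions of a
#' [cohort_spec()] (normal on the estimation scale; `a` and `t` truncated at
#' zero by rejection). Reproducible under `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed, or `NULL` to draw from the session RNG.
#' @return data.frame with one row per subject x condition: `subject`,
#'   `condition`, `a`, `m`, `alpha_pos_raw`, `alpha_neg_raw`, `t`, `z_raw`,
#'   and the squashed rates `alpha_pos`, `alpha_neg` and start point `z`.
#' @export
sample_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(.resolve_seed(seed), {
    n <- spec$n_subjects
    sds <- spec$group_sds
    # shared-within-subject parameters
    t_mean <- mean(vapply(spec$group_means, `[[`, 0, "t"))
    z_mean <- mean(vapply(spec$group_means, `[[`, 0, "z_raw"))
    t_s <- .rtrunc_norm(n, t_mean, sds[["t"]], 0)
    z_s <- rnorm(n, z_mean, sds[["z_raw"]])
    out <- list()
    for (cn in spec$conditions) {
      gm <- spec$group_means[[cn]]
      out[[cn]] <- data.frame(
        subject = seq_len(n),
        condition = cn,
        a = .rtrunc_norm(n, gm[["a"]], sds[["a"]], 0),
        m = rnorm(n, gm[["m"]], sds[["m"]]),
        alpha_pos_raw = rnorm(n, gm[["alpha_pos_raw"]], sds[["alpha_pos_raw"]]),
        alpha_neg_raw = rnorm(n, gm[["alpha_neg_raw"]], sds[["alpha_neg_raw"]]),
        t = t_s,
        z_raw = z_s,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out$alpha_pos <- squash_rate(out$alpha_pos_raw)
    out$alpha_neg <- squash_rate(out$alpha_neg_raw)
    out$z <- plogis(out$z_raw)
    out
  })
}

#' Simulate choices and decision times for a cohort
#'
#' Runs the full generative loop for every subject x condition: the drift on
#' each trial is `m * (Q_A - Q_B)` from the current expected values, a
#' choice and decision time are simulated from the diffusion process, the
#' outcome is drawn from the schedule, and the chosen option's Q-value is
#' updated by the delta rule. Omissions occur as independent Bernoulli
#' events (and when the simulated response would exceed the response
#' window); omitted trials carry no outcome and trigger no value update.
#'
#' @param cohort data.frame of subject parameters as from [sample_cohort()].
#' @param schedule a [make_schedule()] object.
#' @param omission_rate per-trial omission probability.
#' @param response_window response deadline in seconds (default 3; `Inf`
#'   disables the deadline).
#' @param q0 initial expected values for options A and B.
#' @param step Euler step of the diffusion simulation (seconds).
#' @param cap hard simulation time cap (seconds); capped trials are omitted.
#' @param seed integer seed or `NULL`.
#' @return data.frame of trials with columns `subject`, `condition`,
#'   `session`, `trial`, `choice` (`"A"`/`"B"`/`NA`), `outcome` (0/1/`NA`),
#'   `dt_s`, `omitted`.
#' @export
generate_cohort_data <- function(cohort, schedule, omission_rate = 0.015,
                                 response_window = 3, q0 = c(0.5, 0.5),
                                 step = 1e-4, cap = 10, seed = NULL) {
  stopifnot(inherits(schedule, "task_schedule"),
            all(c("subject", "condition", "a", "m", "alpha_pos_raw",
                  "alpha_neg_raw", "t") %in% names(cohort)))
  if (!all(is.finite(as.matrix(cohort[, c("a", "m", "alpha_pos_raw",
                                          "alpha_neg_raw", "t")]))))
    stop("all cohort parameters must be finite", call. = FALSE)
  z <- if ("z" %in% names(cohort)) cohort$z else plogis(cohort$z_raw)
  .with_seed(.resolve_seed(seed), {
    seeds <- sample.int(.Machine$integer.max, nrow(cohort))
    out <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      sim <- .generate_dataset_cpp(schedule$p_reward,
                                   cohort$a[i], cohort$m[i],
                                   cohort$alpha_pos_raw[i], cohort$alpha_neg_raw[i],
                                   cohort$t[i], z[i],
                                   omission_rate, response_window,
                                   q0[1], q0[2], step, cap, seeds[i])
      out[[i]] <- data.frame(
        subject = cohort$subject[i],
        condition = cohort$condition[i],
        session = schedule$session,
        trial = seq_len(schedule$n_trials),
        choice = c("B", "A")[sim$choice + 1L],
        outcome = sim$outcome,
        dt_s = sim$dt,
        omitted = sim$omitted,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}
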