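#' Squash an unbounded learning rate into (0, 1)
#'
#' Logistic transform mapping the estimation scale (where group-level
#' summaries such as negative learning-rate means live) onto valid
#' delta-rule learning rates.
#'
#' @param raw numeric vector on the unbounded scale.
#' @return learning rates in (0, 1).
#' @examples
#' squash_rate(0)      # 0.5
#' squash_rate(-2.65)  # ~0.066
#' @export
squash_rate <- function(raw) {
  if (!all(is.finite(raw))) stop("`raw` must be finite", call. = FALSE)
  plogis(raw)
}

#' Delta-rule value update with asymmetric learning rates
#'
#' `Q <- Q + alpha * (R - Q)`, using `alpha_pos` when the prediction error
#' `R - Q` is positive and `alpha_neg` when it is negative.
#'
#' @param q current expected value in `[0, 1]`.
#' @param outcome observed outcome, 0 or 1.
#' @param alpha_pos,alpha_neg learning rates in (0, 1).
#' @return updated expected value.
#' @export
update_q <- function(q, outcome, alpha_pos, alpha_neg = alpha_pos) {
  if (!all(outcome %in% c(0, 1)))
    stop("`outcome` must be 0 or 1", call. = FALSE)
  stopifnot(all(q >= 0 & q <= 1),
            all(alpha_pos > 0 & alpha_pos < 1),
            all(alpha_neg > 0 & alpha_neg < 1))
  pe <- outcome - q
  q + ifelse(pe > 0, alpha_pos, alpha_neg) * pe
}

#' Expected-value trajectory of one dataset
#'
#' Replays the delta rule through an ordered single-subject,
#' single-condition trial table: only the chosen option's value is updated,
#' omitted trials update nothing, and the reported values are the
#' *pre-choice* values of each trial (decision precedes feedback). The
#' per-trial drift is `m * (q_a - q_b)`.
#'
#' @param trials data.frame with columns `trial`, `choice` (`"A"`/`"B"`/NA),
#'   `outcome`, `omitted`.
#' @param params named list or vector with `m`, `alpha_pos_raw`,
#'   `alpha_neg_raw` (rates on the unbounded scale).
#' @param q0 initial values `c(q_a, q_b)`.
#' @return data.frame with columns `trial`, `q_a`, `q_b`, `drift`, `pe`
#'   (prediction error; `NA` on omitted trials).
#' @export
compute_q_trajectory <- function(trials, params, q0 = c(0.5, 0.5)) {
  .assert_single_dataset(trials)
  ap <- squash_rate(params[["alpha_pos_raw"]])
  an <- squash_rate(params[["alpha_neg_raw"]])
  m <- params[["m"]]
  n <- nrow(trials)
  q_a <- q_b <- pe <- numeric(n)
  qa <- q0[1]; qb <- q0[2]
  for (i in seq_len(n)) {
    q_a[i] <- qa; q_b[i] <- qb
    if (isTRUE(trials$omitted[i]) || is.na(trials$choice[i])) {
      pe[i] <- NA_real_
      next
    }
    r <- trials$outcome[i]
    if (trials$choice[i] == "A") {
      pe[i] <- r - qa
      qa <- qa + (if (pe[i] > 0) ap else an) * pe[i]
    } else {
      pe[i] <- r - qb
      qb <- qb + (if (pe[i] > 0) ap else an) * pe[i]
    }
  }
  data.frame(trial = trials$trial, q_a = q_a, q_b = q_b,
             drift = m * (q_a - q_b), pe = pe)
}

#' Flag exploratory choices
#'
#' A responded trial is exploratory when the chosen option's pre-choice
#' expected value is *strictly* below the alternative's (ties count as
#' exploitative). Omitted trials are `NA` and excluded from downstream
#' denominators.
#'
#' @param trials single-subject trial table (see [compute_q_trajectory()]).
#' @param traj matching trajectory from [compute_q_trajectory()].
#' @return logical vector, one element per trial.
#' @export
classify_exploratory <- function(trials, traj) {
  if (nrow(trials) != nrow(traj) || any(trials$trial != traj$trial))
    stop("trials and trajectory are not aligned", call. = FALSE)
  flag <- ifelse(trials$choice == "A", traj$q_a < traj$q_b, traj$q_b < traj$q_a)
  flag[is.na(trials$choice) | trials$omitted] <- NA
  flag
}

#' Session-level probability of exploring
#'
#' Fraction of responded trials flagged exploratory.
#'
#' @param flags output of [classify_exploratory()].
#' @return proportion in `[0, 1]` (NaN if no responded trials).
#' @export
pexplore <- function(flags) mean(flags, na.rm = TRUE)
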