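#' Learning curve of a trial table
#'
#' Per-trial probability of choosing the objectively better option (the one
#' with the higher scheduled reward probability), averaged across the
#' responded datasets of each condition.
#'
#' @param trials multi-subject trial table.
#' @param schedule the [make_schedule()] the data were collected under.
#' @return data.frame `condition`, `trial`, `p_best`, `n` (responders).
#' @export
learning_curve <- function(trials, schedule) {
  best <- ifelse(schedule$p_reward[, "A"] >= schedule$p_reward[, "B"], "A", "B")
  out <- lapply(split(trials, trials$condition), function(d) {
    resp <- d[!d$omitted, , drop = FALSE]
    agg <- lapply(seq_len(schedule$n_trials), function(tt) {
      i <- resp$trial == tt
      data.frame(trial = tt,
                 p_best = if (any(i)) mean(resp$choice[i] == best[tt]) else NA_real_,
                 n = sum(i))
    })
    agg <- do.call(rbind, agg)
    agg$condition <- d$condition[1]
    agg[, c("condition", "trial", "p_best", "n")]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Posterior-predictive check
#'
#' Simulates full synthetic replications of the experiment from the
#' subject-level posterior means of a fit and compares the observed learning
#' curve with the 95% band across simulations; per-session P(Explore) and
#' P(Reward) of each simulation are returned alongside.
#'
#' @param fit an `rlddm_fit` (whole-task window).
#' @param trials the observed trial table the fit was computed from.
#' @param schedule the task schedule.
#' @param n_sims number of replications (default 50).
#' @param omission_rate omission rate used in the simulations (default 0).
#' @param seed integer seed or `NULL`.
#' @return object of class `rlddm_ppc`: `observed` (learning curve),
#'   `band` (per condition x trial: `lo`, `hi`, `mean`), `coverage`
#'   (per-condition fraction of trials whose observed curve lies inside the
#'   band), `session_stats` (per simulation x dataset session summaries)
#'   and `n_sims`.
#' @export
posterior_predictive <- function(fit, trials, schedule, n_sims = 50,
                                 omission_rate = 0, seed = NULL) {
  stopifnot(inherits(fit, "rlddm_fit"), n_sims >= 1)
  est <- coef(fit)
  obs <- learning_curve(trials, schedule)
  .with_seed(.resolve_seed(seed), {
    seeds <- sample.int(.Machine$integer.max, n_sims)
    curves <- vector("list", n_sims)
    stats <- vector("list", n_sims)
    for (s in seq_len(n_sims)) {
      sim <- generate_cohort_data(est, schedule, omission_rate = omission_rate,
                                  seed = seeds[s])
      lc <- learning_curve(sim, schedule)
      lc$sim <- s
      curves[[s]] <- lc
      pe <- cohort_pexplore(sim, est, fit$model$q0)
      pe$sim <- s
      stats[[s]] <- pe
    }
    curves <- do.call(rbind, curves)
    band <- lapply(split(curves, list(curves$condition, curves$trial), drop = TRUE),
                   function(d) data.frame(
                     condition = d$condition[1], trial = d$trial[1],
                     mean = mean(d$p_best, na.rm = TRUE),
                     lo = quantile(d$p_best, 0.025, na.rm = TRUE, names = FALSE),
                     hi = quantile(d$p_best, 0.975, na.rm = TRUE, names = FALSE)))
    band <- do.call(rbind, band)
    band <- band[order(band$condition, band$trial), ]
    rownames(band) <- NULL
    mrg <- merge(obs, band, by = c("condition", "trial"))
    inside <- mrg$p_best >= mrg$lo & mrg$p_best <= mrg$hi
    coverage <- tapply(inside, mrg$condition, mean, na.rm = TRUE)
    structure(list(observed = obs, band = band,
                   coverage = coverage,
                   session_stats = do.call(rbind, stats),
                   n_sims = n_sims),
              class = "rlddm_ppc")
  })
}

#' @export
print.rlddm_ppc <- function(x, ...) {
  cat(sprintf("Posterior-predictive check (%d simulated experiments)\n", x$n_sims))
  for (cc in names(x$coverage))
    cat(sprintf("  %s: observed learning curve inside the 95%% band at %.1f%% of trials\n",
                cc, 100 * x$coverage[[cc]]))
  invisible(x)
}

#' Parameter recovery
#'
#' Simulates `n_sets` replications of the experiment from known
#' subject-level parameters, refits the model to each, and correlates the
#' generating with the recovered (posterior-mean) values per parameter.
#' Failed refits are excluded and counted.
#'
#' @param generating parameter table (as from [sample_cohort()] or
#'   `coef(fit)`).
#' @param schedule the task schedule.
#' @param n_sets number of simulated sets to refit (>= 2).
#' @param model an [rlddm_model()] used for the refits.
#' @param chains,burn,draws reduced MCMC budget for the refits.
#' @param omission_rate omission rate of the simulations.
#' @param seed integer seed or `NULL`.
#' @return object of class `rlddm_recovery`: `pairs` (set, subject,
#'   condition, parameter, generating, recovered), `correlations`
#'   (parameter, r, p, n) and `n_failed`.
#' @export
parameter_recovery <- function(generating, schedule, n_sets = 5,
                               model = rlddm_model(), chains = 2,
                               burn = 1000, draws = 1000,
                               omission_rate = 0.015, seed = NULL) {
  stopifnot(n_sets >= 2)
  pnames <- c("a", "m", "alpha_pos_raw", "alpha_neg_raw")
  .with_seed(.resolve_seed(seed), {
    seeds <- matrix(sample.int(.Machine$integer.max, 2L * n_sets), ncol = 2)
    pairs <- list(); n_failed <- 0L
    for (s in seq_len(n_sets)) {
      sim <- generate_cohort_data(generating, schedule,
                                  omission_rate = omission_rate,
                                  seed = seeds[s, 1])
      refit <- tryCatch(
        suppressWarnings(fit_rlddm(sim, model, chains = chains, burn = burn,
                                   draws = draws, seed = seeds[s, 2])),
        error = function(e) NULL)
      if (is.null(refit)) { n_failed <- n_failed + 1L; next }
      rec <- coef(refit)
      mrg <- merge(generating, rec, by = c("subject", "condition"),
                   suffixes = c("_gen", "_rec"))
      for (p in pnames) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          set = s, subject = mrg$subject, condition = mrg$condition,
          parameter = p,
          generating = mrg[[paste0(p, "_gen")]],
          recovered = mrg[[paste0(p, "_rec")]])
      }
    }
    if (n_failed > 0L) message(n_failed, " refit(s) failed and were excluded")
    pairs <- do.call(rbind, pairs)
    cors <- lapply(split(pairs, pairs$parameter), function(d) {
      ct <- cor.test(d$generating, d$recovered)
      data.frame(parameter = d$parameter[1], r = unname(ct$estimate),
                 p = ct$p.value, n = nrow(d))
    })
    cors <- do.call(rbind, cors)
    rownames(cors) <- NULL
    structure(list(pairs = pairs, correlations = cors, n_failed = n_failed),
              class = "rlddm_recovery")
  })
}

#' @export
print.rlddm_recovery <- function(x, ...) {
  cat("Parameter recovery (generating vs recovered):\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

#' Map P(Explore) over the parameter space
#'
#' Simulates synthetic datasets at each combination of a parameter grid
#' centred on a reference parameter set, and records the mean probability
#' of exploring (with its Monte-Carlo standard error) per cell.
#'
#' @param center named vector of reference parameters (`a`, `m`,
#'   `alpha_pos_raw`, `alpha_neg_raw`, `t`, `z_raw`).
#' @param grid named list of value vectors for the axes to vary (e.g.
#'   `list(m = seq(0, 6, 1))`).
#' @param schedule the task schedule.
#' @param sims_per_cell simulated datasets per cell (default 20).
#' @param omission_rate omission rate of the simulations (default 0).
#' @param seed integer seed or `NULL`.
#' @return data.frame with one row per cell: the grid columns plus
#'   `p_explore`, `se`, `n_sims`.
#' @export
pexplore_parameter_map <- function(center, grid, schedule, sims_per_cell = 20,
                                   omission_rate = 0, seed = NULL) {
  stopifnot(length(grid) >= 1, all(names(grid) %in% .param_names))
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  .with_seed(.resolve_seed(seed), {
    seeds <- sample.int(.Machine$integer.max, nrow(cells))
    res <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      par <- as.list(center)
      for (nm in names(grid)) par[[nm]] <- cells[i, nm]
      cohort <- data.frame(subject = seq_len(sims_per_cell), condition = "SIM",
                           a = par$a, m = par$m,
                           alpha_pos_raw = par$alpha_pos_raw,
                           alpha_neg_raw = par$alpha_neg_raw,
                           t = par$t, z = plogis(par$z_raw))
      sim <- generate_cohort_data(cohort, schedule,
                                  omission_rate = omission_rate,
                                  seed = seeds[i])
      pe <- cohort_pexplore(sim, cohort)$p_explore
      res[[i]] <- cbind(cells[i, , drop = FALSE],
                        data.frame(p_explore = mean(pe),
                                   se = sd(pe) / sqrt(length(pe)),
                                   n_sims = sims_per_cell))
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}
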