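#' Weakly-informative default priors
#'
#' Group-level locations get broad normal priors and group spreads
#' half-normal priors, in the style of hierarchical drift-diffusion
#' conventions; learning rates and the start point live on unbounded scales
#' (logistic transform at use time). Order of entries: `a`, `m`,
#' `alpha_pos_raw`, `alpha_neg_raw`, `t`, `z_raw`.
#'
#' @return list with `mu0`, `sd0` (normal location/scale of the group means)
#'   and `sigma_scale` (half-normal scale of the group sds).
#' @export
rlddm_priors <- function() {
  list(mu0 = c(a = 1.5, m = 0, alpha_pos_raw = 0, alpha_neg_raw = 0,
               t = 0.4, z_raw = 0),
       sd0 = c(a = 3, m = 10, alpha_pos_raw = 3, alpha_neg_raw = 3,
               t = 1, z_raw = 1.5),
       sigma_scale = c(a = 1, m = 2, alpha_pos_raw = 1, alpha_neg_raw = 1,
                       t = 0.5, z_raw = 0.5))
}

#' Specify an RLDDM model
#'
#' Defines the model variant (dual or single learning rate), the trial
#' window, and the priors. The condition-dependent parameters are
#' `alpha_pos_raw`, `alpha_neg_raw`, `m` and `a`; the non-decision time and
#' start point are shared across conditions within a subject.
#'
#' @param variant `"dual"` (separate rates for positive/negative prediction
#'   errors) or `"single"` (one shared rate).
#' @param window `"whole"`, `"pre"` (trials 1-60) or `"post"` (61-120);
#'   windowed fits restart the value trajectory at `q0`.
#' @param priors prior specification, see [rlddm_priors()].
#' @param q0 initial expected values.
#' @param reversal_trial boundary used by the pre/post windows.
#' @return object of class `rlddm_model`.
#' @export
rlddm_model <- function(variant = c("dual", "single"),
                        window = c("whole", "pre", "post"),
                        priors = rlddm_priors(), q0 = c(0.5, 0.5),
                        reversal_trial = 60) {
  structure(list(variant = match.arg(variant), window = match.arg(window),
                 priors = priors, q0 = q0,
                 reversal_trial = as.integer(reversal_trial)),
            class = "rlddm_model")
}

.apply_window <- function(trials, model) {
  switch(model$window,
         whole = trials,
         pre = trials[trials$trial <= model$reversal_trial, , drop = FALSE],
         post = trials[trials$trial > model$reversal_trial, , drop = FALSE])
}

#' Fit the hierarchical RLDDM
#'
#' Hierarchical Bayesian estimation by adaptive Metropolis-within-Gibbs:
#' subject-level parameters are normal around condition-specific group means
#' (`a`, `m` and the two learning rates) or a single group mean (`t`,
#' `z_raw`, shared across conditions within a subject); group means receive
#' conjugate Gibbs updates and group sds half-normal priors. The per-trial
#' likelihood is the WFPT density at the drift implied by the delta-rule
#' value trajectory. Omitted trials are excluded from the likelihood.
#'
#' @param trials trial table covering one or more subjects and conditions
#'   (columns as written by [generate_cohort_data()] / [read_trials()]).
#' @param model an [rlddm_model()].
#' @param chains number of MCMC chains (default 4).
#' @param burn burn-in iterations per chain (default 7000).
#' @param draws retained iterations per chain (default 15000).
#' @param seed integer seed or `NULL`.
#' @param rhat_warn warn when any group-level split R-hat is at or above
#'   this value (default 1.1).
#' @return object of class `rlddm_fit` with posterior draw arrays
#'   (`theta` draws x dataset x parameter, `shared` draws x subject x
#'   (t, z_raw), `mu`/`sigma` group arrays, `shared_group`), the deviance
#'   per draw, chain ids, dataset index, convergence diagnostics and the
#'   windowed data.
#' @export
fit_rlddm <- function(trials, model = rlddm_model(), chains = 4,
                      burn = 7000, draws = 15000, seed = NULL,
                      rhat_warn = 1.1) {
  stopifnot(inherits(model, "rlddm_model"),
            all(.trial_columns %in% names(trials)))
  trials <- trials[!trials$omitted, , drop = FALSE]
  trials <- .apply_window(trials, model)
  if (nrow(trials) == 0L)
    stop("no responded trials in the requested window", call. = FALSE)

  subjects <- sort(unique(trials$subject))
  conditions <- sort(unique(trials$condition))
  key <- interaction(trials$subject, trials$condition, drop = TRUE)
  split_tr <- split(trials, key)
  split_tr <- split_tr[order(vapply(split_tr, function(d) {
    match(d$subject[1], subjects) + length(subjects) *
      (match(d$condition[1], conditions) - 1L)
  }, 0L))]
  index <- data.frame(
    dataset = seq_along(split_tr),
    subject = vapply(split_tr, function(d) d$subject[1], split_tr[[1]]$subject[1]),
    condition = vapply(split_tr, function(d) d$condition[1], ""),
    n_trials = vapply(split_tr, nrow, 0L)
  )
  if (any(index$n_trials == 0L))
    stop("every subject must have at least one responded trial in the window",
         call. = FALSE)
  ord <- lapply(split_tr, function(d) d[order(d$trial), , drop = FALSE])

  pr <- model$priors
  res <- .rlddm_mcmc_cpp(
    lapply(ord, function(d) as.integer(d$choice == "A")),
    lapply(ord, function(d) as.integer(d$outcome)),
    lapply(ord, function(d) as.numeric(d$dt_s)),
    match(index$subject, subjects) - 1L,
    match(index$condition, conditions) - 1L,
    length(subjects), length(conditions),
    model$variant == "single",
    model$q0[1], model$q0[2],
    list(mu0 = unname(pr$mu0), sd0 = unname(pr$sd0),
         sigma_scale = unname(pr$sigma_scale)),
    as.integer(chains), as.integer(burn), as.integer(draws),
    .resolve_seed(seed))

  pnames <- c("a", "m", "alpha_pos_raw", "alpha_neg_raw")
  dimnames(res$mu) <- list(NULL, pnames, conditions)
  dimnames(res$sigma) <- list(NULL, pnames, conditions)
  colnames(res$shared_group) <- c("mu_t", "sigma_t", "mu_z_raw", "sigma_z_raw")

  # convergence of group-level nodes and the deviance
  rh <- c(
    vapply(seq_along(pnames), function(p) {
      max(vapply(seq_along(conditions), function(cc)
        gelman_rubin(res$mu[, p, cc], res$chain), 0))
    }, 0),
    gelman_rubin(res$shared_group[, "mu_t"], res$chain),
    gelman_rubin(res$shared_group[, "mu_z_raw"], res$chain),
    gelman_rubin(res$deviance, res$chain)
  )
  names(rh) <- c(paste0("mu_", pnames), "mu_t", "mu_z_raw", "deviance")
  if (model$variant == "single") rh <- rh[names(rh) != "mu_alpha_neg_raw"]
  if (any(rh >= rhat_warn, na.rm = TRUE))
    warning(sprintf("Gelman-Rubin >= %.2f for: %s", rhat_warn,
                    paste(names(rh)[which(rh >= rhat_warn)], collapse = ", ")),
            call. = FALSE)

  structure(list(theta = res$theta, shared = res$shared, mu = res$mu,
                 sigma = res$sigma, shared_group = res$shared_group,
                 deviance = res$deviance, chain = res$chain,
                 index = index, subjects = subjects, conditions = conditions,
                 model = model, data = ord,
                 chains = chains, burn = burn, draws = draws, rhat = rh),
            class = "rlddm_fit")
}

#' Posterior-mean subject-level parameters
#'
#' @param object an `rlddm_fit`.
#' @param ... unused.
#' @return data.frame with one row per subject x condition and columns
#'   `subject`, `condition`, `a`, `m`, `alpha_pos_raw`, `alpha_neg_raw`,
#'   `t`, `z_raw`, `z`.
#' @export
coef.rlddm_fit <- function(object, ...) {
  th <- apply(object$theta, c(2, 3), mean)
  sh <- apply(object$shared, c(2, 3), mean)
  si <- match(object$index$subject, object$subjects)
  out <- data.frame(subject = object$index$subject,
                    condition = object$index$condition,
                    a = th[, 1], m = th[, 2],
                    alpha_pos_raw = th[, 3], alpha_neg_raw = th[, 4],
                    t = sh[si, 1], z_raw = sh[si, 2])
  out$z <- plogis(out$z_raw)
  rownames(out) <- NULL
  out
}

#' Group-level posterior summary
#'
#' Posterior mean and 95% HDI of each group-level location, per condition,
#' plus the shared non-decision time and start point.
#'
#' @param object an `rlddm_fit`.
#' @param mass HDI mass (default 0.95).
#' @param ... unused.
#' @return data.frame with `parameter`, `condition`, `mean`, `hdi_lo`,
#'   `hdi_hi`.
#' @export
summary.rlddm_fit <- function(object, mass = 0.95, ...) {
  pnames <- dimnames(object$mu)[[2]]
  rows <- list()
  for (cc in object$conditions)
    for (p in pnames) {
      if (object$model$variant == "single" && p == "alpha_neg_raw") next
      dr <- object$mu[, p, cc]
      h <- hdi(dr, mass)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, condition = cc, mean = mean(dr),
        hdi_lo = h[1], hdi_hi = h[2])
    }
  for (p in c("mu_t", "mu_z_raw")) {
    dr <- object$shared_group[, p]
    h <- hdi(dr, mass)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = sub("^mu_", "", p), condition = "shared", mean = mean(dr),
      hdi_lo = h[1], hdi_hi = h[2])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.rlddm_fit <- function(x, ...) {
  cat(sprintf("Hierarchical RLDDM fit (%s learning rate, window = %s)\n",
              x$model$variant, x$model$window))
  cat(sprintf("  %d subjects, %d condition(s), %d datasets, %d trials\n",
              length(x$subjects), length(x$conditions), nrow(x$index),
              sum(x$index$n_trials)))
  cat(sprintf("  %d chains x %d draws (burn-in %d); max group R-hat %.3f\n",
              x$chains, x$draws, x$burn, max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' DIC from deviance draws
#'
#' `DIC = mean(D) + pD` with `pD = mean(D) - D(posterior mean)`. Non-finite
#' deviance draws are excluded (their count is reported via a message).
#'
#' @param deviance vector of deviance draws (`-2 log L`).
#' @param deviance_at_mean deviance evaluated at the posterior mean.
#' @return list with `dic`, `p_d`, `mean_deviance`, `deviance_at_mean`.
#' @export
dic_from_deviance <- function(deviance, deviance_at_mean) {
  bad <- !is.finite(deviance)
  if (any(bad)) {
    message(sum(bad), " non-finite deviance draws excluded")
    deviance <- deviance[!bad]
  }
  dbar <- mean(deviance)
  pd <- dbar - deviance_at_mean
  list(dic = dbar + pd, p_d = pd, mean_deviance = dbar,
       deviance_at_mean = deviance_at_mean)
}

#' Deviance Information Criterion of a fit
#'
#' Evaluates the deviance at the posterior means of the subject-level
#' parameters and combines it with the per-draw deviances; lower is better.
#'
#' @param fit an `rlddm_fit`.
#' @return list as in [dic_from_deviance()].
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "rlddm_fit"))
  est <- coef(fit)
  ll <- 0
  for (i in seq_len(nrow(fit$index))) {
    d <- fit$data[[i]]
    ll <- ll + .loglik_dataset_cpp(
      as.integer(d$choice == "A"), as.integer(d$outcome), as.numeric(d$dt_s),
      est$a[i], est$m[i], est$alpha_pos_raw[i], est$alpha_neg_raw[i],
      est$t[i], est$z[i], fit$model$q0[1], fit$model$q0[2])
  }
  dic_from_deviance(fit$deviance, -2 * ll)
}

#' Posterior contrast between two conditions
#'
#' Draw-wise difference of the group-level means of one parameter between
#' two conditions, summarised by its mean and 85%/95% highest density
#' intervals. The difference is called significant when the 95% HDI
#' excludes zero.
#'
#' @param fit an `rlddm_fit`.
#' @param parameter one of `"a"`, `"m"`, `"alpha_pos_raw"`,
#'   `"alpha_neg_raw"`.
#' @param cond_a,cond_b condition labels; the contrast is `cond_a - cond_b`.
#' @return list of class `rlddm_contrast` with `parameter`, `conditions`,
#'   `m_diff`, `hdi95`, `hdi85`, `significant`, `draws`.
#' @export
posterior_contrast <- function(fit, parameter, cond_a, cond_b) {
  stopifnot(inherits(fit, "rlddm_fit"))
  pnames <- dimnames(fit$mu)[[2]]
  if (!parameter %in% pnames) stop("unknown parameter: ", parameter, call. = FALSE)
  if (!all(c(cond_a, cond_b) %in% fit$conditions))
    stop("unknown condition label", call. = FALSE)
  dr <- fit$mu[, parameter, cond_a] - fit$mu[, parameter, cond_b]
  h95 <- hdi(dr, 0.95)
  h85 <- hdi(dr, 0.85)
  structure(list(parameter = parameter, conditions = c(cond_a, cond_b),
                 m_diff = mean(dr), hdi95 = h95, hdi85 = h85,
                 significant = h95[1] > 0 || h95[2] < 0, draws = dr),
            class = "rlddm_contrast")
}

#' @export
print.rlddm_contrast <- function(x, ...) {
  cat(sprintf("%s: %s - %s  M_diff = %.3f  95%% HDI [%.3f, %.3f]%s\n",
              x$parameter, x$conditions[1], x$conditions[2], x$m_diff,
              x$hdi95[1], x$hdi95[2], if (x$significant) " *" else ""))
  invisible(x)
}
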