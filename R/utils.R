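# Internal helpers shared across modules.

# Resolve a user-supplied seed: NULL draws one from the session RNG so that
# set.seed() upstream still governs reproducibility.
.resolve_seed <- function(seed) {
  if (is.null(seed)) return(sample.int(.Machine$integer.max, 1L))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer", call. = FALSE)
  as.integer(seed)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# session RNG is restored afterwards.  seed = NULL evaluates in place.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.assert_single_dataset <- function(trials) {
  if (length(unique(trials$subject)) > 1L || length(unique(trials$condition)) > 1L)
    stop("expected trials from a single subject and condition", call. = FALSE)
  if (is.unsorted(trials$trial, strictly = TRUE))
    stop("trials must be ordered by strictly increasing trial index", call. = FALSE)
  invisible(trials)
}

.trial_columns <- c("subject", "condition", "session", "trial",
                    "choice", "outcome", "dt_s", "omitted")

#' Highest density interval of a sample
#'
#' Narrowest interval containing a given posterior mass, computed from the
#' empirical distribution (assumes unimodality).
#'
#' @param x numeric vector of draws.
#' @param mass probability mass to cover (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.95) {
  stopifnot(is.numeric(x), length(x) > 1L, mass > 0, mass < 1)
  x <- sort(x[is.finite(x)])
  n <- length(x)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(x[1L], x[n]))
  widths <- x[(k + 1L):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Gelman-Rubin convergence diagnostic
#'
#' Split-chain potential scale reduction factor: each chain is halved, and
#' the between/within variance ratio computed across the resulting
#' sequences. Values near 1 indicate convergence.
#'
#' @param x numeric vector of draws (all chains concatenated).
#' @param chain integer vector identifying the chain of each draw.
#' @return the split R-hat value.
#' @export
gelman_rubin <- function(x, chain) {
  stopifnot(length(x) == length(chain))
  seqs <- list()
  for (ch in unique(chain)) {
    xc <- x[chain == ch]
    h <- floor(length(xc) / 2)
    if (h < 2L) return(NA_real_)
    seqs <- c(seqs, list(xc[1:h]), list(xc[(h + 1L):(2L * h)]))
  }
  m <- length(seqs)
  n <- min(lengths(seqs))
  seqs <- lapply(seqs, function(s) s[1:n])
  means <- vapply(seqs, mean, 0)
  vars <- vapply(seqs, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
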