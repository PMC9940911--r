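# Voxelwise connectivity analysis: R-maps, spatial-similarity prediction,
# permutation testing and stimulation-volume heat maps.

# Coerce a stack to a voxels x subjects matrix, remembering grid dims.
.stack_matrix <- function(maps) {
  d <- dim(maps)
  if (is.null(d) || length(d) != 4L)
    stop("`maps` must be a 4-D array (grid x subjects)", call. = FALSE)
  list(X = matrix(maps, ncol = d[4]), dims = d[1:3], n = d[4])
}

# Voxelwise Pearson correlations of a voxels x subjects matrix with one or
# more behaviour vectors (rows of B). Returns voxels x nrow(B).
.voxel_cor <- function(X, B) {
  Xc <- X - rowMeans(X)
  rn <- sqrt(rowSums(Xc^2))
  Bc <- B - rowMeans(B)
  bn <- sqrt(rowSums(Bc^2))
  R <- (Xc %*% t(Bc)) / outer(rn, bn)
  R[rn == 0, ] <- NA_real_
  R
}

#' Voxelwise R-map
#'
#' Pearson correlation, at every voxel, between the across-subject voxel
#' values and a behavioural regressor (e.g. the stimulation-induced change
#' in P(Explore)).
#'
#' @param maps 4-D voxel-map stack (grid x subjects).
#' @param behaviour per-subject regressor.
#' @param threshold optional `|r|` cut: sub-threshold voxels are zeroed
#'   (used for display; computation is unthresholded by default).
#' @return 3-D array of class `rmap` with correlation values in `[-1, 1]`
#'   (`NA` at zero-variance voxels); the threshold, if any, is recorded in
#'   `attr(, "threshold")`.
#' @export
voxelwise_rmap <- function(maps, behaviour, threshold = NULL) {
  st <- .stack_matrix(maps)
  if (length(behaviour) != st$n)
    stop("`behaviour` length must equal the number of subjects", call. = FALSE)
  if (sd(behaviour) == 0)
    stop("`behaviour` has zero variance", call. = FALSE)
  if (st$n < 3)
    warning("fewer than 3 subjects: voxelwise correlations are degenerate (+/-1)",
            call. = FALSE)
  r <- .voxel_cor(st$X, matrix(behaviour, nrow = 1))[, 1]
  if (!is.null(threshold)) r[!is.na(r) & abs(r) < threshold] <- 0
  out <- array(r, st$dims)
  attr(out, "threshold") <- threshold
  class(out) <- c("rmap", class(out))
  out
}

#' Spatial similarity between a map and an R-map
#'
#' Pearson correlation over the voxels where both maps are finite.
#'
#' @param map 3-D voxel map of one subject.
#' @param rmap a [voxelwise_rmap()] result (or any 3-D map).
#' @return scalar correlation.
#' @export
spatial_similarity <- function(map, rmap) {
  if (!identical(dim(map)[1:3], dim(rmap)[1:3]))
    stop("map and R-map are on different grids", call. = FALSE)
  ok <- is.finite(map) & is.finite(rmap)
  if (!any(ok)) stop("no jointly finite voxels", call. = FALSE)
  cor(as.numeric(map)[ok], as.numeric(rmap)[ok])
}

#' Predict behaviour from spatial similarity
#'
#' Simple linear regression of the behavioural values on the per-subject
#' spatial-similarity coefficients.
#'
#' @param similarities per-subject spatial correlations with the R-map.
#' @param behaviour per-subject behavioural values.
#' @return list with `r` (Pearson), `r2`, `p` (two-sided), `n`.
#' @export
predict_behaviour <- function(similarities, behaviour) {
  n <- length(behaviour)
  stopifnot(length(similarities) == n, n >= 3)
  if (sd(similarities) == 0 || sd(behaviour) == 0)
    stop("zero-variance input", call. = FALSE)
  ct <- cor.test(similarities, behaviour)
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = n)
}

# Per-subject spatial similarities for one behaviour vector. With
# loo = TRUE each subject is scored against the R-map rebuilt from the
# other subjects only (leave-one-out); loo = FALSE scores against the
# full-sample R-map, which is circular: at realistic voxel counts the
# similarity-behaviour correlation then approaches 1 for any regressor.
# The leave-one-out voxel correlations come from rank-1 downdates of the
# full-sample sums, vectorised over subjects.
.similarity_scores <- function(X, b, loo = TRUE) {
  n <- length(b)
  if (loo) {
    Sx <- rowSums(X); Sxx <- rowSums(X^2); Sxy <- as.vector(X %*% b)
    Sy <- sum(b); Syy <- sum(b^2)
    np <- n - 1
    Bs <- matrix(b, nrow(X), n, byrow = TRUE)
    Sx_ <- Sx - X; Sxx_ <- Sxx - X^2; Sxy_ <- Sxy - X * Bs
    Sy_ <- matrix(Sy - b, nrow(X), n, byrow = TRUE)
    Syy_ <- matrix(Syy - b^2, nrow(X), n, byrow = TRUE)
    num <- np * Sxy_ - Sx_ * Sy_
    den2 <- (np * Sxx_ - Sx_^2) * (np * Syy_ - Sy_^2)
    Rm <- num / sqrt(pmax(den2, 0))
    Rm[!is.finite(Rm)] <- 0
  } else {
    r <- .voxel_cor(X, matrix(b, nrow = 1))[, 1]
    r[!is.finite(r)] <- 0
    Rm <- matrix(r, nrow(X), n)
  }
  Xc <- X - matrix(colMeans(X), nrow(X), n, byrow = TRUE)
  Rc <- Rm - matrix(colMeans(Rm), nrow(Rm), n, byrow = TRUE)
  colSums(Xc * Rc) / sqrt(colSums(Xc^2) * colSums(Rc^2))
}

# Full pipeline for one behaviour vector: R-map -> similarities ->
# similarity-behaviour correlation.
.pipeline_r <- function(X, b, loo = TRUE) {
  cor(.similarity_scores(X, b, loo), b)
}

#' Per-subject spatial-similarity scores
#'
#' Scores each subject's map against the R-map of the remaining subjects
#' (leave-one-out, the default) or against the full-sample R-map. The
#' leave-one-out form is the one suitable for prediction: the full-sample
#' form correlates a subject's own behaviour into the reference map and is
#' strongly optimistic at realistic voxel counts.
#'
#' @param maps 4-D voxel-map stack.
#' @param behaviour per-subject regressor.
#' @param loo leave the scored subject out of the R-map (default TRUE).
#' @return numeric vector of per-subject similarities.
#' @export
rmap_similarity_scores <- function(maps, behaviour, loo = TRUE) {
  st <- .stack_matrix(maps)
  stopifnot(length(behaviour) == st$n)
  if (sd(behaviour) == 0) stop("`behaviour` has zero variance", call. = FALSE)
  .similarity_scores(st$X, behaviour, loo)
}

#' Permutation test of the R-map prediction
#'
#' Recomputes the *entire* pipeline — R-map construction, per-subject
#' spatial similarity, similarity-behaviour correlation — for the observed
#' behaviour and for `n_perm` random re-orderings, and reports the
#' add-one-smoothed two-sided permutation p-value (fraction of null `|R|`
#' at or above the observed `|R|`) together with the directional p.
#'
#' @param maps 4-D voxel-map stack.
#' @param behaviour per-subject regressor.
#' @param n_perm number of permutations (default 1000).
#' @param loo leave-one-out similarity scoring (default TRUE, see
#'   [rmap_similarity_scores()]).
#' @param seed integer seed or `NULL`.
#' @return list with `observed_r`, `p` (two-sided), `p_directional`,
#'   `null_r` (length `n_perm`), `n_perm`.
#' @export
permutation_test <- function(maps, behaviour, n_perm = 1000, loo = TRUE,
                             seed = NULL) {
  stopifnot(n_perm >= 1)
  st <- .stack_matrix(maps)
  if (sd(behaviour) == 0) stop("`behaviour` has zero variance", call. = FALSE)
  obs <- .pipeline_r(st$X, behaviour, loo)
  .with_seed(.resolve_seed(seed), {
    null_r <- vapply(seq_len(n_perm), function(i)
      .pipeline_r(st$X, sample(behaviour), loo), 0)
    list(observed_r = obs,
         p = (1 + sum(abs(null_r) >= abs(obs))) / (n_perm + 1),
         p_directional = (1 + sum(null_r >= obs)) / (n_perm + 1),
         null_r = null_r, n_perm = n_perm)
  })
}

#' Stimulation-volume heat map and region overlap
#'
#' Overlaps binary per-subject stimulation volumes into an n-map (each voxel
#' counts the subjects whose volume covers it) and scores named regions by
#' the weighted sum of n-map values inside each region mask.
#'
#' @param stim_volumes 4-D stack of binary stimulation volumes.
#' @param region_masks named list of 3-D region images (probabilistic maps
#'   are binarised at `prob_threshold`).
#' @param prob_threshold binarisation threshold for the region masks
#'   (default 0.5).
#' @return list with `n_map` (3-D integer array) and `overlap` (named
#'   numeric, one weighted-overlap score per region).
#' @export
heatmap_overlap <- function(stim_volumes, region_masks, prob_threshold = 0.5) {
  st <- .stack_matrix(stim_volumes)
  if (!all(st$X %in% c(0, 1)))
    stop("stimulation volumes must be binary", call. = FALSE)
  n_map <- array(rowSums(st$X), st$dims)
  overlap <- vapply(region_masks, function(msk) {
    if (!identical(dim(msk)[1:3], st$dims))
      stop("region mask grid does not match the stimulation volumes; resample first",
           call. = FALSE)
    sum(n_map[as.vector(msk) >= prob_threshold])
  }, 0)
  list(n_map = n_map, overlap = overlap)
}
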