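#' Synthesise a voxel-map cohort with a planted behaviour correlation
#'
#' Builds per-subject 3-D voxel maps (emulating stimulation-volume
#' seed-connectivity maps) together with a behavioural vector (emulating the
#' stimulation-induced change in exploration). Inside `effect_mask` the
#' voxel values correlate with the behaviour at approximately
#' `effect_size`; everywhere else they are pure noise.
#'
#' @param n_subjects number of subjects.
#' @param grid_dims 3-D grid extents (default `c(12, 12, 12)`).
#' @param effect_mask logical array of dimension `grid_dims` marking the
#'   voxels carrying the planted effect (default: central 4x4x4 block).
#' @param effect_size target voxelwise correlation, `|effect_size| <= 1`.
#' @param noise_sd standard deviation of the voxel noise (> 0).
#' @param behaviour optional behaviour vector (length `n_subjects`); by
#'   default drawn as `N(behaviour_mean, behaviour_sd)`.
#' @param behaviour_mean,behaviour_sd location/spread of the default
#'   behaviour draw.
#' @param seed integer seed or `NULL`.
#' @return list with `maps` (4-D array `grid_dims x n_subjects`),
#'   `behaviour`, `mask`.
#' @export
synth_voxel_cohort <- function(n_subjects, grid_dims = c(12, 12, 12),
                               effect_mask = NULL, effect_size = 0.6,
                               noise_sd = 1, behaviour = NULL,
                               behaviour_mean = 0.15, behaviour_sd = 0.1,
                               seed = NULL) {
  stopifnot(n_subjects >= 2, length(grid_dims) == 3, noise_sd > 0)
  if (abs(effect_size) > 1)
    stop("`effect_size` must lie in [-1, 1]", call. = FALSE)
  if (is.null(effect_mask)) {
    effect_mask <- array(FALSE, grid_dims)
    ctr <- lapply(grid_dims, function(d) {
      lo <- max(1L, floor(d / 2) - 1L); lo:min(d, lo + 3L)
    })
    effect_mask[ctr[[1]], ctr[[2]], ctr[[3]]] <- TRUE
  }
  if (!identical(dim(effect_mask), as.integer(grid_dims)))
    stop("`effect_mask` dimensions must match `grid_dims`", call. = FALSE)
  if (!any(effect_mask) && effect_size != 0)
    stop("empty `effect_mask` with non-zero `effect_size`", call. = FALSE)
  .with_seed(.resolve_seed(seed), {
    if (is.null(behaviour))
      behaviour <- rnorm(n_subjects, behaviour_mean, behaviour_sd)
    stopifnot(length(behaviour) == n_subjects)
    zb <- as.numeric(scale(behaviour))
    V <- prod(grid_dims)
    X <- matrix(rnorm(V * n_subjects, 0, noise_sd), nrow = V)
    idx <- which(as.vector(effect_mask))
    if (length(idx) && effect_size != 0) {
      eps <- X[idx, , drop = FALSE]
      X[idx, ] <- noise_sd * effect_size * matrix(zb, length(idx), n_subjects,
                                                  byrow = TRUE) +
        sqrt(1 - effect_size^2) * eps
    }
    list(maps = array(X, c(grid_dims, n_subjects)),
         behaviour = behaviour, mask = effect_mask)
  })
}

#' Write a voxel-map stack as NIfTI
#'
#' Stores an `x y z subject` array as a 4-D NIfTI volume.
#'
#' @param maps 4-D array (3-D grid x subjects) or 3-D array.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param voxel_size isotropic voxel edge in mm (default 0.5).
#' @return the path, invisibly.
#' @export
write_voxel_stack <- function(maps, path, voxel_size = 0.5) {
  img <- RNifti::asNifti(maps, pixdim = rep(voxel_size, min(3L, length(dim(maps)))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a voxel-map stack from NIfTI
#'
#' @param path NIfTI file path.
#' @return plain array (3-D or 4-D) with voxel dimensions in
#'   `attr(, "voxel_size")`.
#' @export
read_voxel_stack <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)
  out
}
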