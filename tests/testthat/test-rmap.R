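test_that("R-maps recover planted signal and reject degenerate regressors", {
  syn <- synth_voxel_cohort(16, c(8, 8, 8), effect_size = 0.8, seed = 81)
  r <- voxelwise_rmap(syn$maps, syn$behaviour)
  expect_true(all(abs(r[is.finite(r)]) <= 1))
  expect_gt(mean(abs(r[syn$mask])), mean(abs(r[!syn$mask])))
  # permuted behaviour: null centred at zero
  set.seed(82)
  r0 <- voxelwise_rmap(syn$maps, sample(syn$behaviour))
  expect_lt(abs(mean(r0)), 0.05)
  expect_error(voxelwise_rmap(syn$maps, rep(1, 16)), "variance")
  # thresholding zeroes sub-threshold voxels only
  rt <- voxelwise_rmap(syn$maps, syn$behaviour, threshold = 0.5)
  expect_true(all(rt[abs(r) < 0.5] == 0))
  expect_identical(rt[abs(r) >= 0.5], r[abs(r) >= 0.5])
})

test_that("spatial similarity behaves like a correlation", {
  syn <- synth_voxel_cohort(10, c(6, 6, 6), effect_size = 0.5, seed = 83)
  r <- voxelwise_rmap(syn$maps, syn$behaviour)
  expect_equal(spatial_similarity(unclass(r), r), 1)
  expect_equal(spatial_similarity(-unclass(r), r), -1)
  set.seed(84)
  null_sims <- vapply(1:200, function(i)
    spatial_similarity(array(rnorm(216), c(6, 6, 6)), r), 0)
  expect_lt(abs(mean(null_sims)), 0.02)
  expect_error(spatial_similarity(array(1, c(5, 5, 5)), r), "grids")
})

test_that("behaviour prediction from similarity reduces to a simple regression", {
  set.seed(85)
  b <- rnorm(14)
  expect_equal(predict_behaviour(2 * b + 1, b)$r2, 1, tolerance = 1e-12)
  z <- as.numeric(scale(b))
  pr <- predict_behaviour(z, b)
  expect_equal(pr$r2, cor(z, b)^2, tolerance = 1e-12)
  expect_error(predict_behaviour(rep(1, 14), b), "variance")
})

test_that("similarity scores match naive per-subject oracles, in-sample and leave-one-out", {
  syn <- synth_voxel_cohort(8, c(5, 5, 5), effect_size = 0.6, seed = 89)
  # in-sample: identical to scoring each map against the full R-map
  full <- voxelwise_rmap(syn$maps, syn$behaviour)
  naive_in <- apply(syn$maps, 4, spatial_similarity, rmap = full)
  expect_equal(rmap_similarity_scores(syn$maps, syn$behaviour, loo = FALSE),
               unname(naive_in), tolerance = 1e-10)
  # leave-one-out: each map scored against the R-map of the others
  naive_loo <- vapply(1:8, function(s) {
    r_s <- voxelwise_rmap(syn$maps[, , , -s, drop = FALSE], syn$behaviour[-s])
    spatial_similarity(syn$maps[, , , s], r_s)
  }, 0)
  expect_equal(rmap_similarity_scores(syn$maps, syn$behaviour, loo = TRUE),
               naive_loo, tolerance = 1e-10)
})

test_that("the permutation test recomputes the pipeline and is affine-invariant", {
  syn <- synth_voxel_cohort(14, c(6, 6, 6), effect_size = 0.9, noise_sd = 0.5,
                            seed = 86)
  pt <- permutation_test(syn$maps, syn$behaviour, n_perm = 199, seed = 87)
  expect_length(pt$null_r, 199)
  expect_true(pt$p > 0 && pt$p <= 1)
  expect_lt(pt$p, 0.05)             # strong planted effect
  expect_gt(pt$observed_r, 0.5)
  # common affine rescaling of the behaviour changes nothing
  pt2 <- permutation_test(syn$maps, 10 * syn$behaviour + 3, n_perm = 199, seed = 87)
  expect_equal(pt2$observed_r, pt$observed_r, tolerance = 1e-10)
  expect_equal(pt2$p, pt$p)
  # the circular in-sample variant is optimistic about the observed R
  pt_in <- permutation_test(syn$maps, syn$behaviour, n_perm = 19, loo = FALSE,
                            seed = 87)
  expect_gte(pt_in$observed_r, pt$observed_r - 1e-9)
})

test_that("stimulation-volume heat maps count coverage and score regions additively", {
  dims <- c(6, 6, 6)
  vol <- array(0, dims); vol[2:3, 2:3, 2:3] <- 1
  region <- array(0, dims); region[1:4, 1:4, 1:4] <- 0.7  # probabilistic mask
  far <- array(0, dims); far[6, 6, 6] <- 1
  one <- array(vol, c(dims, 1))
  hm1 <- heatmap_overlap(one, list(near = region, far = far))
  expect_equal(unname(hm1$overlap["near"]), sum(vol))  # fully inside
  expect_equal(unname(hm1$overlap["far"]), 0)          # disjoint
  two <- array(c(vol, vol), c(dims, 2))
  hm2 <- heatmap_overlap(two, list(near = region))
  expect_equal(unname(hm2$overlap["near"]), 2 * sum(vol))
  expect_equal(max(hm2$n_map), 2)
  expect_lte(max(hm2$n_map), dim(two)[4])
  # sub-threshold probabilistic mask contributes nothing
  weak <- region * 0.5  # 0.35 < 0.5
  expect_equal(unname(heatmap_overlap(one, list(w = weak))$overlap["w"]), 0)
  bad <- array(0.7, c(5, 5, 5))
  expect_error(heatmap_overlap(one, list(b = bad)), "resample")
  expect_error(heatmap_overlap(one * 2, list(near = region)), "binary")
})

test_that("voxel stacks round-trip through NIfTI", {
  syn <- synth_voxel_cohort(4, c(5, 5, 5), effect_size = 0.3, seed = 88)
  path <- tempfile(fileext = ".nii.gz")
  write_voxel_stack(syn$maps, path)
  back <- read_voxel_stack(path)
  expect_equal(dim(back), dim(syn$maps))
  expect_equal(as.vector(back), as.vector(syn$maps), tolerance = 1e-6)
  unlink(path)
})
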