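test_that("tracer generator is deterministic and shaped to spec", {
  spec <- tracer_sim_spec(10, 30, 3, separation = 5, noise_sd = 1,
                          rng_seed = 11)
  a <- generate_tracer_matrix(spec)
  b <- generate_tracer_matrix(spec)
  expect_identical(a$connectome$strengths, b$connectome$strengths)
  expect_equal(dim(a$connectome$strengths), c(10, 30))
  expect_length(a$truth$cluster_labels, 30)
  expect_setequal(unique(a$truth$cluster_labels), 1:3)
  # contiguous blocks: cluster blobs are disconnected boxes in the layout
  expect_equal(nrow(a$connectome$voxel_coordinates), 30)
})

test_that("invalid tracer specs name the offending field", {
  expect_error(tracer_sim_spec(10, 2, 3), "n_voxels")
  expect_error(tracer_sim_spec(10, 30, 3, separation = -1), "separation")
  expect_error(tracer_sim_spec(10, 30, 3, noise_sd = -0.1), "noise_sd")
  expect_error(tracer_sim_spec(0, 30, 3), "n_injections")
})

test_that("noiseless planted clusters are recovered exactly", {
  tr <- generate_tracer_matrix(tracer_sim_spec(12, 60, 3, separation = 3,
                                               noise_sd = 0, rng_seed = 2))
  sim <- fingerprint_similarity_matrix(zscore_connectome(tr$connectome))
  p <- hierarchical_parcellation(sim, 2:6)
  expect_equal(p$k, 3)
  expect_equal(adjusted_rand_index(p$labels, tr$truth$cluster_labels), 1)
})

test_that("separation 0 gives chance-level recovery (permutation oracle)", {
  tr <- generate_tracer_matrix(tracer_sim_spec(20, 90, 3, separation = 0,
                                               noise_sd = 1, rng_seed = 3))
  sim <- fingerprint_similarity_matrix(zscore_connectome(tr$connectome))
  p <- hierarchical_parcellation(sim, 2:5)
  ari <- adjusted_rand_index(cutree(p$linkage_record, 3),
                             tr$truth$cluster_labels)
  # oracle: the null spread of ARI between random relabellings of the same
  # partition sizes
  set.seed(1)
  null <- replicate(200, adjusted_rand_index(
    sample(tr$truth$cluster_labels), tr$truth$cluster_labels))
  expect_lt(abs(ari), max(abs(null)) + 0.05)
  expect_lt(abs(mean(null)), 0.02)
})

test_that("species generator obeys the closed-form correlation", {
  W <- rbind(seed1 = c(1, 1, 0, 0), seed2 = c(0, 0, 1, 0))
  spec <- species_sim_spec(2, 10000, 1, paste0("t", 1:4), W,
                           voxel_labels = c("seed1", "seed2"),
                           noise_sd = 0, rng_seed = 5)
  ds <- generate_species_dataset(spec)
  vx <- ds$subjects[[1]]$voxels$values
  tg <- ds$subjects[[1]]$targets$values
  r <- cor(vx[, 1], tg)
  # w = (1,1,0,0), noise 0 -> r = 1/sqrt(2) with each loaded target
  expect_equal(as.numeric(r[1:2]), rep(1 / sqrt(2), 2), tolerance = 0.02)
  expect_equal(as.numeric(abs(r[3:4])), c(0, 0), tolerance = 0.05)
  # single target, w = 1, noise 0 -> r = 1
  expect_equal(cor(vx[, 2], tg[, 3]), 1, tolerance = 1e-12)
})

test_that("species generator converges to expectation with noise", {
  W <- rbind(seed1 = c(2, 1, 0))
  spec <- species_sim_spec(1, 10000, 1, paste0("t", 1:3), W,
                           voxel_labels = "seed1", noise_sd = 1, rng_seed = 6)
  ds <- generate_species_dataset(spec)
  r <- cor(ds$subjects[[1]]$voxels$values[, 1],
           ds$subjects[[1]]$targets$values)
  expected <- c(2, 1, 0) / sqrt(4 + 1 + 1)
  expect_equal(as.numeric(r), expected, tolerance = 0.02)
})

test_that("unique voxels are orthogonal to every seed in target space", {
  W <- rbind(seed1 = c(1, 0, 0, 1), seed2 = c(0, 1, 1, 0))
  spec <- species_sim_spec(1, 100, 1, paste0("t", 1:4), W,
                           voxel_labels = c("seed1", "unique"),
                           noise_sd = 0.5, rng_seed = 7)
  ds <- generate_species_dataset(spec)
  u <- ds$truth$unique_loading
  expect_equal(as.numeric(W %*% u), c(0, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(u^2)), mean(sqrt(rowSums(W^2))), tolerance = 1e-12)
})

test_that("species generator validates its inputs", {
  W <- rbind(seed1 = c(1, 0))
  expect_error(species_sim_spec(2, 100, 1, paste0("t", 1:3), W, "seed1"),
               "length")
  expect_error(species_sim_spec(2, 100, 1, paste0("t", 1:2), W, "seedX"),
               "seedX")
  expect_error(species_sim_spec(2, 5, 1, paste0("t", 1:2), W, "seed1"),
               "n_timepoints")
})

test_that("species generator is deterministic given the seed", {
  W <- rbind(seed1 = c(1, 0, 1))
  spec <- species_sim_spec(3, 50, 1, paste0("t", 1:3), W,
                           voxel_labels = c("seed1", "unique"), rng_seed = 9)
  a <- generate_species_dataset(spec)
  b <- generate_species_dataset(spec)
  expect_identical(a$subjects[[3]]$voxels$values, b$subjects[[3]]$voxels$values)
})

test_that("probabilistic atlas bumps behave as constructed", {
  atl <- generate_prob_atlas(2, c(7, 7, 5),
                             peak_locations = rbind(c(2, 3, 2), c(6, 6, 4)),
                             spread = 1.5)
  expect_true(all(atl$prob >= 0 & atl$prob <= 1))
  p1 <- atl$prob[, , , 1]
  expect_equal(which(p1 == max(p1), arr.ind = TRUE)[1, ],
               c(dim1 = 2, dim2 = 3, dim3 = 2))
  uni <- generate_prob_atlas(1, c(4, 4, 4), uniform = TRUE)
  expect_equal(length(unique(as.vector(uni$prob))), 1L)
  expect_identical(generate_prob_atlas(3, c(5, 5, 5), rng_seed = 4)$prob,
                   generate_prob_atlas(3, c(5, 5, 5), rng_seed = 4)$prob)
  expect_error(generate_prob_atlas(0, c(4, 4, 4)), "n_areas")
  expect_error(generate_prob_atlas(1, c(4, 4, 4),
                                   peak_locations = rbind(c(9, 1, 1))),
               "inside the grid")
})

test_that("within-cluster profile correlation exceeds between-cluster", {
  tr <- generate_tracer_matrix(tracer_sim_spec(30, 60, 3, separation = 2,
                                               noise_sd = 0.2, rng_seed = 13))
  sim <- fingerprint_similarity_matrix(zscore_connectome(tr$connectome))
  lab <- tr$truth$cluster_labels
  same <- outer(lab, lab, `==`) & upper.tri(sim)
  diff <- outer(lab, lab, `!=`) & upper.tri(sim)
  expect_gt(min(sim[same]), max(sim[diff]))
})
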