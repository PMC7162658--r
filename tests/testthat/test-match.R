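test_that("TFCE matches its closed forms", {
  v <- array(0, c(7, 7, 7)); v[4, 4, 4] <- 3
  # isolated voxel: integral of 1^E h^H dh from 0 to 3 = 3^3/3 = 9
  expect_equal(tfce_enhance(v, E = 0.5, H = 2, dh = 0.01)[4, 4, 4], 9,
               tolerance = 0.01 * 9)
  v2 <- array(0, c(7, 7, 7)); v2[3:4, 4, 4] <- 3
  # two-voxel plateau: sqrt(2) * h^3 / 3 at each voxel
  expect_equal(tfce_enhance(v2, E = 0.5, H = 2, dh = 0.01)[3, 4, 4],
               sqrt(2) * 27 / 3, tolerance = 0.01 * sqrt(2) * 9)
  expect_equal(tfce_enhance(array(0, c(3, 3, 3))), array(0, c(3, 3, 3)))
  expect_error(tfce_enhance(matrix(1, 2, 2)), "3D")
  expect_error(tfce_enhance(v, connectivity = 10), "connectivity")
})

test_that("TFCE agrees with the per-threshold component oracle", {
  skip_if_not_installed("igraph")
  set.seed(71)
  for (rep in 1:6) {
    v <- array(rnorm(125), c(5, 5, 5))
    for (conn in c(6L, 26L)) {
      got <- tfce_enhance(v, dh = max(abs(v)) / 25, connectivity = conn)
      want <- tfce_oracle(v, dh = max(abs(v)) / 25, connectivity = conn)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("TFCE is monotone under positive scaling", {
  set.seed(72)
  v <- array(pmax(rnorm(240), 0), c(8, 6, 5))
  base <- tfce_enhance(v, dh = 0.02)
  for (c_ in c(1.5, 3)) {
    up <- tfce_enhance(c_ * v, dh = 0.02)
    expect_true(all(up - base >= -1e-9))
  }
})

test_that("similarity maps are fingerprint correlations in z", {
  set.seed(73)
  tplv <- runif(12, -0.4, 0.6)
  tpl <- structure(list(values = tplv, target_labels = paste0("t", 1:12),
                        scale = "r"), class = "template_fingerprint")
  grid <- list(dim = c(4L, 1L, 1L), coords = cbind(1:4, 1L, 1L))
  M <- rbind(0.5 * tplv + 0.1,   # positive affine -> r = 1
             -tplv,              # negation -> z < 0
             runif(12), rep(0.3, 12))
  expect_warning(sm <- voxelwise_similarity_map(list(M), tpl, grid),
                 "constant")
  expect_gt(sm$z[1, 1], fisher_z(0.999))
  expect_lt(sm$z[1, 2], 0)
  expect_equal(sm$z[1, 4], 0)  # constant fingerprint -> 0
  # null: i.i.d. fingerprints, 12 targets -> sd(z) ~ 1/sqrt(12 - 3)
  nsim <- 4000
  Mn <- matrix(rnorm(nsim * 12), nsim, 12)
  smn <- voxelwise_similarity_map(list(Mn), tpl,
                                  list(dim = c(nsim, 1L, 1L),
                                       coords = cbind(1:nsim, 1L, 1L)))
  expect_lt(abs(mean(smn$z)), 0.02)
  expect_equal(sd(as.vector(smn$z)), 1 / 3, tolerance = 0.05)
})

test_that("group inference: exact enumeration, caps, and p floor", {
  grid <- list(dim = c(4L, 4L, 2L), mask_idx = 1:32)
  set.seed(74)
  maps <- matrix(rnorm(6 * 32, 0, 0.5), 6, 32)
  maps[, 1:8] <- maps[, 1:8] + 3
  sm <- group_onesample_tfce(maps, grid, rng_seed = 1)
  expect_true(sm$exact)
  expect_equal(sm$n_permutations, 64L)
  expect_true(all(sm$p_corrected >= 1 / 64))
  expect_true(all(sm$p_corrected[1:8] < 0.05))
  expect_true(all(sm$p_corrected > 0 & sm$p_corrected <= 1))
  # identical maps with constant nonzero region: t capped, region significant
  m1 <- c(rep(2, 8), rep(0, 24))
  maps2 <- rbind(m1, m1, m1, m1, m1, m1, m1, m1)
  sm2 <- group_onesample_tfce(maps2, grid, rng_seed = 2)
  expect_equal(max(sm2$t), 50)
  expect_true(all(sm2$p_corrected[1:8] < 0.05))
  expect_error(group_onesample_tfce(maps[1, , drop = FALSE], grid), "subjects")
})

test_that("sign-flip inference is invariant to subject relabelling", {
  grid <- list(dim = c(4L, 2L, 2L), mask_idx = 1:16)
  set.seed(75)
  maps <- matrix(rnorm(8 * 16), 8, 16) + 0.8
  a <- group_onesample_tfce(maps, grid, rng_seed = 3)
  b <- group_onesample_tfce(maps[sample(8), ], grid, rng_seed = 3)
  expect_equal(a$t, b$t)
  expect_equal(a$p_corrected, b$p_corrected)  # exact: order-free null
})

test_that("planted-block power at n = 20", {
  # planted positive effect in block B, noise elsewhere; effect/noise = 1
  grid <- list(dim = c(8L, 8L, 4L), mask_idx = 1:256)
  block <- 1:32
  hits <- vapply(1:10, function(r) {
    set.seed(200 + r)
    maps <- matrix(rnorm(20 * 256), 20, 256)
    maps[, block] <- 1
    sm <- group_onesample_tfce(maps, grid, n_perm = 300L, rng_seed = r)
    all(sm$p_corrected[block] < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("classification keeps multi-membership and flags unassigned", {
  grid <- list(dim = c(3L, 1L, 1L), mask_idx = 1:3)
  mk <- function(p) structure(list(p_corrected = p, grid = grid,
                                   t = rep(1, 3)), class = "stat_map")
  am <- classify_voxels(list(a = mk(c(0.01, 0.2, 0.9)),
                             b = mk(c(0.5, 0.02, 0.9)),
                             c = mk(c(0.9, 0.01, 0.9))), alpha = 0.05)
  expect_equal(unname(am$assigned[1, ]), c(TRUE, FALSE, FALSE))
  expect_equal(unname(am$assigned[2, ]), c(FALSE, TRUE, TRUE))  # overlap kept
  expect_true(am$unassigned[3])
  expect_equal(am$argmax[1], 1L)
  expect_true(is.na(am$argmax[3]))
})

test_that("conjunction is the intersection of its contrasts", {
  grid <- list(dim = c(6L, 2L, 2L), mask_idx = 1:24)
  set.seed(76)
  n <- 10
  U <- matrix(rnorm(n * 24, 0, 0.5), n, 24)
  U[, 1:6] <- U[, 1:6] + 2           # unassigned evidence high in block
  A1 <- matrix(rnorm(n * 24, 0, 0.5), n, 24)
  A2 <- matrix(rnorm(n * 24, 0, 0.5), n, 24)
  res <- conjunction_difference(U, list(t1 = A1, t2 = A2), grid,
                                n_perm = 200, rng_seed = 5)
  expect_true(all(res$conjunction == (res$masks[, 1] & res$masks[, 2])))
  expect_true(all(which(res$conjunction) %in% 1:6) || !any(res$conjunction))
  # unassigned identical to one template -> that contrast (and so the
  # conjunction) is empty
  res2 <- conjunction_difference(U, list(t1 = U, t2 = A2), grid,
                                 n_perm = 100, rng_seed = 6)
  expect_false(any(res2$conjunction))
  expect_error(conjunction_difference(U, list(t1 = A1[1:3, ]), grid),
               "unpaired")
})

test_that("weighted timeseries normalises positive t", {
  X <- cbind(a = 1:5, b = 11:15, c = 21:25)
  expect_equal(weighted_timeseries(c(-1, 0, 2), X), X[, 3])
  expect_equal(weighted_timeseries(c(1, 3, 0), X),
               as.vector(X %*% c(0.25, 0.75, 0)))
  expect_error(weighted_timeseries(c(-1, -2, 0), X), "positive")
})

test_that("whole-brain map finds a planted block and validates input", {
  set.seed(77)
  n <- 12; V <- 4 * 4 * 3
  grid <- list(dim = c(4L, 4L, 3L), mask_idx = seq_len(V))
  n_time <- 200
  seeds <- lapply(1:n, function(i) rnorm(n_time))
  brain <- lapply(1:n, function(i) {
    B <- matrix(rnorm(n_time * V), n_time, V)
    B[, 1:8] <- B[, 1:8] + seeds[[i]]  # connected block follows the seed
    B
  })
  res <- wholebrain_connectivity_map(seeds, brain, grid, n_perm = 200,
                                     rng_seed = 7)
  expect_true(all(res$significant[1:8]))
  expect_true(any(res$cluster_table$significant))
  expect_error(wholebrain_connectivity_map(seeds, brain, grid, voxel_p = 1),
               "voxel_p")
  expect_error(wholebrain_connectivity_map(seeds[1], brain[1], grid),
               "subjects")
})

test_that("component labelling matches igraph on random masks", {
  skip_if_not_installed("igraph")
  set.seed(78)
  for (rep in 1:4) {
    m <- array(runif(150) < 0.4, c(5, 6, 5))
    lab <- label_components(m, 6L)
    expect_equal(sort(unique(lab[m])), seq_len(max(lab)))
    expect_true(all(lab[!m] == 0))
    # same partition as the oracle's components at one threshold
    v <- array(0, dim(m)); v[m] <- 1
    oracle <- tfce_oracle(v, E = 1, H = 0, dh = 1, connectivity = 6L)
    # oracle value at h=1 equals component size; check sizes agree per voxel
    sizes <- tabulate(lab)[lab[m]]
    expect_equal(sizes, oracle[m] / 1)
  }
})
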