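test_that("fisher transform is the arctanh with clipping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_warning(z <- fisher_z(1), "clipped")
  expect_equal(z, atanh(1 - 1e-7))
})

test_that("fingerprints are seed-target correlations", {
  set.seed(61)
  n <- 10000
  t1 <- rnorm(n); t2 <- rnorm(n); t3 <- rnorm(n)
  targets <- region_ts(cbind(t1 = t1, t2 = t2, t3 = t3), 1)
  # seed = t1 + t2 -> r ~ 1/sqrt(2) with each loaded target
  fp <- compute_fingerprint(t1 + t2, targets)
  expect_equal(fp$values[1:2], rep(1 / sqrt(2), 2), tolerance = 0.02)
  expect_lt(abs(fp$values[3]), 0.05)  # null sd = 1/sqrt(n)
  # target identical to seed -> r = 1 (clipped on the r scale)
  fp1 <- compute_fingerprint(t1, targets)
  expect_equal(fp1$values[1], 1, tolerance = 1e-10)
  expect_warning(compute_fingerprint(t1, targets, scale = "fisher_z"),
                 "clipped")
  expect_error(compute_fingerprint(rep(1, n), targets), "constant")
  expect_error(compute_fingerprint(t1, region_ts(cbind(a = rnorm(n),
                                                       b = rep(2, n)), 1)),
               "b")
})

test_that("robust mean template trims outliers (sort-and-trim oracle)", {
  M <- matrix(0.2, 20, 3)
  M[20, 2] <- 5.0
  tpl <- robust_mean_template(fps_from_matrix(M, scale = "fisher_z"))
  expect_equal(tpl$values, c(0.2, 0.2, 0.2), ignore_attr = TRUE)
  # oracle: explicit sort and trim of 20% each side
  x <- rnorm(20)
  M2 <- cbind(x, x)
  tpl2 <- robust_mean_template(fps_from_matrix(M2, scale = "fisher_z"))
  kept <- sort(x)[5:16]
  expect_equal(tpl2$values[1], mean(kept))
  expect_equal(tpl2$dispersion[1], sd(kept) / sqrt(12))
  # n = 1: the fingerprint itself, dispersion 0
  tpl3 <- robust_mean_template(
    fps_from_matrix(M2[1, , drop = FALSE], scale = "fisher_z"))
  expect_equal(tpl3$values, M2[1, ], ignore_attr = TRUE)
  expect_equal(tpl3$dispersion, c(0, 0), ignore_attr = TRUE)
  # identical subjects -> that fingerprint
  tpl4 <- robust_mean_template(fps_from_matrix(matrix(0.4, 7, 2)))
  expect_equal(tpl4$values, c(0.4, 0.4), ignore_attr = TRUE)
})

test_that("template is invariant to subject order and checks targets", {
  set.seed(62)
  M <- matrix(runif(15, -0.5, 0.5), 5, 3)
  fps <- fps_from_matrix(M)
  expect_equal(robust_mean_template(fps)$values,
               robust_mean_template(rev(fps))$values)
  bad <- fps
  bad[[2]]$target_labels <- c("x", "y", "z")
  expect_error(robust_mean_template(bad), "target order")
})

test_that("manhattan distance is the hand sum and a metric", {
  a <- fingerprint(c(0.1, 0.2), c("t1", "t2"))
  b <- fingerprint(c(0.3, 0.0), c("t1", "t2"))
  expect_equal(manhattan_distance(a, b), 0.4)
  expect_equal(manhattan_distance(a, a), 0)
  set.seed(63)
  for (i in 1:20) {
    x <- fingerprint(runif(4, -1, 1) * 0.9, paste0("t", 1:4))
    y <- fingerprint(runif(4, -1, 1) * 0.9, paste0("t", 1:4))
    z <- fingerprint(runif(4, -1, 1) * 0.9, paste0("t", 1:4))
    dxy <- manhattan_distance(x, y)
    expect_gte(dxy, 0)
    expect_equal(dxy, manhattan_distance(y, x))
    expect_lte(manhattan_distance(x, z), dxy + manhattan_distance(y, z) + 1e-12)
  }
  expect_error(manhattan_distance(a, fingerprint(0.1, "t1")), "mismatch")
})

test_that("distance test: floor, identity, and null C++/R agreement", {
  set.seed(64)
  A <- matrix(rnorm(20 * 3, 0, 0.1), 20, 3)
  fpsA <- fps_from_matrix(A, scale = "fisher_z")
  # A vs itself: observed 0, p = 1
  res0 <- fingerprint_distance_test(fpsA, fpsA, n_perm = 99)
  expect_equal(res0$observed_distance, 0)
  expect_equal(res0$p_value, 1)
  # disjoint supports: minimum attainable p = 1/(n_perm + 1)
  B <- A + 10
  res1 <- fingerprint_distance_test(fpsA, fps_from_matrix(B, scale = "fisher_z"), n_perm = 999,
                                    rng_seed = 7)
  expect_equal(res1$p_value, 1 / 1000)
  expect_error(fingerprint_distance_test(fpsA, fps_from_matrix(B, scale = "fisher_z"),
                                         n_perm = 0), "n_perm")
  expect_error(fingerprint_distance_test(fpsA[1],
                                         fps_from_matrix(B, scale = "fisher_z")[1]),
               "subjects")
  # the C++ permutation statistic equals the R template-distance statistic
  set.seed(99)
  null1 <- fingermatch:::.dist_perm_null_cpp(A, B, 5L, 0.2)
  set.seed(99)
  null2 <- vapply(1:5, function(p) {
    flip <- runif(20) < 0.5
    A2 <- A; B2 <- B
    A2[flip, ] <- B[flip, ]; B2[flip, ] <- A[flip, ]
    manhattan_distance(
      robust_mean_template(fps_from_matrix(A2, scale = "fisher_z")),
      robust_mean_template(fps_from_matrix(B2, scale = "fisher_z")))
  }, numeric(1))
  expect_equal(as.numeric(null1), null2, tolerance = 1e-12)
})

test_that("rejection rate rises with planted separation", {
  set.seed(65)
  rej <- vapply(c(0, 0.4, 1.2), function(delta) {
    mean(vapply(1:40, function(r) {
      A <- matrix(rnorm(8 * 4, 0.2, 0.15), 8, 4)
      B <- matrix(rnorm(8 * 4, 0.2, 0.15), 8, 4) + delta / 4
      fingerprint_distance_test(fps_from_matrix(A, scale = "fisher_z"),
                                fps_from_matrix(B, scale = "fisher_z"),
                                n_perm = 199,
                                rng_seed = r + delta * 1000)$p_value < 0.05
    }, logical(1)))
  }, numeric(1))
  expect_lte(rej[1], rej[2] + 0.1)
  expect_lte(rej[2], rej[3] + 0.1)
  expect_gt(rej[3], rej[1])
  expect_gt(rej[3], 0.8)
})

test_that("long-format export carries all fields", {
  fps <- fps_from_matrix(matrix(c(0.1, 0.2), 1, 2))
  df <- fingerprints_to_df(fps, seed = "seedA")
  expect_equal(df$value, c(0.1, 0.2))
  expect_equal(df$seed, rep("seedA", 2))
  expect_equal(df$target, c("t1", "t2"))
})
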