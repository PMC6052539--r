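test_that("centroid_size matches its definition", {
  sq <- matrix(c(-0.5, 0.5, 0.5, -0.5, -0.5, -0.5, 0.5, 0.5), ncol = 2)
  expect_equal(centroid_size(sq), sqrt(2))

  set.seed(1)
  m <- matrix(rnorm(36), ncol = 2)
  expect_equal(centroid_size(3.7 * m), 3.7 * centroid_size(m))
  ## brute-force formula
  ctr <- colMeans(m)
  expect_equal(centroid_size(m),
               sqrt(sum((m[, 1] - ctr[1])^2 + (m[, 2] - ctr[2])^2)))
  expect_error(centroid_size(matrix(1, 5, 2)), "degenerate")
})

test_that("align_gpa removes nuisance rotation/translation/scale", {
  base <- goodeid_template()
  moved <- rigid_transform(base, theta = 37 * pi / 180, s = 2.4,
                           dx = 3, dy = -1)
  fit <- align_gpa(list(landmark_config(base, "a"),
                        landmark_config(moved, "b")))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$aligned[1, ] - fit$aligned[2, ])), 1e-8)
  expect_lt(procrustes_distance(base, moved), 1e-8)
})

test_that("gpa_fit satisfies the superimposition invariants", {
  set.seed(7)
  base <- goodeid_template()
  cfgs <- noisy_configs(base, 50, noise_sd = 0.01)
  fit <- align_gpa(cfgs)
  k <- fit$k
  xi <- seq(1, 2 * k, by = 2)

  ## unit centroid size, centroid at origin
  expect_equal(unname(sqrt(rowSums(fit$aligned^2))), rep(1, 50),
               tolerance = 1e-8)
  expect_lt(max(abs(rowMeans(fit$aligned[, xi]))), 1e-8)
  expect_lt(max(abs(rowMeans(fit$aligned[, xi + 1]))), 1e-8)

  ## consensus is the arithmetic mean of the aligned configurations
  expect_equal(colMeans(fit$aligned), as.vector(t(fit$consensus)),
               tolerance = 1e-8, ignore_attr = TRUE)

  ## aligned data occupy ~2k - 4 dimensions. On the unit-size sphere
  ## the scale direction is removed only to first order (leakage is
  ## O(noise^2)); in tangent coordinates the rank bound is exact.
  ev <- eigen(stats::cov(fit$aligned), symmetric = TRUE,
              only.values = TRUE)$values
  expect_lt(ev[2 * k - 3], 1e-3 * ev[1])
  ft <- align_gpa(cfgs, project_tangent = TRUE)
  evt <- eigen(stats::cov(ft$aligned), symmetric = TRUE,
               only.values = TRUE)$values
  expect_lt(evt[2 * k - 3], 1e-10 * evt[1])

  ## consensus recovers the (aligned) base shape
  expect_lt(procrustes_distance(fit$consensus, base), 0.01)
})

test_that("align_gpa is size-invariant and order-invariant", {
  set.seed(8)
  cfgs <- noisy_configs(goodeid_template(), 30, noise_sd = 0.02)
  fit <- align_gpa(cfgs)

  doubled <- lapply(cfgs, function(cfg)
    landmark_config(2 * cfg$coords, cfg$specimen_id))
  fit2 <- align_gpa(doubled)
  expect_equal(fit2$aligned, fit$aligned, tolerance = 1e-8)

  perm <- sample(length(cfgs))
  fit3 <- align_gpa(cfgs[perm])
  expect_lt(procrustes_distance(fit3$consensus, fit$consensus), 1e-6)
  ## same specimens end up at the same shapes (up to global rotation)
  d <- vapply(seq_along(cfgs), function(i)
    procrustes_distance(.unflat(fit$aligned[cfgs[[i]]$specimen_id, ]),
                        .unflat(fit3$aligned[cfgs[[i]]$specimen_id, ])),
    numeric(1))
  expect_lt(max(d), 1e-6)
})

test_that("tangent projection is a small, rank-preserving perturbation", {
  set.seed(9)
  cfgs <- noisy_configs(goodeid_template(), 25, noise_sd = 0.01)
  f0 <- align_gpa(cfgs)
  f1 <- align_gpa(cfgs, project_tangent = TRUE)
  expect_equal(dim(f1$aligned), dim(f0$aligned))
  expect_lt(max(abs(f1$aligned - f0$aligned)), 1e-3)
  expect_gt(max(abs(f1$aligned - f0$aligned)), 0)
})

test_that("species_means averages aligned specimens per species", {
  base <- goodeid_template()
  ## two specimens symmetric about the base: mean must be the base
  dev <- matrix(rnorm(36, sd = 0.01), ncol = 2)
  dev <- dev - matrix(colMeans(dev), 18, 2, byrow = TRUE)
  cfgs <- list(landmark_config(base, "a1"), landmark_config(base, "a2"),
               landmark_config(base + dev, "b1"),
               landmark_config(base - dev, "b2"))
  fit <- align_gpa(cfgs)
  Y <- species_means(fit, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_equal(rownames(Y), c("A", "B"))
  ## identical specimens: mean equals either one
  expect_equal(Y["A", ], fit$aligned["a1", ], tolerance = 1e-12)
  ## symmetric pair: mean is the base shape
  expect_lt(procrustes_distance(.unflat(Y["B", ]), base), 1e-3)
  expect_error(species_means(fit, c(a1 = "A")), "without a species")
})

test_that("a study-shaped dataset yields a 44 x 36 species matrix", {
  st <- make_fixture("paper-scale-44taxa")
  expect_length(st$configs, 44L * 38L)
  fit <- align_gpa(st$configs)
  Y <- species_means(fit, st$species_map)
  expect_equal(dim(Y), c(44L, 36L))
})

test_that("subset_landmarks selects x/y pairs for the module schemes", {
  Y <- matrix(rnorm(5 * 36), 5, dimnames = list(paste0("t", 1:5), NULL))
  head_idx <- c(1:8, 15:18)
  expect_equal(ncol(subset_landmarks(Y, head_idx)), 24L)
  expect_equal(ncol(subset_landmarks(Y, 9:14)), 12L)
  expect_equal(subset_landmarks(Y, 1:18), Y)
  expect_equal(subset_landmarks(Y, 9:14), Y[, 17:28])
  expect_error(subset_landmarks(Y, c(1, 19)), "out of range")
  expect_error(subset_landmarks(Y, integer(0)), "empty")
})
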