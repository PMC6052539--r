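test_that("module_partition validates its sets", {
  p <- module_partition(head = c(1:8, 15:18), trunk = 9:14, k = 18)
  expect_s3_class(p, "module_partition")
  expect_equal(default_partition()$trunk, 9:14)
  expect_error(module_partition(a = 1:5, b = 5:8, k = 18), "overlap")
  expect_error(module_partition(a = 1:5, b = integer(0), k = 18), "empty")
  expect_error(module_partition(a = 1:5, b = 17:19, k = 18), "out of range")
  expect_error(module_partition(a = 1:5, k = 18), "at least 2")
  expect_message(module_partition(a = 1:5, b = 6:10, k = 18), "ignored")
})

test_that("module_rates matches its definition", {
  set.seed(31)
  n <- 6
  block <- matrix(rnorm(n * 12), n)
  ## identical data in both modules -> equal rates
  Yt <- cbind(block, block)
  rownames(Yt) <- paste0("t", 1:n)
  part <- module_partition(a = 1:6, b = 7:12, k = 12)
  r <- module_rates(Yt, part)
  expect_equal(unname(r["a"]), unname(r["b"]))

  ## doubling one module's columns quadruples only that rate
  Yt2 <- Yt
  Yt2[, 13:24] <- 2 * Yt2[, 13:24]
  r2 <- module_rates(Yt2, part)
  expect_equal(unname(r2["a"]), unname(r["a"]))
  expect_equal(unname(r2["b"]), 4 * unname(r["b"]))

  ## concatenation: overall rate is the trait-count-weighted mean
  expect_equal(sigma_mult(Yt2)$overall,
               unname((12 * r2["a"] + 12 * r2["b"]) / 24),
               tolerance = 1e-10)
  expect_error(module_rates(Yt, default_partition()), "k = 18")
})

test_that("a 2.5x module rate contrast is recovered", {
  set.seed(32)
  gc <- generate_chronogram(seed = 32)
  part <- default_partition()
  cols_b <- rep(1, 36)
  cols_b[17:28] <- sqrt(2.5)  # x/y columns of trunk landmarks 9-14
  C <- phylo_covariance(gc$tree)
  est <- replicate(100, {
    Y <- simulate_bm_tips(gc$tree, diag(2e-4, 36))
    Y <- sweep(Y, 2, cols_b, `*`)
    r <- module_rates(phylo_transform(Y, C)$Yt, part)
    unname(r["trunk"] / r["head"])
  })
  expect_lt(abs(median(est) - 2.5) / 2.5, 0.20)
})

test_that("modularity_rate_test is deterministic and labels the ratio", {
  set.seed(33)
  gc <- generate_chronogram(12, 4, seed = 33)
  Y <- simulate_bm_tips(gc$tree, diag(2e-4, 36))
  m1 <- modularity_rate_test(Y, gc$tree, default_partition(),
                             nsim = 99, seed = 7)
  m2 <- modularity_rate_test(Y, gc$tree, default_partition(),
                             nsim = 99, seed = 7)
  expect_identical(m1, m2)
  expect_gte(m1$r_mult, 1)
  expect_equal(m1$r_mult,
               max(m1$sigma2_by_module) / min(m1$sigma2_by_module))
  ## invariant to module naming order
  m3 <- modularity_rate_test(Y, gc$tree,
                             module_partition(trunk = 9:14,
                                              head = c(1:8, 15:18)),
                             nsim = 99, seed = 7)
  expect_equal(m3$r_mult, m1$r_mult)
})

test_that("modularity test detects a strong module contrast", {
  set.seed(34)
  gc <- generate_chronogram(seed = 34)
  rv <- rep(2e-4, 36)
  rv[17:28] <- 5e-4  # trunk columns evolve 2.5x faster
  pv <- replicate(20, {
    Y <- simulate_bm_tips(gc$tree, diag(rv))
    modularity_rate_test(Y, gc$tree, default_partition(),
                         nsim = 199)$p_value
  })
  expect_lt(median(pv), 0.05)
})

test_that("within-module tests subset columns, whitening unchanged", {
  set.seed(35)
  gc <- generate_chronogram(10, 4, seed = 35)
  Y <- simulate_bm_tips(gc$tree, diag(2e-4, 36))
  wt <- suppressMessages(within_module_clade_test(Y, gc$tree, gc$groups,
                                                  9:14, nsim = 99, seed = 3))
  expect_equal(wt$trait_dim, 12L)
  wh <- suppressMessages(within_module_clade_test(Y, gc$tree, gc$groups,
                                                  c(1:8, 15:18),
                                                  nsim = 99, seed = 3))
  expect_equal(wh$trait_dim, 24L)

  ## full landmark set: identical to the overall test with the same seed
  wall <- suppressMessages(within_module_clade_test(Y, gc$tree, gc$groups,
                                                    1:18, nsim = 99,
                                                    seed = 3))
  oall <- suppressMessages(rate_ratio_test(Y, gc$tree, gc$groups,
                                           nsim = 99, seed = 3))
  expect_identical(wall, oall)

  ## rates from a module equal rates on the whitened column subset
  C <- phylo_covariance(gc$tree, rownames(Y))
  Yt <- phylo_transform(Y, C)$Yt
  s_sub <- suppressMessages(
    sigma_mult(phylo_transform(subset_landmarks(Y, 9:14),
                               C)$Yt, gc$groups))
  s_cols <- suppressMessages(
    sigma_mult(subset_landmarks(Yt, 9:14), gc$groups))
  expect_equal(s_sub$by_group, s_cols$by_group, tolerance = 1e-10)
})
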