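test_that("phylo_transform reduces to closed forms on simple trees", {
  ## identity covariance: plain column centering
  Y <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("t", 1:4), NULL))
  tr <- phylo_transform(Y, diag(4))
  expect_equal(tr$gls_mean, colMeans(Y), ignore_attr = TRUE)
  expect_equal(unname(tr$Yt), unname(sweep(Y, 2, colMeans(Y))))

  ## star tree, branch length t: centered data scaled by 1/sqrt(t)
  star <- read_newick(text = "(A:4,B:4,C:4,D:4);")
  Ys <- matrix(rnorm(8), 4, 2, dimnames = list(c("A", "B", "C", "D"), NULL))
  trs <- phylo_transform(Ys, phylo_covariance(star))
  expect_equal(trs$gls_mean, colMeans(Ys), ignore_attr = TRUE)
  expect_equal(unname(trs$Yt), unname(sweep(Ys, 2, colMeans(Ys)) / 2))

  expect_error(phylo_transform(Y, diag(c(1, 1, 1, 0))), "singular")
})

test_that("whitening yields unit per-trait variance (Monte Carlo)", {
  set.seed(21)
  tree <- rand_chronogram(20)
  C <- phylo_covariance(tree)
  sigma2 <- 0.5
  n <- 20; p <- 2
  acc <- matrix(0, p, p)
  nrep <- 1000
  for (r in seq_len(nrep)) {
    Y <- simulate_bm_tips(tree, diag(sigma2, p))
    Yt <- phylo_transform(Y, C)$Yt
    acc <- acc + crossprod(Yt) / n
  }
  acc <- acc / nrep
  ## GLS-mean removal leaves expectation sigma2 * (1 - 1/n) on the
  ## diagonal (standard ML bias) and 0 off it
  expect_equal(diag(acc), rep(sigma2 * (1 - 1 / n), p), tolerance = 0.05)
  expect_lt(max(abs(acc[upper.tri(acc)])), 0.05 * sigma2)
})

test_that("sigma_mult matches its definition and scaling laws", {
  ## 1 trait, star tree (branch 1), tips {1,-1,1,-1}: sigma2 = 1
  star <- read_newick(text = "(A:1,B:1,C:1,D:1);")
  Y <- matrix(c(1, -1, 1, -1), 4, 1,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  Yt <- phylo_transform(Y, phylo_covariance(star))$Yt
  expect_equal(sigma_mult(Yt)$overall, 1)

  ## scaling data by c scales rates by c^2
  set.seed(22)
  tree <- rand_chronogram(8)
  Y8 <- simulate_bm_tips(tree, diag(0.3, 5))
  Yt8 <- phylo_transform(Y8, phylo_covariance(tree))$Yt
  g <- setNames(rep(c("u", "v"), each = 4), rownames(Y8))
  s1 <- suppressMessages(sigma_mult(Yt8, g))
  s2 <- suppressMessages(sigma_mult(3 * Yt8, g))
  expect_equal(s2$overall, 9 * s1$overall)
  expect_equal(s2$by_group, 9 * s1$by_group)
  expect_error(sigma_mult(Yt8, setNames(rep("u", 8), rownames(Y8))[1:4]),
               "without a group")
})

test_that("sigma_mult equals the explicit C^-1 quadratic form (oracle)", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    tree <- rand_chronogram(n)
    Y <- simulate_bm_tips(tree, diag(0.2, 3))
    C <- phylo_covariance(tree)
    Yt <- phylo_transform(Y, C)$Yt
    ## oracle: GLS mean and quadratic form via solve(), no eigen sqrt
    Ci <- solve(C)
    one <- rep(1, n)
    a <- drop((crossprod(one, Ci) %*% Y) / drop(crossprod(one, Ci %*% one)))
    Rm <- sweep(Y, 2, a)
    qf <- sum(diag(t(Rm) %*% Ci %*% Rm)) / (n * ncol(Y))
    expect_equal(sigma_mult(Yt)$overall, qf, tolerance = 1e-10)
  }
})

test_that("sigma_mult recovers the generating rate (p = 1 and p = 36)", {
  set.seed(24)
  tree <- rand_chronogram(46, age = 18.02)
  C <- phylo_covariance(tree)
  sigma2 <- 5e-4
  est <- replicate(200, {
    Y <- simulate_bm_tips(tree, diag(sigma2, 36))
    sigma_mult(phylo_transform(Y, C)$Yt)$overall
  })
  expect_lt(abs(median(est) - sigma2) / sigma2, 0.10)

  ## p = 1: estimator is sum(d^2)/N on the whitened data
  y <- simulate_bm_tips(tree, matrix(1))
  yt <- phylo_transform(y, C)$Yt
  expect_equal(sigma_mult(yt)$overall, sum(yt^2) / 46)
})

test_that("rate_ratio reproduces the published worked examples", {
  expect_equal(rate_ratio(1.397e-2, 5.567e-3), 2.51, tolerance = 0.002)
  expect_equal(rate_ratio(2.737e-3, 1.071e-3), 2.556, tolerance = 2e-4)
  expect_equal(rate_ratio(0.7, 0.7), 1)
  expect_error(rate_ratio(1, 0), "positive")
})

test_that("simulate_bm_tips matches the analytic tip covariance", {
  tree <- read_newick(text = "((A:1,B:1):1,C:2);")
  expect_equal(unname(simulate_bm_tips(tree, diag(0, 2), seed = 1)),
               matrix(0, 3, 2))
  expect_identical(simulate_bm_tips(tree, diag(1, 3), seed = 9),
                   simulate_bm_tips(tree, diag(1, 3), seed = 9))
  set.seed(25)
  draws <- replicate(2000, simulate_bm_tips(tree, matrix(1))[, 1])
  emp <- tcrossprod(draws) / 2000
  expect_lt(max(abs(emp - phylo_covariance(tree))), 0.2)
  expect_error(simulate_bm_tips(tree, matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
})

test_that("rate_ratio_test is deterministic and scale-consistent", {
  set.seed(26)
  gc <- generate_chronogram(10, 4, seed = 26)
  Y <- simulate_bm_tips(gc$tree, diag(2e-4, 8))
  r1 <- suppressMessages(rate_ratio_test(Y, gc$tree, gc$groups,
                                         nsim = 99, seed = 5))
  r2 <- suppressMessages(rate_ratio_test(Y, gc$tree, gc$groups,
                                         nsim = 99, seed = 5))
  expect_identical(r1, r2)
  expect_gte(r1$ratio, 1)
  expect_equal(r1$ratio,
               max(r1$sigma2_by_group) / min(r1$sigma2_by_group))
  expect_true(r1$p_value > 0 && r1$p_value <= 1)

  ## multiplying branch lengths by c divides rates by c, fixes ratio
  scaled <- gc$tree
  scaled$edge.length <- scaled$edge.length * 4
  r3 <- suppressMessages(rate_ratio_test(Y, scaled, gc$groups,
                                         nsim = 99, seed = 5))
  expect_equal(r3$sigma2_by_group, r1$sigma2_by_group / 4)
  expect_equal(r3$ratio, r1$ratio, tolerance = 1e-12)
  expect_identical(r3$p_value, r1$p_value)

  ## taxon order invariance of the estimates
  perm <- sample(nrow(Y))
  r4 <- suppressMessages(rate_ratio_test(Y[perm, ], gc$tree, gc$groups,
                                         nsim = 99, seed = 5))
  expect_equal(r4$sigma2_by_group, r1$sigma2_by_group)
})

test_that("rate_ratio_test recovers a true 2x rate difference", {
  gc <- generate_chronogram(seed = 27)
  est <- numeric(30)
  set.seed(27)
  for (r in seq_len(30)) {
    st <- simulate_study(gc$tree, gc$groups,
                         truth_record(seed = 2700 + r,
                                      specimens_per_species = 1L,
                                      specimen_noise_sd = 0))
    Yt <- phylo_transform(st$species_means_true,
                          phylo_covariance(gc$tree))$Yt
    s <- suppressMessages(sigma_mult(Yt, gc$groups))
    est[r] <- s$by_group["Goodeinae"] / s$by_group["Empetrichthyinae"]
  }
  expect_gt(median(est), 1.6)
  expect_lt(median(est), 2.5)
})
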