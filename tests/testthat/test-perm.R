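test_that("permutation p-values follow the (b+1)/(m+1) convention", {
  # observed beats all 1000 draws
  expect_equal(perm_pvalue(10, rnorm(1000), "greater"), 1 / 1001)
  # observed equal to every draw
  expect_equal(perm_pvalue(1, rep(1, 50), "greater"), 1)
  expect_equal(perm_pvalue(1, rep(1, 50), "two"), 1)
  # 9-draw toy with 2 draws more extreme (two-tailed around 0)
  draws <- c(3, -2.5, 1, -1, 0.5, 0.2, -0.1, 0.8, 1.5)
  expect_equal(perm_pvalue(2, draws, "two"), 3 / 10)
  expect_error(perm_pvalue(1, numeric(0)), "empty")
  expect_error(perm_pvalue(1, c(1, NA)), "non-finite")
  # never zero
  expect_gt(perm_pvalue(1e9, rnorm(100), "greater"), 0)
})

test_that("group mean test matches exhaustive enumeration on a tiny design", {
  values <- c(1.2, 0.8, 1.1, 2.4, 2.0, 2.6)
  groups <- factor(rep(c("x", "y"), each = 3))
  f_obs <- pdcognet:::oneway_f(values, groups)
  expect_equal(f_obs, summary(aov(values ~ groups))[[1]]$`F value`[1],
               tolerance = 1e-10)
  # exact p by enumerating all 20 label assignments
  combos <- combn(6, 3)
  f_all <- apply(combos, 2, function(ix) {
    g <- factor(ifelse(seq_len(6) %in% ix, "x", "y"))
    pdcognet:::oneway_f(values, g)
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  res <- perm_group_mean_test(values, groups, n_perms = 4000, seed = 1)
  expect_lt(abs(res$omnibus$p_value - p_exact), 0.02)
  # strong separation -> near-minimal p (the complementary assignment
  # reproduces the same F, so the floor is ~2 draws in 500)
  v8 <- c(rnorm(8), rnorm(8) + 50)
  g8 <- factor(rep(c("x", "y"), each = 8))
  res2 <- perm_group_mean_test(v8, g8, n_perms = 500, seed = 2)
  expect_lte(res2$omnibus$p_value, 3 / 501)
  expect_true(all(c("p_adjusted", "reject") %in% names(res2$pairwise)))
})

test_that("permutation correlation agrees with the parametric test", {
  set.seed(51)
  x <- rnorm(200); y <- rnorm(200)
  res <- perm_correlation(x, y, n_perms = 4000, seed = 3)
  expect_equal(res$r, cor(x, y), tolerance = 1e-12)
  expect_lt(abs(res$null$p_value - cor.test(x, y)$p.value), 0.02)
  # y = x: perfect correlation, minimal p
  res2 <- perm_correlation(x, x, n_perms = 500, seed = 4)
  expect_equal(res2$r, 1)
  expect_equal(res2$null$p_value, 1 / 501)
  # 5-point toy matches the hand formula
  a <- c(1, 2, 3, 4, 5); b <- c(2, 1, 4, 3, 6)
  expect_equal(perm_correlation(a, b, n_perms = 10, seed = 5)$r,
               sum(scale(a) * scale(b)) / 4, tolerance = 1e-12)
  expect_error(perm_correlation(a[1:4], b[1:4]), "at least 5")
  expect_error(perm_correlation(rep(1, 5), b), "zero variance")
})

test_that("standardized betas behave like correlations where they should", {
  set.seed(52)
  n <- 120
  x1 <- rnorm(n)
  y <- 0.5 * x1 + rnorm(n)
  # single predictor: standardized beta equals Pearson r
  res <- perm_regression(y, data.frame(x1 = x1), n_perms = 200, seed = 6)
  expect_equal(res$beta, cor(x1, y), tolerance = 1e-10)
  # orthogonal predictors: betas equal the marginal correlations
  x2 <- qr.resid(qr(cbind(1, x1)), rnorm(n))
  res2 <- perm_regression(y, data.frame(x1 = x1, x2 = x2),
                          n_perms = 200, seed = 7)
  expect_equal(res2$beta[res2$predictor == "x1"], cor(x1, y),
               tolerance = 1e-10)
  expect_equal(res2$beta[res2$predictor == "x2"], cor(x2, y),
               tolerance = 1e-10)
  # planted coefficient recovered by least squares at n = 500
  set.seed(53)
  xb <- rnorm(500); yb <- 0.5 * xb + rnorm(500)
  res3 <- perm_regression(yb, data.frame(x = xb), n_perms = 100, seed = 8)
  r_planted <- 0.5 / sqrt(0.5^2 + 1)
  expect_lt(abs(res3$beta - r_planted), 0.05)
  # collinear predictors are rejected by name
  expect_error(perm_regression(y, data.frame(a = x1, b = 2 * x1),
                               n_perms = 10), "rank-deficient")
})

test_that("BH-FDR matches the exhaustive step-up search", {
  # single p: adjusted equals raw
  expect_equal(bh_fdr(0.03)$p_adjusted, 0.03)
  # the classic boundary set: all rejected at q = 0.05
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  expect_true(all(bh_fdr(p)$reject))
  expect_false(any(bh_fdr(rep(1, 4))$reject))
  # exhaustive oracle: largest k with p_(k) <= k q / m for random sets
  set.seed(54)
  for (rep in 1:20) {
    m <- sample(2:10, 1)
    p <- round(runif(m), 3)
    res <- bh_fdr(p, q = 0.05)
    ps <- sort(p)
    k <- max(c(0, which(ps <= 0.05 * seq_len(m) / m)))
    oracle_reject <- if (k == 0) rep(FALSE, m) else p <= ps[k]
    expect_equal(res$reject, oracle_reject)
    # adjusted p monotone with raw p
    expect_true(all(diff(res$p_adjusted[order(p)]) >= -1e-12))
  }
})

test_that("null draws are exchangeable and seed-stable", {
  set.seed(55)
  v <- rnorm(30); g <- factor(rep(c("a", "b", "c"), each = 10))
  a <- perm_group_mean_test(v, g, n_perms = 200, seed = 10)
  b <- perm_group_mean_test(v, g, n_perms = 200, seed = 10)
  expect_identical(a$omnibus$draws, b$omnibus$draws)
  c <- perm_group_mean_test(v, g, n_perms = 200, seed = 11)
  expect_false(identical(a$omnibus$draws, c$omnibus$draws))
  # null F mean stays near 1 across seeds (exchangeability)
  expect_lt(abs(mean(c$omnibus$draws) - 1), 0.4)
})
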