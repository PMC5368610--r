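test_that("bandpass filter removes DC, keeps the passband, rejects above it", {
  tr <- 2
  t <- seq_len(300)
  gain_at <- function(freq_hz) {
    x <- sin(2 * pi * freq_hz * t * tr)
    y <- bandpass_filter(x, tr)[1, ]
    core <- 50:250 # trim filter edge transients
    # FFT-based amplitude at the probe frequency
    amp <- function(v) {
      sp <- Mod(fft(v - mean(v)))[seq_len(length(v) %/% 2)]
      f <- (seq_along(sp) - 1) / (length(v) * tr)
      sp[which.min(abs(f - freq_hz))]
    }
    amp(y[core]) / amp(x[core])
  }
  constant <- bandpass_filter(matrix(5, 2, 300), tr)
  expect_lt(max(abs(constant[, 50:250])), 1e-8)
  expect_gt(gain_at(0.05), 0.9)
  expect_lt(gain_at(0.05), 1.1)
  expect_lt(gain_at(0.2), 0.1)
  expect_error(bandpass_filter(matrix(1, 2, 10), tr), "too short")
  expect_error(bandpass_filter(matrix(rnorm(200), 2), tr, low_hz = 0.2,
                               high_hz = 0.3), "Nyquist")
})

test_that("first eigenvariate matches the dense SVD oracle and conventions", {
  set.seed(1)
  # single voxel: perfect correlation with itself
  v1 <- rnorm(50)
  expect_equal(abs(cor(first_eigenvariate(v1), v1)), 1, tolerance = 1e-12)
  # two identical voxels: same series
  expect_equal(abs(cor(first_eigenvariate(rbind(v1, v1)), v1)), 1,
               tolerance = 1e-12)
  # random 3 x 50: matches brute-force SVD of the centered matrix
  x <- matrix(rnorm(150), 3, 50)
  ev <- first_eigenvariate(x)
  sv <- svd(x - rowMeans(x))
  oracle <- sv$v[, 1]
  if (sum(sv$u[, 1]) < 0) oracle <- -oracle
  expect_equal(ev, oracle / sd(oracle), tolerance = 1e-10)
  # sign convention: positive sum of voxel weights
  expect_gt(cor(ev, colMeans(x * sign(sum(sv$u[, 1])))), 0)
  expect_error(first_eigenvariate(matrix(3, 4, 20)), "constant")
})

test_that("aCompCor components match the eigendecomposition oracle", {
  set.seed(2)
  pool <- matrix(rnorm(5 * 40), 5, 40)
  nc <- compute_acompcor(pool, n_components = 3)
  # oracle: eigendecomposition of the covariance of the normalized pool
  xc <- pool - rowMeans(pool)
  xc <- xc / sqrt(rowMeans(xc^2))
  eg <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  for (k in 1:3) {
    expect_equal(abs(cor(nc$components[k, ], eg$vectors[, k])), 1,
                 tolerance = 1e-8)
  }
  expect_equal(nc$explained_variance, (eg$values / sum(eg$values))[1:3],
               tolerance = 1e-8)
  # orthogonality and ordering
  cc <- cor(t(nc$components))
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  expect_true(all(diff(nc$explained_variance) <= 1e-12))
})

test_that("rank-1 noise pool concentrates variance in one component", {
  set.seed(3)
  src <- rnorm(60)
  pool <- outer(rnorm(12), src) + 1e-6 * matrix(rnorm(720), 12)
  nc <- compute_acompcor(pool, n_components = 3)
  expect_gt(nc$explained_variance[1], 0.99)
})

test_that("regressing components out leaves 1 - sum(explained) variance", {
  set.seed(4)
  pool <- matrix(rnorm(30 * 80), 30, 80)
  pool <- pool + outer(rnorm(30), rnorm(80)) # one strong latent
  nc <- compute_acompcor(pool, n_components = 10)
  xc <- pool - rowMeans(pool)
  xc <- xc / sqrt(rowMeans(xc^2))
  res <- regress_nuisance(xc, nc)
  total <- sum(xc^2)
  expect_equal(sum(res^2) / total, 1 - sum(nc$explained_variance),
               tolerance = 1e-6)
})

test_that("framewise displacement follows the 50-mm sphere convention", {
  zero <- matrix(0, 10, 6)
  ms <- framewise_displacement(zero)
  expect_equal(ms$fd, rep(0, 9))
  expect_equal(ms$max_translation, 0)
  # single 1-mm translation step
  m <- matrix(0, 2, 6); m[2, 1] <- 1
  expect_equal(framewise_displacement(m)$fd, 1.0)
  # single 1-degree rotation step: arc length on a 50 mm sphere
  m <- matrix(0, 2, 6); m[2, 4] <- 1
  expect_equal(framewise_displacement(m)$fd, 50 * pi / 180,
               tolerance = 1e-12)
  m[2, 4] <- NA
  expect_error(framewise_displacement(m), "finite")
})

test_that("motion exclusion applies inclusive thresholds and is monotone", {
  base <- structure(list(fd = 0, mean_translation = 0.1, max_translation = 0.5,
                         mean_rotation = 0.1, max_rotation = 0.5),
                    class = "motion_summary")
  expect_true(motion_exclude(base)$keep)
  hi <- base; hi$mean_translation <- 0.31
  dec <- motion_exclude(hi)
  expect_false(dec$keep)
  expect_match(dec$reason, "mean translation")
  exact <- base; exact$max_rotation <- 1.0 # boundary is inclusive
  expect_false(motion_exclude(exact)$keep)
  # monotone: increasing any summary never flips exclude -> keep
  fields <- c("mean_translation", "mean_rotation", "max_translation",
              "max_rotation")
  for (f in fields) {
    worse <- hi; worse[[f]] <- worse[[f]] + 2
    expect_false(motion_exclude(worse)$keep)
  }
})

test_that("FD-signal coupling drops after nuisance regression", {
  fx <- small_cohort()
  qc <- qc_report(fx$cohort)
  expect_gt(mean(qc$r_before), mean(qc$r_after) + 0.1)
  expect_lt(mean(abs(qc$r_after)), 0.15)
  # uncontaminated series: both correlations near zero
  set.seed(6)
  clean <- matrix(rnorm(15 * 80), 15, 80)
  motion <- pdcognet:::simulate_motion(80, 0.05)
  qc2 <- qc_fd_signal_coupling(clean, clean, motion)
  expect_lt(abs(qc2$r_before), 0.35)
  expect_equal(qc2$r_before, qc2$r_after)
})

test_that("QC statistic matches a hand computation on a toy series", {
  x5 <- rbind(c(0, 2, 1, 5, 3), c(1, 1, 4, 2, 2))
  m5 <- cbind(c(0, 1, 1, 3, 3), matrix(0, 5, 5))
  expect_error(qc_fd_signal_coupling(x5, x5, m5), "10 frames")
  # replicate the pattern to reach the frame minimum
  xb <- x5[, c(1:5, 1:5)]
  mo <- m5[c(1:5, 1:5), ]
  qc <- qc_fd_signal_coupling(xb, xb, mo)
  fd <- framewise_displacement(mo)$fd
  dv <- sqrt(colMeans((xb[, -1] - xb[, -10])^2))
  expect_equal(qc$r_before, cor(fd, dv), tolerance = 1e-12)
  expect_equal(qc$r_before, qc$r_after)
})

test_that("filtering and eigenvariate extraction commute given a dominant mode", {
  set.seed(7)
  src <- rnorm(200)
  x <- outer(rnorm(6, 1, 0.2), src) + 0.3 * matrix(rnorm(6 * 200), 6)
  a <- first_eigenvariate(bandpass_filter(x, 2))
  b <- bandpass_filter(first_eigenvariate(x), 2)[1, ]
  b <- b / sd(b)
  expect_gt(abs(cor(a[30:170], b[30:170])), 0.98)
})
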