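test_that("C tuning uses the printed grid and breaks ties toward small C", {
  # wide-margin separable toy: every C reaches 100%, smallest returned
  set.seed(41)
  x <- rbind(matrix(rnorm(20, -5, 0.2), 10), matrix(rnorm(20, 5, 0.2), 10))
  y <- rep(c("PD-nonMCI", "PD-MCI"), each = 10)
  tc <- tune_c_nested(x, y)
  expect_equal(sort(as.numeric(names(tc$accuracy))), 10^(-3:2))
  expect_equal(tc$c, 1e-3)
  expect_true(all(tc$accuracy == 1))
})

test_that("tuned C matches an independently coded inner loop", {
  set.seed(42)
  n <- 14
  x <- matrix(rnorm(n * 3), n)
  y <- factor(rep(c("PD-nonMCI", "PD-MCI"), each = n / 2))
  x[, 1] <- x[, 1] + ifelse(y == "PD-MCI", 1.2, 0)
  grid <- 10^(-3:2)
  acc <- vapply(grid, function(cost) {
    mean(vapply(seq_len(n), function(s) {
      fit <- pdcognet:::fit_weighted_svm(x[-s, ], y[-s], cost, "PD-MCI")
      pr <- pdcognet:::predict_weighted_svm(fit, x[s, , drop = FALSE])
      pr$label == as.character(y[s])
    }, logical(1)))
  }, numeric(1))
  oracle <- grid[which(acc == max(acc))][1]
  expect_equal(tune_c_nested(x, y, grid)$c, oracle)
})

test_that("classification metrics match hand counts and Mann-Whitney AUC", {
  m <- classification_metrics(rep("a", 4), rep(1, 4), rep("a", 4),
                              pos_class = "a")
  expect_equal(m$accuracy, 100)
  expect_false(m$auc_defined)
  # all decision values equal -> AUC 0.5 by midranks
  y <- c("a", "a", "b", "b")
  m2 <- classification_metrics(y, rep(0, 4), y, pos_class = "a")
  expect_equal(m2$auc, 0.5)
  expect_equal(m2$accuracy, 100)
  # 5-subject toy against the exhaustive pair-count formula
  dec <- c(0.9, 0.2, 0.4, 0.4, -1)
  lab <- c("a", "b", "a", "b", "b")
  m3 <- classification_metrics(lab, dec, lab, pos_class = "a")
  pos <- which(lab == "a"); neg <- which(lab == "b")
  pairs <- expand.grid(p = pos, n = neg)
  auc_oracle <- mean(ifelse(dec[pairs$p] > dec[pairs$n], 1,
                            ifelse(dec[pairs$p] == dec[pairs$n], 0.5, 0)))
  expect_equal(m3$auc, auc_oracle)
  # per-class accuracies from a toy confusion
  pred <- c("a", "b", "b", "b", "b")
  m4 <- classification_metrics(pred, dec, lab, pos_class = "a")
  expect_equal(unname(m4$per_class[c("a", "b")]), c(50, 100))
})

test_that("a label-copy feature yields perfect LOOCV classification", {
  set.seed(43)
  n <- 14
  y <- factor(rep(c("PD-nonMCI", "PD-MCI"), each = n / 2))
  x <- cbind(ifelse(y == "PD-MCI", 1, -1),
             matrix(rnorm(n * 30), n))
  res <- suppressWarnings(
    loocv_pipeline(x, y, n_repeats = 2, rlr = list(n_iterations = 15),
                   seed = 5))
  expect_equal(res$summary$mean_accuracy, 100)
  expect_equal(res$summary$mean_auc, 1)
  # structure: one stored prediction per subject and repeat
  expect_equal(dim(res$predictions), c(n, 2))
  expect_false(anyNA(res$predictions))
  # reported means equal recomputation from per-repeat values
  expect_equal(res$summary$mean_accuracy, mean(res$per_repeat$accuracy))
  expect_equal(res$summary$sd_auc, sd(res$per_repeat$auc))
})

test_that("the held-out subject cannot influence feature selection", {
  fx <- small_cohort()
  pat <- fx$groups != "HC"
  x <- fx$features[pat, ]
  y <- fx$groups[pat]
  s <- 3 # corrupt one subject's features with an extreme outlier
  x_out <- x
  x_out[s, ] <- 100
  a <- suppressWarnings(loocv_pipeline(x, y, n_repeats = 1,
                                       rlr = list(n_iterations = 10), seed = 11))
  b <- suppressWarnings(loocv_pipeline(x_out, y, n_repeats = 1,
                                       rlr = list(n_iterations = 10), seed = 11))
  # fold s trains without subject s: identical selection despite corruption
  expect_identical(a$selected[[1]][[s]], b$selected[[1]][[s]])
})

test_that("funnel tiers nest and match hand tallies", {
  # toy log: 3 repeats x 4 training sets over 6 edges
  sel <- list(
    list(c(1, 2), c(1, 2, 5), c(1, 2), c(1, 2)),
    list(c(1, 2), c(1, 3), c(1, 2), c(1, 2)),
    list(c(1, 2), c(1), c(1, 2), c(1, 6)))
  fn <- consensus_funnel(sel, n_edges = 6)
  expect_equal(fn$tier_any, c(1, 2, 3, 5, 6))
  expect_equal(fn$tier_all_repeats, c(1, 2)) # edge 2: all repeats in sets 1/3
  # consensus: selected by >= 80% of the 4 sets in every repeat -> edge 1 only
  expect_equal(fn$tier_consensus, 1)
  # per-subject tier at >= ceiling(0.8 * 3) = 3 of 3 repeats
  expect_equal(fn$per_subject[[2]], 1)
  expect_equal(fn$per_subject[[1]], c(1, 2))
  expect_true(all(fn$tier_consensus %in% fn$tier_all_repeats))
  expect_true(all(fn$tier_all_repeats %in% fn$tier_any))
  # incomplete logs rejected
  sel_bad <- sel; sel_bad[[2]][[3]] <- NULL
  expect_error(consensus_funnel(sel_bad, 6), "incomplete")
})

test_that("final model validates and self-classifies consistently", {
  set.seed(44)
  n <- 16
  y <- factor(rep(c("PD-nonMCI", "PD-MCI"), each = n / 2))
  x <- cbind(ifelse(y == "PD-MCI", 1.5, 0) + rnorm(n, 0, 0.4),
             matrix(rnorm(n * 10), n))
  res <- fit_final_and_validate(x, y, x, y, edges = 1, tune_c = FALSE)
  # validation = training copy: accuracy equals resubstitution accuracy
  fit <- pdcognet:::fit_weighted_svm(x[, 1, drop = FALSE], y, 1, "PD-MCI")
  resub <- mean(pdcognet:::predict_weighted_svm(fit, x[, 1, drop = FALSE])$label ==
                  as.character(y)) * 100
  expect_equal(res$metrics$accuracy, resub)
  expect_error(fit_final_and_validate(x, y, x[, 1:5], y, edges = 1),
               "edge-map mismatch")
  expect_error(fit_final_and_validate(x, y, x, y, edges = integer(0)),
               "empty")
})
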