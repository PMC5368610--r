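test_that("cohort spec validates counts and planted-edge feasibility", {
  expect_error(cohort_spec(n_hc = 0), "positive")
  # baseline within-block r = 0.3 plus delta 0.8 would exceed 1
  bad <- data.frame(i = 1, j = 2, delta = 0.75)
  expect_error(cohort_spec(n_nodes = 20, signal_edges = bad), "leaves")
  # sign/direction consistency
  bad2 <- data.frame(i = 1, j = 2, delta = 0.3, direction = "decrease")
  expect_error(cohort_spec(n_nodes = 20, signal_edges = bad2), "sign")
})

test_that("same seed gives an identical cohort, different seed does not", {
  spec <- cohort_spec(n_hc = 3, n_pd_nonmci = 4, n_pd_mci = 3,
                      n_nodes = 10, n_frames = 50, n_noise_voxels = 15,
                      seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  spec2 <- cohort_spec(n_hc = 3, n_pd_nonmci = 4, n_pd_mci = 3,
                       n_nodes = 10, n_frames = 50, n_noise_voxels = 15,
                       seed = 43)
  c <- generate_cohort(spec2)
  expect_false(identical(a$subjects[[1]]$roi_series,
                         c$subjects[[1]]$roi_series))
})

test_that("default spec reproduces the modeled sample structure", {
  spec <- cohort_spec()
  expect_equal(spec$n_hc + spec$n_pd_nonmci + spec$n_pd_mci, 108)
  expect_equal(spec$n_nodes, 246)
  expect_equal(spec$n_frames, 295) # 300 volumes minus 5 discarded
  expect_equal(nrow(spec$signal_edges), 21)
  expect_equal(sum(spec$signal_edges$delta < 0), 16)
  expect_equal(sum(spec$signal_edges$delta > 0), 5)
  cohort <- generate_cohort(spec)
  expect_length(cohort$subjects, 108)
  expect_equal(dim(cohort$subjects[[1]]$roi_series), c(246, 295))
  expect_equal(dim(cohort$subjects[[1]]$motion_params), c(295, 6))
  expect_equal(as.vector(table(factor(cohort$truth$group,
                                      c("HC", "PD-nonMCI", "PD-MCI")))),
               c(38, 43, 27))
})

test_that("empirical group contrast converges to the planted delta", {
  # one planted edge, long series, clean signal path
  edges <- data.frame(i = 2, j = 7, delta = -0.4)
  spec <- cohort_spec(n_hc = 2, n_pd_nonmci = 6, n_pd_mci = 6,
                      n_nodes = 10, n_frames = 10000, n_noise_voxels = 12,
                      signal_edges = edges, contamination_weight = 0,
                      motion_coupling = 0, seed = 99)
  cohort <- generate_cohort(spec)
  g <- cohort$truth$group
  r <- vapply(cohort$subjects, function(s)
    cor(s$roi_series[2, ], s$roi_series[7, ]), numeric(1))
  diff <- mean(r[g == "PD-MCI"]) - mean(r[g == "PD-nonMCI"])
  target <- cohort$truth$sigma[["PD-MCI"]][2, 7] -
    cohort$truth$sigma[["PD-nonMCI"]][2, 7]
  expect_equal(target, -0.4, tolerance = 0.02)
  expect_lt(abs(diff - (-0.4)), 0.05)
})

test_that("zero planted effects leave the groups exchangeable edge-wise", {
  fx <- null_cohort()
  pat <- fx$groups != "HC"
  x <- fx$features[pat, ]
  y <- fx$groups[pat]
  p <- apply(x, 2, function(v) t.test(v[y == "PD-MCI"],
                                      v[y == "PD-nonMCI"])$p.value)
  # approximately uniform p-values (edges sharing nodes are mildly
  # dependent, so only coarse calibration is asserted)
  expect_lt(mean(p < 0.05), 0.12)
  expect_lt(abs(mean(p < 0.5) - 0.5), 0.12)
})

test_that("neuropsych scores respond to planted domain effects", {
  spec <- cohort_spec(n_hc = 20, n_pd_nonmci = 10, n_pd_mci = 10,
                      n_nodes = 8, n_frames = 40, n_noise_voxels = 12,
                      neuropsych_effects = c(attention = 0, executive = 3,
                                             visuospatial = 0, memory = 3),
                      seed = 3)
  hits <- fp <- numeric(5)
  for (k in 1:5) {
    spec$seed <- 100 + k
    cohort <- generate_cohort(spec)
    np <- withr::with_seed(200 + k, generate_neuropsych(spec, cohort))
    st <- cognitive_status(np)$status
    hits[k] <- mean(st$label[np$group == "PD-MCI"] == "MCI")
    fp[k] <- mean(st$label[np$group == "HC"] == "MCI")
  }
  expect_gte(mean(hits), 0.9) # planted two-domain 3-SD deficits recovered
  expect_lt(mean(fp), 0.3)    # HC mislabeling stays low
})

test_that("zero neuropsych effects give group-independent labeling rates", {
  spec <- cohort_spec(n_hc = 25, n_pd_nonmci = 25, n_pd_mci = 25,
                      n_nodes = 8, n_frames = 40, n_noise_voxels = 12,
                      neuropsych_effects = c(attention = 0, executive = 0,
                                             visuospatial = 0, memory = 0),
                      seed = 8)
  cohort <- generate_cohort(spec)
  rates <- replicate(6, {
    np <- generate_neuropsych(spec, cohort)
    st <- cognitive_status(np)$status
    tapply(st$label == "MCI", np$group, mean)
  })
  # same criterion false-positive rate in every group
  expect_lt(max(abs(rowMeans(rates) - mean(rates))), 0.1)
})

test_that("cohort writes to disk and reads back consistently", {
  fx <- small_cohort()
  np <- withr::with_seed(1, generate_neuropsych(fx$spec, fx$cohort))
  dir <- withr::local_tempdir()
  write_cohort(fx$cohort, np, dir)
  expect_true(file.exists(file.path(dir, "cohort.yaml")))
  back <- read_cohort(dir)
  expect_equal(nrow(back$records), length(fx$cohort$subjects))
  expect_equal(back$subjects[[1]]$roi_series,
               unname(fx$cohort$subjects[[1]]$roi_series),
               tolerance = 1e-6, ignore_attr = TRUE)
  # ground truth is not part of the on-disk pipeline inputs
  expect_false(any(grepl("signal", readLines(file.path(dir, "cohort.yaml")))))
})
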