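# Synthetic cohort generation.
#
# The generator draws per-subject ROI time series from zero-mean multivariate
# Gaussians whose population correlation matrix is a common block-modular
# base plus group-specific deltas on a planted edge set, then contaminates
# the signals with shared latent nuisance sources (mirrored in a stand-in
# white-matter/CSF noise pool) and a motion-locked artifact, so that the
# conditioning, connectome, selection, classification and permutation stages
# can all be exercised end-to-end with known ground truth.

#' Specify a synthetic cohort
#'
#' Defaults emulate the structure of the modeled study: 38 healthy controls,
#' 43 PD patients without mild cognitive impairment (PD-nonMCI) and 27 with
#' it (PD-MCI), 246 network nodes, 295 retained frames at a 2-s sampling
#' interval, and a planted set of 21 discriminating edges (16 with reduced,
#' 5 with increased connectivity in PD-MCI relative to the other groups).
#'
#' @param n_hc,n_pd_nonmci,n_pd_mci group sizes.
#' @param n_nodes number of network nodes.
#' @param n_frames retained frames per subject (first-volume trimming is
#'   assumed to have happened upstream; series arrive already trimmed).
#' @param tr_seconds sampling interval in seconds.
#' @param signal_edges `NULL` for the default planted set, or a data frame
#'   with columns `i`, `j` (node pair, `i < j`), `delta` (correlation shift
#'   applied to the PD-MCI group) and optionally `direction`
#'   (`"decrease"`/`"increase"`, checked against the sign of `delta`).
#' @param n_signal_decrease,n_signal_increase,effect_delta used only when
#'   `signal_edges` is `NULL`: number of planted decreased/increased edges
#'   and the absolute correlation shift.
#' @param n_noise_components number of latent nuisance sources shared by the
#'   ROI signals and the noise pool.
#' @param n_noise_voxels voxels in the simulated noise pool.
#' @param contamination_weight unitless mixing coefficient of the latent
#'   nuisance sources into the ROI signals.
#' @param motion_scale typical per-frame translation increment (mm);
#'   rotation increments are scaled to 0.4 of this value (degrees),
#'   matching the relative magnitudes of the modeled cohort.
#' @param motion_coupling amplitude of the motion-locked signal artifact.
#' @param neuropsych_effects named per-domain downward shift (in HC SD
#'   units) of the PD-MCI domain latents; defaults follow the composite
#'   score gaps observed between patient groups in the modeled cohort.
#' @param seed RNG seed; same seed, same cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 38, n_pd_nonmci = 43, n_pd_mci = 27,
                        n_nodes = 246, n_frames = 295, tr_seconds = 2,
                        signal_edges = NULL,
                        n_signal_decrease = 16, n_signal_increase = 5,
                        effect_delta = 0.35,
                        n_noise_components = 10, n_noise_voxels = 120,
                        contamination_weight = 0.6,
                        motion_scale = 0.05, motion_coupling = 0.8,
                        neuropsych_effects = c(attention = 0, executive = 1.7,
                                               visuospatial = 1.3, memory = 0.9),
                        seed = 1L) {
  counts <- c(n_hc = n_hc, n_pd_nonmci = n_pd_nonmci, n_pd_mci = n_pd_mci,
              n_nodes = n_nodes, n_frames = n_frames,
              n_noise_components = n_noise_components,
              n_noise_voxels = n_noise_voxels)
  if (any(counts <= 0)) {
    stop("all counts must be positive; offending: ",
         paste(names(counts)[counts <= 0], collapse = ", "))
  }
  if (n_nodes < 8) stop("n_nodes must be at least 8")
  base <- base_correlation(n_nodes)
  if (is.null(signal_edges)) {
    signal_edges <- with_seed(seed, {
      default_signal_edges(n_nodes, n_signal_decrease, n_signal_increase,
                           effect_delta)
    })
  } else {
    signal_edges <- as.data.frame(signal_edges)
    stopifnot(all(c("i", "j", "delta") %in% names(signal_edges)))
    if (any(signal_edges$i >= signal_edges$j))
      stop("signal edges must have i < j")
    if (!is.null(signal_edges$direction)) {
      ok <- ifelse(signal_edges$direction == "decrease",
                   signal_edges$delta <= 0, signal_edges$delta >= 0)
      if (!all(ok)) stop("effect_delta sign must match direction")
    }
  }
  signal_edges$direction <- ifelse(signal_edges$delta < 0, "decrease", "increase")
  r0 <- base[cbind(signal_edges$i, signal_edges$j)]
  bad <- which(abs(r0 + signal_edges$delta) >= 1)
  if (length(bad) > 0) {
    stop(sprintf("edge (%d,%d): baseline %.2f + delta %.2f leaves [-1,1]",
                 signal_edges$i[bad[1]], signal_edges$j[bad[1]],
                 r0[bad[1]], signal_edges$delta[bad[1]]))
  }
  spec <- list(n_hc = n_hc, n_pd_nonmci = n_pd_nonmci, n_pd_mci = n_pd_mci,
               n_nodes = n_nodes, n_frames = n_frames, tr_seconds = tr_seconds,
               signal_edges = signal_edges,
               n_noise_components = n_noise_components,
               n_noise_voxels = n_noise_voxels,
               contamination_weight = contamination_weight,
               motion_scale = motion_scale, motion_coupling = motion_coupling,
               neuropsych_effects = neuropsych_effects, seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

# Block-modular base correlation: 7 contiguous communities, within-block
# r = 0.3, between-block r = 0.05, unit diagonal.
base_correlation <- function(n_nodes, n_blocks = 7,
                             r_within = 0.3, r_between = 0.05) {
  block <- block_assignment(n_nodes, n_blocks)
  same <- outer(block, block, "==")
  m <- ifelse(same, r_within, r_between)
  diag(m) <- 1
  m
}

block_assignment <- function(n_nodes, n_blocks = 7) {
  sizes <- diff(round(seq(0, n_nodes, length.out = n_blocks + 1)))
  rep(seq_len(n_blocks), times = sizes)
}

# Default planted edges: node pairs sampled uniformly over the whole
# network (the emulated effect pattern spans many regions rather than
# concentrating inside communities), decreases first, then increases.
default_signal_edges <- function(n_nodes, n_dec, n_inc, effect_delta) {
  map <- edge_index_map(n_nodes)
  pick <- sample(nrow(map), n_dec + n_inc)
  data.frame(i = map$i[pick], j = map$j[pick],
             delta = c(rep(-effect_delta, n_dec), rep(effect_delta, n_inc)))
}

# Deterministic positive-definiteness repair: clip eigenvalues at 1e-6,
# reconstruct, renormalize to unit diagonal.
repair_correlation <- function(m, floor = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values > floor)) return(m)
  v <- pmax(e$values, floor)
  m2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m2))
  m2 <- m2 / outer(d, d)
  diag(m2) <- 1
  (m2 + t(m2)) / 2
}

#' Generate a synthetic cohort
#'
#' Draws every subject's ROI time series, motion trace and noise pool, plus
#' demographics and clinical scores, from the model described in
#' [cohort_spec()]. The HC and PD-nonMCI groups share the base population
#' correlation matrix; the PD-MCI group receives the planted edge deltas.
#' Latent nuisance sources enter both the ROI signals (scaled by
#' `contamination_weight`) and the noise pool; a framewise-displacement-locked
#' artifact enters both, so nuisance regression can recover clean networks.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `pd_cohort`: a list with `spec`, `subjects`
#'   (each holding `record`, `roi_series` (nodes x frames), `motion_params`
#'   (frames x 6: 3 translations mm, 3 rotations degrees), `noise_pool`
#'   (voxels x frames)), and `truth` (ground-truth group labels, planted
#'   edges with their edge-map indices, and the target population
#'   correlation matrices) kept separate from the pipeline inputs.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_hc + spec$n_pd_nonmci + spec$n_pd_mci
  groups <- rep(c("HC", "PD-nonMCI", "PD-MCI"),
                times = c(spec$n_hc, spec$n_pd_nonmci, spec$n_pd_mci))
  base <- repair_correlation(base_correlation(spec$n_nodes))
  mci <- base_correlation(spec$n_nodes)
  idx <- cbind(spec$signal_edges$i, spec$signal_edges$j)
  mci[idx] <- mci[idx] + spec$signal_edges$delta
  mci[idx[, 2:1, drop = FALSE]] <- mci[idx]
  mci <- repair_correlation(mci)
  chol_by_group <- list("HC" = chol(base), "PD-nonMCI" = chol(base),
                        "PD-MCI" = chol(mci))
  k <- spec$n_noise_components
  subjects <- vector("list", n)
  for (s in seq_len(n)) {
    g <- groups[s]
    z <- matrix(rnorm(spec$n_frames * spec$n_nodes), spec$n_frames)
    roi <- t(z %*% chol_by_group[[g]])
    latent <- matrix(rnorm(k * spec$n_frames), k)
    load_roi <- matrix(rnorm(spec$n_nodes * k), ncol = k) / sqrt(k)
    roi <- roi + spec$contamination_weight * load_roi %*% latent
    motion <- simulate_motion(spec$n_frames, spec$motion_scale)
    fd <- framewise_displacement(motion)$fd
    m <- c(0, fd)
    m <- (m - mean(m)) / max(sd(m), 1e-12)
    gain_roi <- rnorm(spec$n_nodes, 1, 0.3)
    roi <- roi + spec$motion_coupling * outer(gain_roi, m)
    load_pool <- matrix(rnorm(spec$n_noise_voxels * k), ncol = k)
    gain_pool <- rnorm(spec$n_noise_voxels, 1, 0.3)
    pool <- load_pool %*% latent +
      spec$motion_coupling * outer(gain_pool, m) +
      0.5 * matrix(rnorm(spec$n_noise_voxels * spec$n_frames),
                   spec$n_noise_voxels)
    subjects[[s]] <- list(
      record = subject_record(s, g),
      roi_series = roi,
      motion_params = motion,
      noise_pool = pool
    )
  }
  map <- edge_index_map(spec$n_nodes)
  planted <- spec$signal_edges
  planted$edge <- pair_to_edge(planted$i, planted$j, spec$n_nodes)
  cohort <- list(spec = spec, subjects = subjects,
                 truth = list(group = groups, signal_edges = planted,
                              sigma = list("HC" = base, "PD-nonMCI" = base,
                                           "PD-MCI" = mci)))
  class(cohort) <- "pd_cohort"
  cohort
}

# Demographics and clinical scores drawn to match the modeled cohort's
# group-wise summaries (age, education, sex ratio, disease duration, LEDD,
# UPDRS, Hoehn & Yahr stage distribution).
subject_record <- function(id, group) {
  par <- switch(group,
    "HC"        = list(age = c(63.3, 10.3), edu = c(11.5, 4.5), pf = 17 / 38),
    "PD-nonMCI" = list(age = c(63.6, 9.5),  edu = c(11.9, 5.2), pf = 19 / 43),
    "PD-MCI"    = list(age = c(66.5, 11.1), edu = c(10.0, 5.5), pf = 10 / 27))
  rec <- data.frame(
    subject_id = sprintf("S%03d", id), group = group,
    age = round(rnorm_trunc(1, par$age[1], par$age[2], 40, 90), 1),
    sex = as.integer(runif(1) < par$pf),
    education = round(rnorm_trunc(1, par$edu[1], par$edu[2], 0, 25)),
    ledd = NA_real_, disease_duration = NA_real_, updrs = NA_real_,
    hy = NA_real_, stringsAsFactors = FALSE)
  if (group != "HC") {
    cp <- switch(group,
      "PD-nonMCI" = list(dur = c(5.9, 4.0), ledd = c(646.7, 434.2),
                         updrs = c(14.6, 7.2), hy = c(11, 5, 22, 3, 2)),
      "PD-MCI"    = list(dur = c(10.1, 7.2), ledd = c(950.7, 555.2),
                         updrs = c(16.8, 11.0), hy = c(4, 0, 15, 3, 5)))
    rec$disease_duration <- round(rnorm_trunc(1, cp$dur[1], cp$dur[2], 0.5, 40), 1)
    rec$ledd <- round(rnorm_trunc(1, cp$ledd[1], cp$ledd[2], 0, 4000))
    rec$updrs <- round(rnorm_trunc(1, cp$updrs[1], cp$updrs[2], 0, 80))
    rec$hy <- sample(c(1, 1.5, 2, 2.5, 3), 1, prob = cp$hy / sum(cp$hy))
  }
  rec
}

# Motion trace: AR(1) per-frame absolute increments with occasional spikes,
# integrated into positions. Translations in mm, rotations in degrees.
simulate_motion <- function(n_frames, motion_scale, ar = 0.4,
                            spike_prob = 0.02, spike_mult = 8) {
  one <- function(scale) {
    innov <- rnorm(n_frames, 0, scale)
    spikes <- runif(n_frames) < spike_prob
    innov[spikes] <- innov[spikes] * spike_mult
    d <- as.numeric(stats::filter(innov, ar, method = "recursive"))
    cumsum(d)
  }
  motion <- cbind(one(motion_scale), one(motion_scale), one(motion_scale),
                  one(0.4 * motion_scale), one(0.4 * motion_scale),
                  one(0.4 * motion_scale))
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  motion
}

#' Generate neuropsychological scores for a cohort
#'
#' Eight test scores (two per cognitive domain: attention/working memory,
#' executive, visuospatial/visuoperceptual, memory) are generated as a
#' linear age/sex/education trend plus a per-subject domain latent plus
#' noise, all oriented so that higher is better. PD-MCI domain latents are
#' shifted down by `spec$neuropsych_effects` (HC SD units).
#'
#' @param spec the [cohort_spec()] used to generate `cohort`.
#' @param cohort a [generate_cohort()] result.
#' @return data frame with subject id, group, demographics and the 8 test
#'   scores; the battery layout is available via [neuropsych_battery()].
#' @export
generate_neuropsych <- function(spec, cohort) {
  stopifnot(inherits(cohort, "pd_cohort"))
  battery <- neuropsych_battery()
  n_par <- 4 # intercept + age + sex + education
  if (spec$n_hc <= n_par)
    stop("need more HC subjects than regression parameters (", n_par, ")")
  records <- do.call(rbind, lapply(cohort$subjects, `[[`, "record"))
  n <- nrow(records)
  eff <- spec$neuropsych_effects
  domains <- unique(battery$domain)
  out <- records[, c("subject_id", "group", "age", "sex", "education")]
  for (d in domains) {
    shift <- ifelse(records$group == "PD-MCI", -(eff[[d]] %||% 0), 0)
    latent <- rnorm(n, shift, 0.6)
    for (test in battery$test[battery$domain == d]) {
      out[[test]] <- -0.02 * (records$age - 64) +
        0.05 * (records$education - 11) - 0.1 * records$sex +
        latent + rnorm(n, 0, 0.5)
    }
  }
  out
}

#' Battery layout: 8 tests in 4 domains
#'
#' Two tests per domain, named after the instruments of the modeled battery
#' (digit span backward-minus-forward and Stroop interference for
#' attention/working memory; Trail-Making A-minus-B and phonemic fluency for
#' executive function; visual form discrimination and line orientation for
#' visuospatial/visuoperceptual function; verbal learning total and delayed
#' recall for memory). `direction = 1` means scores are already oriented
#' higher-is-better (the generator emits them that way; real batteries may
#' need `-1` for time-based scores).
#'
#' @return data frame with columns `test`, `domain`, `direction`.
#' @export
neuropsych_battery <- function() {
  data.frame(
    test = c("digit_span_diff", "stroop_interference",
             "tmt_a_minus_b", "phonemic_fluency",
             "form_discrimination", "line_orientation",
             "verbal_learning_total", "delayed_recall"),
    domain = rep(c("attention", "executive", "visuospatial", "memory"),
                 each = 2),
    direction = 1,
    stringsAsFactors = FALSE)
}

#' Write a cohort to the on-disk layout the pipeline reads
#'
#' Creates `subjects.tsv`, `neuropsych.tsv`, `cohort.yaml` and per-subject
#' `roi_<id>.tsv` (nodes x frames), `motion_<id>.tsv` (frames x 6) and
#' `noisepool_<id>.tsv` (voxels x frames) under `dir`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param neuropsych a [generate_neuropsych()] table.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, neuropsych, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- do.call(rbind, lapply(cohort$subjects, `[[`, "record"))
  write.table(records, file.path(dir, "subjects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(neuropsych, file.path(dir, "neuropsych.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  spec <- cohort$spec
  spec$signal_edges <- NULL # planted truth stays out of pipeline inputs
  yaml::write_yaml(unclass(spec), file.path(dir, "cohort.yaml"))
  for (s in cohort$subjects) {
    id <- s$record$subject_id
    write.table(s$roi_series, file.path(dir, sprintf("roi_%s.tsv", id)),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(s$motion_params, file.path(dir, sprintf("motion_%s.tsv", id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(s$noise_pool, file.path(dir, sprintf("noisepool_%s.tsv", id)),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from the on-disk layout
#'
#' @param dir directory written by [write_cohort()].
#' @return list with `records`, `neuropsych`, `spec` (as a plain list) and
#'   `subjects` (roi_series/motion_params/noise_pool per subject). Ground
#'   truth is not on disk and is not returned.
#' @export
read_cohort <- function(dir) {
  records <- read.delim(file.path(dir, "subjects.tsv"))
  neuropsych <- read.delim(file.path(dir, "neuropsych.tsv"))
  spec <- yaml::read_yaml(file.path(dir, "cohort.yaml"))
  subjects <- lapply(records$subject_id, function(id) {
    list(
      roi_series = as.matrix(read.delim(
        file.path(dir, sprintf("roi_%s.tsv", id)), header = FALSE)),
      motion_params = as.matrix(read.delim(
        file.path(dir, sprintf("motion_%s.tsv", id)))),
      noise_pool = as.matrix(read.delim(
        file.path(dir, sprintf("noisepool_%s.tsv", id)), header = FALSE))
    )
  })
  names(subjects) <- records$subject_id
  list(records = records, neuropsych = neuropsych, spec = spec,
       subjects = subjects)
}
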