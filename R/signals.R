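# Time-series conditioning and quality control.

#' Bandpass-filter ROI time series
#'
#' Zero-phase (forward-backward) Butterworth bandpass, order 4, applied to
#' each row. The band defaults to the conventional resting-state window of
#' 0.01-0.1 Hz. Zero-phase filtering avoids introducing lag distortion into
#' the correlation structure.
#'
#' @param series nodes x frames matrix (or a single numeric series).
#' @param tr_seconds sampling interval in seconds.
#' @param low_hz,high_hz passband edges in Hz.
#' @param order Butterworth prototype order.
#' @return filtered matrix of the same shape, DC removed.
#' @export
bandpass_filter <- function(series, tr_seconds, low_hz = 0.01, high_hz = 0.1,
                            order = 4) {
  if (is.vector(series)) series <- matrix(series, nrow = 1)
  n_frames <- ncol(series)
  min_frames <- 3 * (2 * order) # bandpass doubles the effective order
  if (n_frames <= min_frames)
    stop("series too short for stable filtering: need more than ",
         min_frames, " frames, got ", n_frames)
  nyquist <- 1 / (2 * tr_seconds)
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyquist))
    stop("need 0 < low_hz < high_hz < Nyquist (", nyquist, " Hz)")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  series <- series - rowMeans(series) # demean first: shorter filter transients
  out <- t(apply(series, 1, function(x) signal::filtfilt(bf, x)))
  dimnames(out) <- dimnames(series)
  out
}

#' First eigenvariate of a voxel set
#'
#' Leading singular-triplet time course of the row-centered voxel x frame
#' matrix (each voxel's mean removed), sign-fixed so the sum of voxel
#' weights is positive, and scaled to unit variance.
#'
#' @param voxel_series voxels x frames matrix.
#' @return numeric time series of length `ncol(voxel_series)`.
#' @export
first_eigenvariate <- function(voxel_series) {
  if (is.vector(voxel_series)) voxel_series <- matrix(voxel_series, nrow = 1)
  stopifnot(nrow(voxel_series) >= 1, ncol(voxel_series) >= 2)
  xc <- voxel_series - rowMeans(voxel_series)
  if (max(abs(xc)) < 1e-12)
    stop("all voxel series are constant: eigenvariate undefined")
  sv <- svd(xc, nu = 1, nv = 1)
  ts <- sv$v[, 1]
  if (sum(sv$u[, 1]) < 0) ts <- -ts
  as.numeric(ts / sd(ts))
}

#' Anatomical component-based nuisance components (aCompCor)
#'
#' Principal-component scores of the variance-normalized, centered noise
#' pool (stand-in for combined white-matter and CSF voxels), ordered by
#' explained variance. The first `n_components` score series are returned
#' as nuisance regressors.
#'
#' @param noise_pool voxels x frames matrix.
#' @param n_components number of components to keep (default 10).
#' @return list of class `nuisance_components` with `components`
#'   (`n_components` x frames), `explained_variance` (fraction per retained
#'   component) and `rank_deficient` flag (TRUE when fewer than
#'   `n_components` informative components exist; the available ones are
#'   returned).
#' @export
compute_acompcor <- function(noise_pool, n_components = 10) {
  v <- nrow(noise_pool); t <- ncol(noise_pool)
  if (v < n_components)
    stop("need at least n_components (", n_components, ") voxels, got ", v)
  if (t <= n_components)
    stop("need more than n_components frames, got ", t)
  xc <- noise_pool - rowMeans(noise_pool)
  s <- sqrt(rowMeans(xc^2))
  keep <- s > 1e-12
  xc <- xc[keep, , drop = FALSE] / s[keep]
  sv <- svd(t(xc)) # frames x voxels; scores live in u * d
  ev <- sv$d^2 / sum(sv$d^2)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  k <- min(n_components, rank)
  comps <- t(sv$u[, seq_len(k), drop = FALSE] *
               rep(sv$d[seq_len(k)], each = t))
  structure(list(components = comps,
                 explained_variance = ev[seq_len(k)],
                 rank_deficient = rank < n_components),
            class = "nuisance_components")
}

#' Framewise displacement and motion summaries
#'
#' `fd[t]` is the sum of absolute interframe translation changes (mm) plus
#' the sum of absolute interframe rotation changes converted to arc length
#' on a 50-mm sphere, following the convention of Power-style framewise
#' displacement. Summary translations/rotations are the Euclidean norms of
#' the three interframe translation/rotation deltas.
#'
#' @param motion_params frames x 6 matrix or data frame: three translations
#'   (mm) then three rotations (degrees).
#' @param radius_mm sphere radius for the rotation-to-displacement
#'   conversion.
#' @return list of class `motion_summary` with `fd` (length frames - 1),
#'   `mean_translation`, `max_translation` (mm), `mean_rotation`,
#'   `max_rotation` (degrees).
#' @export
framewise_displacement <- function(motion_params, radius_mm = 50) {
  m <- as.matrix(motion_params)
  stopifnot(ncol(m) == 6)
  if (!all(is.finite(m))) stop("non-finite motion parameters")
  dtrans <- diff(m[, 1:3, drop = FALSE])
  drot <- diff(m[, 4:6, drop = FALSE])
  fd <- rowSums(abs(dtrans)) + rowSums(abs(drot)) * pi / 180 * radius_mm
  trans_step <- sqrt(rowSums(dtrans^2))
  rot_step <- sqrt(rowSums(drot^2))
  structure(list(fd = as.numeric(fd),
                 mean_translation = mean(trans_step),
                 max_translation = max(trans_step),
                 mean_rotation = mean(rot_step),
                 max_rotation = max(rot_step)),
            class = "motion_summary")
}

#' Motion-based exclusion decision
#'
#' A subject is excluded when mean interframe motion reaches 0.3 mm
#' translation or 0.3 degrees rotation, or maximum interframe motion reaches
#' 1 mm translation or 1 degree rotation (all thresholds inclusive).
#'
#' @param summary a [framewise_displacement()] result.
#' @param mean_trans_mm,mean_rot_deg,max_trans_mm,max_rot_deg thresholds.
#' @return list with `keep` (logical) and `reason` (character vector naming
#'   every violated threshold, empty when kept).
#' @export
motion_exclude <- function(summary, mean_trans_mm = 0.3, mean_rot_deg = 0.3,
                           max_trans_mm = 1, max_rot_deg = 1) {
  stopifnot(inherits(summary, "motion_summary"))
  reasons <- c(
    if (summary$mean_translation >= mean_trans_mm) "mean translation",
    if (summary$mean_rotation >= mean_rot_deg) "mean rotation",
    if (summary$max_translation >= max_trans_mm) "max translation",
    if (summary$max_rotation >= max_rot_deg) "max rotation")
  list(keep = length(reasons) == 0, reason = reasons %||% character(0))
}

#' Regress nuisance covariates out of ROI series
#'
#' Least-squares residualization of each node series against an intercept
#' plus the supplied covariates (typically 10 aCompCor components and the 6
#' motion parameters).
#'
#' @param series nodes x frames matrix.
#' @param covariates frames x k matrix, or a `nuisance_components` object,
#'   or a list of such pieces that are column-bound.
#' @return residual series, nodes x frames.
#' @export
regress_nuisance <- function(series, covariates) {
  x <- covariate_design(covariates, ncol(series))
  qr_x <- qr(x)
  t(qr.resid(qr_x, t(series)))
}

# Assemble a frames x k covariate design (with intercept) from matrices,
# nuisance_components objects, or lists thereof.
covariate_design <- function(covariates, n_frames) {
  pieces <- if (is.list(covariates) && !inherits(covariates, "nuisance_components"))
    covariates else list(covariates)
  mats <- lapply(pieces, function(p) {
    if (inherits(p, "nuisance_components")) return(t(p$components))
    m <- as.matrix(p)
    if (nrow(m) != n_frames && ncol(m) == n_frames) m <- t(m)
    m
  })
  x <- do.call(cbind, mats)
  if (nrow(x) != n_frames)
    stop("covariates do not match the number of frames (", n_frames, ")")
  cbind(1, x)
}

#' Coupling between framewise displacement and signal change, before and
#' after nuisance regression
#'
#' Percent signal change is summarized per frame pair as the root mean
#' square of the temporal derivative across nodes (a DVARS-like index);
#' the returned values are its Pearson correlations with framewise
#' displacement for the raw and the nuisance-regressed series. Effective
#' noise correction drives the second value toward zero.
#'
#' @param roi_before,roi_after nodes x frames matrices sharing frames.
#' @param motion_params frames x 6 motion table.
#' @return list with `r_before` and `r_after`.
#' @export
qc_fd_signal_coupling <- function(roi_before, roi_after, motion_params) {
  stopifnot(ncol(roi_before) == ncol(roi_after))
  if (ncol(roi_before) < 10) stop("need at least 10 frames for the QC statistic")
  fd <- framewise_displacement(motion_params)$fd
  dvars <- function(x) sqrt(colMeans((x[, -1, drop = FALSE] -
                                        x[, -ncol(x), drop = FALSE])^2))
  list(r_before = cor(fd, dvars(roi_before)),
       r_after = cor(fd, dvars(roi_after)))
}

#' Quality-control report for a cohort
#'
#' One row per subject: motion summaries, keep/exclude decision with
#' reason, and the FD-signal coupling before and after nuisance
#' regression (aCompCor components plus motion parameters).
#'
#' @param cohort a [generate_cohort()] result or [read_cohort()] list.
#' @param n_components aCompCor components to regress.
#' @return data frame, one row per subject.
#' @export
qc_report <- function(cohort, n_components = 10) {
  subjects <- cohort$subjects
  ids <- vapply(seq_along(subjects), function(s) {
    rec <- subjects[[s]]$record
    if (is.null(rec)) names(subjects)[s] else rec$subject_id
  }, character(1))
  rows <- lapply(seq_along(subjects), function(s) {
    sub <- subjects[[s]]
    ms <- framewise_displacement(sub$motion_params)
    dec <- motion_exclude(ms)
    comps <- compute_acompcor(sub$noise_pool, n_components)
    cleaned <- regress_nuisance(sub$roi_series,
                                list(comps, sub$motion_params))
    qc <- qc_fd_signal_coupling(sub$roi_series, cleaned, sub$motion_params)
    data.frame(subject_id = ids[s],
               mean_translation = ms$mean_translation,
               mean_rotation = ms$mean_rotation,
               max_translation = ms$max_translation,
               max_rotation = ms$max_rotation,
               keep = dec$keep,
               reason = paste(dec$reason, collapse = "; "),
               r_before = qc$r_before, r_after = qc$r_after,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
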