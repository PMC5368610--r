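# Stability selection: randomized L1-penalized logistic regression over
# stratified data subsamples. This is the feature-selection engine of the
# classification pipeline: edges repeatedly assigned nonzero coefficients
# across subsamples receive high selection scores.

#' Stability selection via randomized L1 logistic regression
#'
#' For each of `n_iterations` iterations a stratified random subsample of
#' `subsample_fraction` of the subjects is drawn without replacement,
#' features are standardized within the subsample, each feature's penalty
#' is optionally rescaled by a random factor in `{weakness, 1}` (the
#' randomized-lasso construction, implemented by rescaling the feature
#' columns), and an L1-penalized logistic regression is fitted; features
#' with nonzero coefficients are recorded. A feature's score is the
#' fraction of iterations in which it was selected.
#'
#' The L1 strength is parameterized as the inverse-regularization `base_c`
#' (penalty `lambda = 1 / (base_c * n_subsample)`), defaulting to 1;
#' neither this nor the selection threshold has a canonical published
#' value, so both are exposed as configuration with these documented
#' defaults.
#'
#' @param features subjects x edges numeric matrix.
#' @param labels two-level factor (or coercible) of group labels.
#' @param n_iterations number of subsample fits (default 200).
#' @param subsample_fraction fraction of subjects per subsample (default
#'   0.75), drawn per class so both classes keep at least 2 subjects.
#' @param selection_threshold score at or above which an edge counts as
#'   selected (default 0.25, the historical randomized-lasso default).
#' @param weakness penalty-randomization factor in (0, 1]; `1` disables
#'   the randomization.
#' @param base_c inverse regularization strength of the base L1 fit.
#' @param seed optional seed; `NULL` uses (and advances) the ambient RNG
#'   stream.
#' @return object of class `selection_profile`: list with `scores`
#'   (per-edge selection frequency in `[0, 1]`), the configuration, and
#'   `n_subjects`.
#' @export
rlr_select <- function(features, labels, n_iterations = 200,
                       subsample_fraction = 0.75,
                       selection_threshold = 0.25, weakness = 0.5,
                       base_c = 1, seed = NULL) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("degenerate labels: need two classes")
  if (nlevels(labels) > 2) stop("binary labels required")
  n <- nrow(features); p <- ncol(features)
  cls <- split(seq_len(n), labels)
  n_take <- pmax(2, round(vapply(cls, length, 1L) * subsample_fraction))
  if (any(vapply(cls, length, 1L) < 2))
    stop("need at least 2 subjects per class")
  const <- apply(features, 2, function(x) max(x) - min(x)) < 1e-12
  if (any(const))
    warning(sum(const), " constant feature column(s): score 0 by construction")
  y <- as.integer(labels) - 1L
  with_seed(seed, {
    counts <- numeric(p)
    for (it in seq_len(n_iterations)) {
      idx <- unlist(lapply(seq_along(cls), function(k) {
        pool <- cls[[k]]
        if (n_take[k] >= length(pool)) pool else
          pool[sample.int(length(pool), n_take[k])]
      }), use.names = FALSE)
      x <- safe_scale(features[idx, , drop = FALSE])
      if (weakness < 1) {
        w <- sample(c(weakness, 1), p, replace = TRUE)
        x <- sweep(x, 2, w, "*")
      }
      lam <- 1 / (base_c * length(idx))
      # small desk-scale subsamples trip glmnet's class-size caution; the
      # stratified draw already guarantees both classes are present
      fit <- withCallingHandlers(
        glmnet::glmnet(x, y[idx], family = "binomial", alpha = 1,
                       lambda = c(4 * lam, 2 * lam, lam),
                       standardize = FALSE),
        warning = function(w) {
          if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      beta <- fit$beta[, ncol(fit$beta)]
      counts[beta != 0] <- counts[beta != 0] + 1
    }
    structure(list(scores = counts / n_iterations,
                   n_iterations = n_iterations,
                   subsample_fraction = subsample_fraction,
                   selection_threshold = selection_threshold,
                   weakness = weakness, base_c = base_c,
                   n_subjects = n, seed = seed),
              class = "selection_profile")
  })
}

#' Edges selected by a stability-selection profile
#'
#' Edges whose score meets the profile's selection threshold (inclusive),
#' sorted by descending score, ties broken by ascending edge index.
#'
#' @param profile a [rlr_select()] result.
#' @param threshold override of the profile's selection threshold.
#' @return integer vector of edge indices (possibly empty, with a warning).
#' @export
selected_edges <- function(profile, threshold = NULL) {
  stopifnot(inherits(profile, "selection_profile"))
  thr <- threshold %||% profile$selection_threshold
  # score-0 edges are never selected, even at threshold 0
  idx <- which(profile$scores >= thr & profile$scores > 0)
  if (length(idx) == 0) {
    warning("empty selection at threshold ", thr)
    return(integer(0))
  }
  idx[order(-profile$scores[idx], idx)]
}
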