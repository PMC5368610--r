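# Outer leave-one-out cross-validation with per-training-set feature
# selection, optional nested C tuning, class-weighted linear SVM, repeat
# aggregation, and the consensus feature funnel.

#' Cross-validated classification with per-fold stability selection
#'
#' For every left-out subject and every repeat: stability selection
#' ([rlr_select()]) runs on the remaining subjects only, the SVM cost is
#' tuned by nested LOOCV on the selected edges (or fixed, for scaled
#' runs), a class-weighted linear SVM is trained on the training set, and
#' the held-out subject is predicted. The held-out subject never
#' participates in feature selection or tuning. If a fold's selection is
#' empty, the 10 highest-scoring edges are used and the fold is flagged.
#'
#' @param features subjects x edges matrix (canonical edge order).
#' @param labels two-class labels.
#' @param n_repeats feature-selection/classification repeats per training
#'   set (default 10).
#' @param rlr list of arguments passed on to [rlr_select()]
#'   (e.g. `n_iterations`, `weakness`, `base_c`, `selection_threshold`).
#' @param tune_c if `TRUE`, tune the SVM cost per fold by nested LOOCV on
#'   the grid; otherwise use `fixed_c`.
#' @param fixed_c SVM cost when `tune_c = FALSE`.
#' @param c_grid grid for nested tuning.
#' @param pos_class positive class label.
#' @param seed RNG seed for the whole procedure.
#' @return object of class `classification_result`: per-repeat predictions,
#'   decision values, tuned costs, per-repeat metrics (accuracy, per-class
#'   accuracy, AUC), their means and SDs across repeats, the selection logs
#'   (`selected[[repeat]][[subject]]`), per-subject selection-score sums,
#'   and the [consensus_funnel()] of the run.
#' @export
loocv_pipeline <- function(features, labels, n_repeats = 10,
                           rlr = list(n_iterations = 200),
                           tune_c = FALSE, fixed_c = 1, c_grid = 10^(-3:2),
                           pos_class = "PD-MCI", seed = 1L) {
  features <- as.matrix(features)
  labels <- droplevels(factor(labels))
  stopifnot(nlevels(labels) == 2, ncol(features) >= 1)
  n <- nrow(features); p <- ncol(features)
  set.seed(seed)
  pred <- matrix(NA_character_, n, n_repeats)
  dec <- matrix(NA_real_, n, n_repeats)
  cost <- matrix(NA_real_, n, n_repeats)
  fallback <- matrix(FALSE, n, n_repeats)
  selected <- lapply(seq_len(n_repeats), function(r) vector("list", n))
  score_sum <- matrix(0, p, n) # summed selection scores per held-out subject
  for (r in seq_len(n_repeats)) {
    for (s in seq_len(n)) {
      x_tr <- features[-s, , drop = FALSE]
      y_tr <- labels[-s]
      profile <- do.call(rlr_select,
                         c(list(features = x_tr, labels = y_tr), rlr))
      sel <- suppressWarnings(selected_edges(profile))
      if (length(sel) == 0) {
        sel <- order(-profile$scores)[seq_len(min(10, p))]
        fallback[s, r] <- TRUE
      }
      selected[[r]][[s]] <- sel
      score_sum[, s] <- score_sum[, s] + profile$scores
      x_sel <- x_tr[, sel, drop = FALSE]
      cc <- if (tune_c) tune_c_nested(x_sel, y_tr, c_grid, pos_class)$c
            else fixed_c
      cost[s, r] <- cc
      fit <- fit_weighted_svm(x_sel, y_tr, cc, pos_class)
      pr <- predict_weighted_svm(fit, features[s, sel, drop = FALSE])
      pred[s, r] <- pr$label
      dec[s, r] <- pr$decision
    }
  }
  per_repeat <- lapply(seq_len(n_repeats), function(r) {
    classification_metrics(pred[, r], dec[, r], labels, pos_class)
  })
  acc <- vapply(per_repeat, `[[`, numeric(1), "accuracy")
  auc <- vapply(per_repeat, `[[`, numeric(1), "auc")
  per_class <- t(vapply(per_repeat, `[[`,
                        numeric(length(per_repeat[[1]]$per_class)),
                        "per_class"))
  funnel <- consensus_funnel(selected, n_edges = p)
  structure(list(
    predictions = pred, decision_values = dec, cost = cost,
    fallback = fallback, labels = labels, pos_class = pos_class,
    selected = selected, score_sum = score_sum,
    per_repeat = list(accuracy = acc, auc = auc, per_class = per_class),
    summary = list(
      mean_accuracy = mean(acc), sd_accuracy = sd(acc),
      mean_auc = mean(auc), sd_auc = sd(auc),
      mean_per_class = colMeans(per_class),
      sd_per_class = apply(per_class, 2, sd)),
    funnel = funnel, n_repeats = n_repeats, seed = seed),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("LOOCV classification over", nrow(x$predictions), "subjects,",
      x$n_repeats, "repeat(s)\n")
  cat(sprintf("  mean accuracy: %.1f%% (SD %.1f)\n",
              x$summary$mean_accuracy, x$summary$sd_accuracy))
  cat(sprintf("  mean AUC: %.3f (SD %.3f)\n",
              x$summary$mean_auc, x$summary$sd_auc))
  pc <- x$summary$mean_per_class
  cat("  per-class accuracy:",
      paste(sprintf("%s %.1f%%", names(pc), pc), collapse = ", "), "\n")
  cat(sprintf("  funnel: %d any / %d all-repeats / %d consensus\n",
              length(x$funnel$tier_any), length(x$funnel$tier_all_repeats),
              length(x$funnel$tier_consensus)))
  invisible(x)
}

#' Consensus feature funnel
#'
#' Tiers of selection stability across training sets and repeats:
#' `tier_any` (selected in at least one repeat of at least one training
#' set), `tier_all_repeats` (selected in all repeats of at least one
#' training set), `tier_consensus` (selected, in every repeat, by at least
#' `consensus_frac` of the training sets), and `per_subject` (for each
#' held-out subject, the edges selected in at least `per_subject_frac` of
#' that subject's repeats -- the fixed feature sets of the first null
#' model). All thresholds are inclusive.
#'
#' @param selections nested list `selections[[repeat]][[subject]]` of edge
#'   index vectors (complete: every repeat x training set present).
#' @param n_edges total number of edges in the feature space.
#' @param consensus_frac training-set fraction for the consensus tier
#'   (default 0.8).
#' @param per_subject_frac repeat fraction for the per-subject tier
#'   (default 0.8, i.e. >= 8 of 10 repeats).
#' @return object of class `feature_funnel` with the four tiers and the
#'   selection count matrix (`counts[edge, subject]` = number of repeats
#'   selecting that edge in that subject's training fold).
#' @export
consensus_funnel <- function(selections, n_edges, consensus_frac = 0.8,
                             per_subject_frac = 0.8) {
  n_repeats <- length(selections)
  stopifnot(n_repeats >= 1)
  n_subj <- length(selections[[1]])
  ok <- all(vapply(selections, function(r)
    length(r) == n_subj && !any(vapply(r, is.null, logical(1))), logical(1)))
  if (!ok) stop("incomplete selection logs: every repeat x training set required")
  counts <- matrix(0L, n_edges, n_subj)
  sel_all <- matrix(TRUE, n_edges, n_subj) # selected in every repeat so far
  frac_per_repeat <- matrix(0, n_edges, n_repeats)
  for (r in seq_len(n_repeats)) {
    this <- matrix(FALSE, n_edges, n_subj)
    for (s in seq_len(n_subj)) this[selections[[r]][[s]], s] <- TRUE
    counts <- counts + this
    sel_all <- sel_all & this
    frac_per_repeat[, r] <- rowMeans(this)
  }
  tier_any <- which(rowSums(counts) > 0)
  tier_all_repeats <- which(rowSums(sel_all) > 0)
  tier_consensus <- which(apply(frac_per_repeat >= consensus_frac, 1, all))
  min_rep <- ceiling(per_subject_frac * n_repeats)
  per_subject <- lapply(seq_len(n_subj), function(s)
    which(counts[, s] >= min_rep))
  structure(list(tier_any = tier_any, tier_all_repeats = tier_all_repeats,
                 tier_consensus = tier_consensus, per_subject = per_subject,
                 counts = counts, n_repeats = n_repeats),
            class = "feature_funnel")
}

#' Train the final model on consensus edges and classify a validation sample
#'
#' A single class-weighted linear SVM is trained on the whole training
#' sample restricted to the supplied (consensus) edges, with the cost tuned
#' by nested LOOCV on the training sample (mirroring the inner procedure),
#' and applied to the validation sample.
#'
#' @param train_features,train_labels training sample.
#' @param validation_features,validation_labels validation sample; columns
#'   must use the identical edge index map as the training features.
#' @param edges edge indices (nonempty) to use as features.
#' @param tune_c,fixed_c,c_grid cost handling as in [loocv_pipeline()].
#' @param pos_class positive class label.
#' @return list with `metrics` ([classification_metrics()] on the
#'   validation sample), `predictions`, `decision_values`, `cost`.
#' @export
fit_final_and_validate <- function(train_features, train_labels,
                                   validation_features, validation_labels,
                                   edges, tune_c = TRUE, fixed_c = 1,
                                   c_grid = 10^(-3:2),
                                   pos_class = "PD-MCI") {
  if (length(edges) == 0) stop("consensus edge set is empty")
  if (ncol(train_features) != ncol(validation_features))
    stop("edge-map mismatch: training has ", ncol(train_features),
         " edges, validation has ", ncol(validation_features))
  x_tr <- as.matrix(train_features)[, edges, drop = FALSE]
  x_va <- as.matrix(validation_features)[, edges, drop = FALSE]
  cc <- if (tune_c) tune_c_nested(x_tr, train_labels, c_grid, pos_class)$c
        else fixed_c
  fit <- fit_weighted_svm(x_tr, factor(train_labels), cc, pos_class)
  pr <- predict_weighted_svm(fit, x_va)
  list(metrics = classification_metrics(pr$label, pr$decision,
                                        validation_labels, pos_class),
       predictions = pr$label, decision_values = pr$decision, cost = cc)
}
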