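# The three classification null models: label reshuffling with fixed
# per-subject features, label reshuffling with full reselection, and
# feature-edge reshuffling for the validation model.

#' Null model 1: label permutation with fixed per-subject feature sets
#'
#' Group membership is reshuffled between the two patient groups and the
#' LOOCV class-weighted SVM procedure is repeated; each subject is
#' classified using the feature set identified for it by the observed run
#' (the per-subject funnel tier), so feature selection is not repeated.
#' The SVM cost is the observed run's (fixed features, fixed tuning);
#' permutations that would leave a training set single-class are redrawn.
#'
#' @param features subjects x edges matrix.
#' @param labels observed two-class labels (permuted internally).
#' @param per_subject_edges list (one per subject) of that subject's fixed
#'   feature-edge indices, e.g. `funnel$per_subject` from the observed
#'   [loocv_pipeline()] run; empty sets fall back to the subject's
#'   top-scoring edges when `score_sum` is supplied.
#' @param n_perms permutations (default 1000).
#' @param cost SVM cost: scalar, or per-subject vector from the observed
#'   run.
#' @param observed_accuracy observed accuracy (percent) to test against;
#'   optional.
#' @param score_sum optional edges x subjects selection-score matrix used
#'   to fill empty per-subject sets (top 10 by score).
#' @param pos_class positive class label.
#' @param seed RNG seed.
#' @return a `null_distribution` of accuracy (percent), greater tail.
#' @export
null_model_1 <- function(features, labels, per_subject_edges,
                         n_perms = 1000, cost = 1,
                         observed_accuracy = NA_real_, score_sum = NULL,
                         pos_class = "PD-MCI", seed = 1L) {
  features <- as.matrix(features)
  labels <- droplevels(factor(labels))
  n <- nrow(features)
  stopifnot(length(per_subject_edges) == n, nlevels(labels) == 2)
  cost <- rep_len(cost, n)
  feats <- lapply(seq_len(n), function(s) {
    e <- per_subject_edges[[s]]
    if (length(e) == 0) {
      if (is.null(score_sum)) stop("subject ", s, " has an empty feature set")
      e <- order(-score_sum[, s])[1:10]
    }
    features[, e, drop = FALSE]
  })
  set.seed(seed)
  draws <- vapply(seq_len(n_perms), function(i) {
    repeat { # redraw degenerate permutations (possible only with singleton classes)
      yp <- sample(labels)
      if (all(table(yp) >= 2)) break
    }
    correct <- vapply(seq_len(n), function(s) {
      fit <- fit_weighted_svm(feats[[s]][-s, , drop = FALSE], yp[-s],
                              cost[s], pos_class)
      predict_weighted_svm(fit, feats[[s]][s, , drop = FALSE])$label ==
        as.character(yp[s])
    }, logical(1))
    mean(correct) * 100
  }, numeric(1))
  p <- if (is.finite(observed_accuracy))
    perm_pvalue(observed_accuracy, draws, "greater") else NA_real_
  new_null_distribution(draws, observed_accuracy, "greater", p, seed,
                        statistic = "LOOCV accuracy (%), fixed features")
}

#' Null model 2: label permutation with full feature reselection
#'
#' Group membership is reshuffled and the entire procedure -- stability
#' selection inside every training fold, then class-weighted SVM
#' classification of the held-out subject -- is repeated at each reshuffle.
#' The held-out subject never enters selection, also under permutation, so
#' the null is free of selection leakage. Accuracy and AUC are recorded
#' per permutation. Scaled configurations (fewer permutations, fewer
#' subsample iterations, fixed cost) reduce compute without changing the
#' procedure's structure.
#'
#' @inheritParams null_model_1
#' @param rlr arguments for [rlr_select()] (use a reduced `n_iterations`
#'   for scaled runs).
#' @param fixed_c SVM cost (scaled runs fix it rather than re-tuning).
#' @param observed optional list with `accuracy` and `auc` to test
#'   against.
#' @return list with `accuracy` and `auc` `null_distribution`s.
#' @export
null_model_2 <- function(features, labels, n_perms = 1000,
                         rlr = list(n_iterations = 50), fixed_c = 1,
                         observed = list(accuracy = NA_real_, auc = NA_real_),
                         pos_class = "PD-MCI", seed = 1L) {
  features <- as.matrix(features)
  labels <- droplevels(factor(labels))
  n <- nrow(features); p <- ncol(features)
  stopifnot(nlevels(labels) == 2)
  set.seed(seed)
  acc <- auc <- numeric(n_perms)
  for (i in seq_len(n_perms)) {
    repeat {
      yp <- sample(labels)
      if (all(table(yp) >= 3)) break
    }
    pred <- character(n); dec <- numeric(n)
    for (s in seq_len(n)) {
      x_tr <- features[-s, , drop = FALSE]
      y_tr <- yp[-s]
      profile <- do.call(rlr_select,
                         c(list(features = x_tr, labels = y_tr), rlr))
      sel <- suppressWarnings(selected_edges(profile))
      if (length(sel) == 0) sel <- order(-profile$scores)[seq_len(min(10, p))]
      fit <- fit_weighted_svm(x_tr[, sel, drop = FALSE], y_tr, fixed_c,
                              pos_class)
      pr <- predict_weighted_svm(fit, features[s, sel, drop = FALSE])
      pred[s] <- pr$label; dec[s] <- pr$decision
    }
    m <- classification_metrics(pred, dec, yp, pos_class)
    acc[i] <- m$accuracy; auc[i] <- m$auc
  }
  p_acc <- if (is.finite(observed$accuracy))
    perm_pvalue(observed$accuracy, acc, "greater") else NA_real_
  p_auc <- if (is.finite(observed$auc))
    perm_pvalue(observed$auc, auc, "greater") else NA_real_
  list(accuracy = new_null_distribution(acc, observed$accuracy, "greater",
                                        p_acc, seed,
                                        "LOOCV accuracy (%), reselection"),
       auc = new_null_distribution(auc, observed$auc, "greater", p_auc,
                                   seed, "LOOCV AUC, reselection"))
}

#' Null model 3: reshuffling the location of the feature edges
#'
#' Draws as many edges as the observed feature set uniformly without
#' replacement from the whole edge universe, trains the final model on the
#' training sample with those edges, and classifies the validation sample;
#' repeated `n_perms` times. Tests whether validation performance is
#' attributable to the specific edges rather than to network-wide
#' information.
#'
#' @param train_features,train_labels training sample (subjects x all
#'   edges).
#' @param validation_features,validation_labels validation sample on the
#'   identical edge map.
#' @param n_feature_edges size of the observed feature set (edges drawn
#'   per permutation).
#' @param n_perms permutations (default 10000; scale down for desk runs).
#' @param cost SVM cost (the observed model's).
#' @param observed optional list with `accuracy` and `auc`.
#' @param pos_class positive class label.
#' @param seed RNG seed.
#' @return list with `accuracy` and `auc` `null_distribution`s.
#' @export
null_model_3 <- function(train_features, train_labels,
                         validation_features, validation_labels,
                         n_feature_edges, n_perms = 10000, cost = 1,
                         observed = list(accuracy = NA_real_, auc = NA_real_),
                         pos_class = "PD-MCI", seed = 1L) {
  train_features <- as.matrix(train_features)
  validation_features <- as.matrix(validation_features)
  p <- ncol(train_features)
  stopifnot(ncol(validation_features) == p)
  if (n_feature_edges > p)
    stop("feature set larger than the edge universe (", p, ")")
  set.seed(seed)
  acc <- auc <- numeric(n_perms)
  for (i in seq_len(n_perms)) {
    edges <- sample.int(p, n_feature_edges)
    res <- fit_final_and_validate(train_features, train_labels,
                                  validation_features, validation_labels,
                                  edges, tune_c = FALSE, fixed_c = cost,
                                  pos_class = pos_class)
    acc[i] <- res$metrics$accuracy
    auc[i] <- res$metrics$auc
  }
  p_acc <- if (is.finite(observed$accuracy))
    perm_pvalue(observed$accuracy, acc, "greater") else NA_real_
  p_auc <- if (is.finite(observed$auc))
    perm_pvalue(observed$auc, auc, "greater") else NA_real_
  list(accuracy = new_null_distribution(acc, observed$accuracy, "greater",
                                        p_acc, seed,
                                        "validation accuracy (%), edge reshuffle"),
       auc = new_null_distribution(auc, observed$auc, "greater", p_auc,
                                   seed, "validation AUC, edge reshuffle"))
}
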