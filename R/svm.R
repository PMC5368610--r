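# Class-weighted linear SVM helpers shared by the classification and
# permutation-null modules. Features are standardized with training-set
# statistics; class weights follow the balanced scheme n / (2 * n_class);
# decision values are oriented so that larger means more PD-MCI-like.

fit_weighted_svm <- function(x, y, cost, pos_class) {
  y <- droplevels(factor(y))
  stopifnot(nlevels(y) == 2, pos_class %in% levels(y))
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, s, "/")
  tab <- table(y)
  w <- as.numeric(length(y) / (2 * tab))
  names(w) <- names(tab)
  model <- e1071::svm(xs, y, kernel = "linear", cost = cost,
                      class.weights = w, scale = FALSE)
  list(model = model, mu = mu, s = s, pos_class = pos_class,
       levels = levels(y))
}

predict_weighted_svm <- function(fit, x_new) {
  if (is.vector(x_new)) x_new <- matrix(x_new, nrow = 1)
  xs <- sweep(sweep(x_new, 2, fit$mu), 2, fit$s, "/")
  pred <- predict(fit$model, xs, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # e1071 orients positive decision values toward the first label of the
  # "a/b" column name; flip so positive always means the positive class
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  dec <- as.numeric(dv[, 1])
  if (first != fit$pos_class) dec <- -dec
  list(label = as.character(pred), decision = dec)
}

#' Tune the SVM C parameter by nested leave-one-out cross-validation
#'
#' For each candidate C on the grid, runs an inner LOOCV over the training
#' set with a class-weighted linear SVM and scores the mean inner accuracy;
#' returns the C with the highest mean accuracy, ties broken toward the
#' smallest C (the most regularized solution).
#'
#' @param x training features (subjects x edges).
#' @param y training labels (two classes, >= 2 subjects each).
#' @param grid candidate C values; defaults to the six-decade grid
#'   10^-3 ... 10^2.
#' @param pos_class label treated as the positive class.
#' @return list with `c` (chosen value) and `accuracy` (mean inner-LOOCV
#'   accuracy per grid value).
#' @export
tune_c_nested <- function(x, y, grid = 10^(-3:2), pos_class = "PD-MCI") {
  y <- droplevels(factor(y))
  stopifnot(all(table(y) >= 2))
  n <- nrow(x)
  acc <- vapply(grid, function(cost) {
    correct <- vapply(seq_len(n), function(s) {
      fit <- fit_weighted_svm(x[-s, , drop = FALSE], y[-s], cost, pos_class)
      predict_weighted_svm(fit, x[s, , drop = FALSE])$label == as.character(y[s])
    }, logical(1))
    mean(correct)
  }, numeric(1))
  grid_sorted <- order(grid) # smallest C wins ties
  best <- grid_sorted[which.max(acc[grid_sorted])]
  if (all(acc == acc[1]))
    warning("all grid values tie at ", round(acc[1] * 100, 1),
            "% inner accuracy; returning smallest C")
  list(c = grid[best], accuracy = setNames(acc, grid))
}

#' Classification metrics: accuracy, per-class accuracy, AUC
#'
#' Overall accuracy is correct/total; per-class accuracy is correct within
#' class / class size; AUC is computed from the decision values by the
#' rank (Mann-Whitney) statistic with midranks for ties, with `pos_class`
#' as the positive class.
#'
#' @param predictions predicted labels.
#' @param decision_values signed distances to the hyperplane (larger =
#'   more positive-class-like).
#' @param labels true labels.
#' @param pos_class positive class label.
#' @return list with `accuracy` and per-class accuracies (percent), and
#'   `auc` (`NA` with `auc_defined = FALSE` for single-class label sets).
#' @export
classification_metrics <- function(predictions, decision_values, labels,
                                   pos_class = "PD-MCI") {
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  stopifnot(length(predictions) == length(labels),
            length(decision_values) == length(labels))
  acc <- mean(predictions == labels) * 100
  per_class <- vapply(unique(labels), function(g) {
    mean(predictions[labels == g] == g) * 100
  }, numeric(1))
  pos <- labels == pos_class
  if (all(pos) || !any(pos)) {
    auc <- NA_real_; defined <- FALSE
  } else {
    r <- rank(decision_values) # midranks
    n_pos <- sum(pos); n_neg <- sum(!pos)
    auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    defined <- TRUE
  }
  list(accuracy = acc, per_class = per_class, auc = auc,
       auc_defined = defined)
}
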