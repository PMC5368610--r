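# Permutation inference: p-value convention, Monte Carlo tests for group
# means, correlations and regression coefficients, and Benjamini-Hochberg
# false-discovery-rate control.

#' Permutation p-value
#'
#' `p = (b + 1) / (m + 1)`, where `b` counts permuted draws as or more
#' extreme than the observed statistic in the stated tail. This estimator
#' is unbiased under exchangeability and can never return 0 (the observed
#' arrangement counts as one draw). Two-tailed extremity is measured as
#' absolute distance from `center` (0 for signed statistics such as
#' correlations or mean differences; pass the null mean for counts).
#'
#' @param observed observed statistic.
#' @param draws vector of permuted statistics.
#' @param tail `"two"`, `"greater"` or `"less"`.
#' @param center reference point for two-tailed extremity.
#' @return p-value in (0, 1].
#' @export
perm_pvalue <- function(observed, draws, tail = c("two", "greater", "less"),
                        center = 0) {
  tail <- match.arg(tail)
  if (length(draws) == 0) stop("empty null draws")
  if (!all(is.finite(draws)) || !is.finite(observed))
    stop("non-finite statistic in permutation draws")
  b <- switch(tail,
    two = sum(abs(draws - center) >= abs(observed - center)),
    greater = sum(draws >= observed),
    less = sum(draws <= observed))
  (b + 1) / (length(draws) + 1)
}

new_null_distribution <- function(draws, observed, tail, p, seed = NULL,
                                  statistic = "statistic") {
  structure(list(draws = draws, observed = observed,
                 n_perms = length(draws), p_value = p, tail = tail,
                 statistic = statistic, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Permutation null of %s: observed %.4g, null mean %.4g (SD %.4g), %d perms, %s-tailed p %s\n",
              x$statistic, x$observed, mean(x$draws), sd(x$draws),
              x$n_perms, x$tail,
              ifelse(x$p_value < 1e-3, "< 0.001",
                     sprintf("= %.4g", x$p_value))))
  invisible(x)
}

#' Permutation test of group means (omnibus F plus pairwise contrasts)
#'
#' Omnibus statistic is the one-way F on the per-subject scalar; group
#' labels are permuted. Pairwise post-hoc contrasts are mean differences,
#' each with its own two-tailed permutation p, corrected across contrasts
#' by Benjamini-Hochberg FDR.
#'
#' @param values numeric scalar per subject.
#' @param groups group labels (>= 2 groups, none empty).
#' @param n_perms Monte Carlo permutations (default 10000).
#' @param seed optional RNG seed.
#' @return list with `omnibus` (a `null_distribution` of F, greater tail)
#'   and `pairwise` (data frame: groups, mean difference, p, p_adjusted,
#'   reject at 5% FDR).
#' @export
perm_group_mean_test <- function(values, groups, n_perms = 10000,
                                 seed = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  f_obs <- oneway_f(values, groups)
  with_seed(seed, {
    draws <- vapply(seq_len(n_perms), function(i)
      oneway_f(values, sample(groups)), numeric(1))
    p <- perm_pvalue(f_obs, draws, "greater")
    omnibus <- new_null_distribution(draws, f_obs, "greater", p,
                                     statistic = "one-way F")
    lv <- levels(groups)
    pairs <- utils::combn(lv, 2)
    pw <- lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      keep <- groups %in% c(a, b)
      v <- values[keep]; g <- droplevels(groups[keep])
      d_obs <- mean(v[g == a]) - mean(v[g == b])
      d_null <- vapply(seq_len(n_perms), function(i) {
        gp <- sample(g)
        mean(v[gp == a]) - mean(v[gp == b])
      }, numeric(1))
      data.frame(group1 = a, group2 = b, diff = d_obs,
                 p = perm_pvalue(d_obs, d_null, "two"))
    })
    pw <- do.call(rbind, pw)
    fdr <- bh_fdr(pw$p)
    pw$p_adjusted <- fdr$p_adjusted
    pw$reject <- fdr$reject
    list(omnibus = omnibus, pairwise = pw)
  })
}

oneway_f <- function(values, groups) {
  n <- length(values)
  k <- nlevels(groups)
  mu <- mean(values)
  m_g <- tapply(values, groups, mean)
  n_g <- tabulate(groups)
  ssb <- sum(n_g * (m_g - mu)^2)
  ssw <- sum((values - m_g[as.integer(groups)])^2)
  if (ssw < 1e-300) return(0)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Permutation test of a Pearson correlation
#'
#' @param x,y numeric vectors (n >= 5).
#' @param n_perms Monte Carlo permutations of `y`.
#' @param seed optional RNG seed.
#' @return list with `r` and `null` (two-tailed `null_distribution`).
#' @export
perm_correlation <- function(x, y, n_perms = 10000, seed = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 5) stop("need at least 5 observations")
  if (sd(x) < 1e-12 || sd(y) < 1e-12) stop("zero variance input")
  xs <- as.numeric(scale(x)); ys <- as.numeric(scale(y))
  r_obs <- sum(xs * ys) / (n - 1)
  with_seed(seed, {
    draws <- vapply(seq_len(n_perms), function(i)
      sum(xs * ys[sample.int(n)]) / (n - 1), numeric(1))
    p <- perm_pvalue(r_obs, draws, "two")
    list(r = r_obs,
         null = new_null_distribution(draws, r_obs, "two", p,
                                      statistic = "Pearson r"))
  })
}

#' Permutation inference for standardized regression coefficients
#'
#' Fits least squares on standardized variables and assesses each
#' predictor's coefficient by Freedman-Lane residual permutation: for
#' predictor j, the reduced model (without j) is fitted, its residuals are
#' permuted and added back to the reduced fit, and the full model is refit
#' on the reconstructed response. Two-tailed p per predictor, corrected by
#' Benjamini-Hochberg FDR across predictors.
#'
#' @param y response.
#' @param predictors data frame or matrix of predictors (full rank).
#' @param n_perms Monte Carlo permutations.
#' @param seed optional RNG seed.
#' @return data frame: predictor, standardized beta, p, p_adjusted,
#'   reject; plus attribute `nulls` holding each predictor's
#'   `null_distribution`.
#' @export
perm_regression <- function(y, predictors, n_perms = 10000, seed = NULL) {
  x <- as.matrix(predictors)
  n <- nrow(x); p <- ncol(x)
  if (n <= p + 2) stop("need n > predictors + 2")
  ys <- as.numeric(scale(y))
  xs <- apply(x, 2, function(col) as.numeric(scale(col)))
  if (qr(xs)$rank < p) {
    qx <- qr(xs)
    bad <- colnames(x)[qx$pivot[-seq_len(qx$rank)]]
    stop("rank-deficient predictors: ", paste(bad, collapse = ", "))
  }
  beta_obs <- qr.coef(qr(cbind(1, xs)), ys)[-1]
  names(beta_obs) <- colnames(x)
  with_seed(seed, {
    nulls <- vector("list", p)
    pvals <- numeric(p)
    for (j in seq_len(p)) {
      xr <- cbind(1, xs[, -j, drop = FALSE])
      qr_r <- qr(xr)
      fitted_r <- qr.fitted(qr_r, ys)
      resid_r <- ys - fitted_r
      draws <- vapply(seq_len(n_perms), function(i) {
        y_star <- fitted_r + resid_r[sample.int(n)]
        qr.coef(qr(cbind(1, xs)), y_star)[j + 1]
      }, numeric(1))
      pvals[j] <- perm_pvalue(beta_obs[j], draws, "two")
      nulls[[j]] <- new_null_distribution(
        draws, beta_obs[j], "two", pvals[j],
        statistic = paste("standardized beta:", colnames(x)[j]))
    }
    fdr <- bh_fdr(pvals)
    out <- data.frame(predictor = colnames(x), beta = unname(beta_obs),
                      p = pvals, p_adjusted = fdr$p_adjusted,
                      reject = fdr$reject, row.names = NULL)
    attr(out, "nulls") <- nulls
    out
  })
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure at level `q`; adjusted p-values are monotone
#' non-decreasing with the raw p-values.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `reject` (logical flags) and `p_adjusted`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  adj <- p.adjust(p_values, method = "BH")
  list(reject = adj <= q, p_adjusted = adj)
}
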