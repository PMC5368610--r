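# Neuropsychological scoring: z-scores against the HC reference,
# demographically expected scores, level-I MCI labeling, domain composites.

#' Z-scores against the healthy-control reference
#'
#' z = (score - HC mean) / HC SD per test, oriented so that higher is
#' better (per-test orientation comes from the battery's `direction`
#' column; the synthetic battery is already oriented).
#'
#' @param scores data frame with `subject_id` and one column per test.
#' @param hc_reference data frame of HC rows with the same test columns
#'   (>= 3 subjects).
#' @param battery battery layout, see [neuropsych_battery()].
#' @return data frame: `subject_id` plus one z column per test.
#' @export
zscore_tests <- function(scores, hc_reference,
                         battery = neuropsych_battery()) {
  tests <- battery$test
  stopifnot(all(tests %in% names(scores)), all(tests %in% names(hc_reference)))
  if (nrow(hc_reference) < 3) stop("need at least 3 HC reference subjects")
  out <- data.frame(subject_id = scores$subject_id,
                    stringsAsFactors = FALSE)
  for (k in seq_along(tests)) {
    test <- tests[k]
    mu <- mean(hc_reference[[test]])
    s <- sd(hc_reference[[test]])
    if (!is.finite(s) || s < 1e-12)
      stop("zero HC standard deviation for test '", test, "'")
    out[[test]] <- battery$direction[k] * (scores[[test]] - mu) / s
  }
  out
}

#' Demographically expected z-scores
#'
#' Per-test least-squares fit of z on age, sex (0/1) and education in the
#' HC group; the fitted model predicts the expected z for every subject.
#'
#' @param z z-score table from [zscore_tests()] (all subjects).
#' @param demographics data frame with `subject_id`, `age`, `sex`,
#'   `education` for all subjects.
#' @param hc_ids subject ids belonging to the HC reference.
#' @param battery battery layout.
#' @return data frame: `subject_id` plus one expected-z column per test.
#' @export
expected_scores <- function(z, demographics, hc_ids,
                            battery = neuropsych_battery()) {
  dem <- demographics[match(z$subject_id, demographics$subject_id), ]
  hc <- z$subject_id %in% hc_ids
  if (sum(hc) <= 4) stop("need more than 4 HC subjects to fit the regression")
  x_hc <- cbind(1, dem$age[hc], dem$sex[hc], dem$education[hc])
  if (qr(x_hc)$rank < ncol(x_hc))
    stop("collinear demographics in the HC reference")
  x_all <- cbind(1, dem$age, dem$sex, dem$education)
  out <- data.frame(subject_id = z$subject_id, stringsAsFactors = FALSE)
  for (test in battery$test) {
    beta <- qr.coef(qr(x_hc), z[[test]][hc])
    out[[test]] <- as.numeric(x_all %*% beta)
  }
  out
}

#' Level-I MCI classification
#'
#' A deficit is an actual z-score at least 1.5 below the expected score
#' (inclusive: `expected - actual >= 1.5`). A subject is labeled MCI when
#' some domain shows deficits in at least two tests, or at least two
#' domains each show at least one deficit. Subjects with missing test
#' scores are flagged unclassifiable rather than imputed.
#'
#' @param z,expected aligned tables from [zscore_tests()] and
#'   [expected_scores()].
#' @param margin deficit margin in z units (default 1.5).
#' @param battery battery layout.
#' @return data frame: `subject_id`, `label` (`"MCI"`/`"nonMCI"`, `NA` if
#'   unclassifiable), `n_deficits`, plus one logical deficit flag per test.
#' @export
classify_mci <- function(z, expected, margin = 1.5,
                         battery = neuropsych_battery()) {
  stopifnot(identical(z$subject_id, expected$subject_id))
  tests <- battery$test
  deficit <- sapply(tests, function(test) expected[[test]] - z[[test]] >= margin)
  deficit <- matrix(deficit, nrow = nrow(z),
                    dimnames = list(NULL, tests))
  domains <- unique(battery$domain)
  per_domain <- sapply(domains, function(d) {
    rowSums(deficit[, battery$test[battery$domain == d], drop = FALSE])
  })
  per_domain <- matrix(per_domain, nrow = nrow(z),
                       dimnames = list(NULL, domains))
  mci <- apply(per_domain, 1, function(cnt) {
    if (any(is.na(cnt))) return(NA)
    any(cnt >= 2) || sum(cnt >= 1) >= 2
  })
  out <- data.frame(subject_id = z$subject_id,
                    label = ifelse(is.na(mci), NA_character_,
                                   ifelse(mci, "MCI", "nonMCI")),
                    n_deficits = rowSums(deficit),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(deficit))
}

#' Domain composite scores
#'
#' Mean over each domain's tests of (actual - expected) z-scores.
#'
#' @inheritParams classify_mci
#' @return data frame: `subject_id` plus one composite column per domain.
#' @export
composite_scores <- function(z, expected, battery = neuropsych_battery()) {
  stopifnot(identical(z$subject_id, expected$subject_id))
  out <- data.frame(subject_id = z$subject_id, stringsAsFactors = FALSE)
  for (d in unique(battery$domain)) {
    tests <- battery$test[battery$domain == d]
    diffs <- sapply(tests, function(test) z[[test]] - expected[[test]])
    diffs <- matrix(diffs, nrow = nrow(z))
    out[[d]] <- rowMeans(diffs)
  }
  out
}

#' Cognitive status for a whole cohort table
#'
#' Convenience wrapper: z-scores, expected scores, MCI labels and domain
#' composites from a neuropsychological score table whose HC rows form the
#' reference sample.
#'
#' @param neuropsych table from [generate_neuropsych()] (or the same layout
#'   read from disk): `subject_id`, `group`, `age`, `sex`, `education`,
#'   plus the 8 test columns.
#' @param battery battery layout.
#' @return list with `status` (labels and deficit flags), `composites`,
#'   `z`, `expected`.
#' @export
cognitive_status <- function(neuropsych, battery = neuropsych_battery()) {
  hc <- neuropsych[neuropsych$group == "HC", ]
  z <- zscore_tests(neuropsych, hc, battery)
  expct <- expected_scores(z, neuropsych, hc$subject_id, battery)
  list(status = classify_mci(z, expct, battery = battery),
       composites = composite_scores(z, expct, battery),
       z = z, expected = expct)
}
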