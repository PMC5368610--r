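# End-to-end orchestration: configuration, stage sequencing, report
# assembly. The configuration carries one global seed that is expanded
# into independent per-stage seeds, so toggling a stage does not change
# the draws of the others.

#' Pipeline configuration
#'
#' Bundles the stage parameters of an end-to-end run. `scaled = TRUE`
#' substitutes reduced, documented settings (fewer stability-selection
#' iterations, repeats and permutations, fixed SVM cost) without changing
#' any algorithm; full-scale settings mirror the modeled study's
#' configuration (200 selection iterations, 10 repeats, 1000/10000
#' permutations, nested cost tuning).
#'
#' @param cohort a `pd_cohort` (in-memory) or a directory written by
#'   [write_cohort()].
#' @param output_dir where reports are written (`NULL`: nothing written).
#' @param seed global seed.
#' @param scaled use the reduced preset.
#' @param stages character vector of stages to run, any of
#'   `"qc"`, `"connectome"`, `"label"`, `"classify"`, `"null"`, `"nbs"`.
#' @param ... overrides of individual preset entries (e.g.
#'   `n_repeats = 5`, `rlr_iterations = 50`, `n_perms_null1 = 200`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, output_dir = NULL, seed = 1L,
                            scaled = TRUE,
                            stages = c("qc", "connectome", "label",
                                       "classify", "null", "nbs"), ...) {
  preset <- if (scaled) {
    list(n_repeats = 5, rlr_iterations = 25, tune_c = FALSE, fixed_c = 1,
         n_perms_null1 = 200, n_perms_null2 = 50, rlr_iterations_null2 = 25,
         n_perms_nbs = 200, n_perms_regional = 500, nbs_threshold = 11)
  } else {
    list(n_repeats = 10, rlr_iterations = 200, tune_c = TRUE, fixed_c = 1,
         n_perms_null1 = 1000, n_perms_null2 = 1000,
         rlr_iterations_null2 = 200, n_perms_nbs = 10000,
         n_perms_regional = 10000, nbs_threshold = 11)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(preset))
  if (length(bad) > 0) stop("unknown config entries: ", paste(bad, collapse = ", "))
  preset[names(over)] <- over
  structure(c(list(cohort = cohort, output_dir = output_dir,
                   seed = as.integer(seed), scaled = scaled,
                   stages = stages), preset),
            class = "pipeline_config")
}

#' Run the pipeline end to end
#'
#' Stage order: QC and motion exclusion, connectome construction (aCompCor
#' components plus motion parameters as nuisance covariates), cognitive
#' labeling (z-scores, expected scores, level-I MCI criterion),
#' LOOCV classification with the consensus funnel, permutation null
#' models, and NBS group contrasts. Results (and TSV/JSON reports when
#' `output_dir` is set) are returned with a manifest recording seeds and
#' parameters.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_run` with per-stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- config$cohort
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  in_memory <- inherits(cohort, "pd_cohort")
  records <- if (in_memory)
    do.call(rbind, lapply(cohort$subjects, `[[`, "record"))
  else cohort$records
  neuropsych <- if (in_memory) {
    spec <- cohort$spec
    with_seed(config$seed + 1L, generate_neuropsych(spec, cohort))
  } else cohort$neuropsych
  stage_seeds <- config$seed + c(qc = 11L, connectome = 12L, label = 13L,
                                 classify = 14L, null = 15L, nbs = 16L)
  out <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if ("qc" %in% config$stages) {
    out$qc <- run_stage("qc", qc_report(cohort))
    keep_ids <- out$qc$subject_id[out$qc$keep]
  } else {
    keep_ids <- records$subject_id
  }

  if ("connectome" %in% config$stages) {
    out$connectomes <- run_stage("connectome", {
      subjects <- cohort$subjects
      ids <- records$subject_id
      conns <- lapply(seq_along(subjects), function(s) {
        sub <- subjects[[s]]
        comps <- compute_acompcor(sub$noise_pool)
        build_connectome(sub$roi_series, comps, sub$motion_params)
      })
      names(conns) <- ids
      conns[ids %in% keep_ids]
    })
    out$features <- edge_table(out$connectomes)
    rownames(out$features) <- names(out$connectomes)
  }

  if ("label" %in% config$stages) {
    out$cognition <- run_stage("label", cognitive_status(neuropsych))
    lab <- out$cognition$status
    out$labels <- ifelse(records$group == "HC", "HC",
                         ifelse(lab$label[match(records$subject_id,
                                                lab$subject_id)] == "MCI",
                                "PD-MCI", "PD-nonMCI"))
    names(out$labels) <- records$subject_id
  } else {
    out$labels <- setNames(records$group, records$subject_id)
  }

  patients <- intersect(keep_ids,
                        records$subject_id[records$group != "HC"])

  if ("classify" %in% config$stages) {
    out$classification <- run_stage("classify", {
      feats <- out$features[patients, , drop = FALSE]
      labs <- out$labels[patients]
      loocv_pipeline(feats, labs, n_repeats = config$n_repeats,
                     rlr = list(n_iterations = config$rlr_iterations),
                     tune_c = config$tune_c, fixed_c = config$fixed_c,
                     seed = stage_seeds[["classify"]])
    })
  }

  if ("null" %in% config$stages && !is.null(out$classification)) {
    out$null1 <- run_stage("null", {
      cl <- out$classification
      feats <- out$features[patients, , drop = FALSE]
      labs <- out$labels[patients]
      null_model_1(feats, labs, cl$funnel$per_subject,
                   n_perms = config$n_perms_null1, cost = config$fixed_c,
                   observed_accuracy = cl$summary$mean_accuracy,
                   score_sum = cl$score_sum,
                   seed = stage_seeds[["null"]])
    })
  }

  if ("nbs" %in% config$stages && !is.null(out$features)) {
    out$nbs <- run_stage("nbs", {
      labs <- out$labels[rownames(out$features)]
      contrasts <- list(c("HC", "PD-MCI"), c("HC", "PD-nonMCI"),
                        c("PD-nonMCI", "PD-MCI"))
      lapply(contrasts, function(ct) {
        keep <- labs %in% ct
        if (sum(labs[keep] == ct[1]) < 3 || sum(labs[keep] == ct[2]) < 3)
          return(NULL)
        nbs(out$features[keep, , drop = FALSE], labs[keep],
            n_nodes = n_nodes_of(out$features),
            threshold = config$nbs_threshold,
            n_perms = config$n_perms_nbs,
            seed = stage_seeds[["nbs"]])
      })
    })
  }

  out$manifest <- list(
    package_version = as.character(utils::packageVersion("pdcognet")),
    seed = config$seed, stage_seeds = as.list(stage_seeds),
    scaled = config$scaled, stages = config$stages,
    parameters = config[setdiff(names(config),
                                c("cohort", "output_dir", "stages"))],
    n_subjects = nrow(records), n_patients = length(patients))
  class(out) <- "pipeline_run"
  if (!is.null(config$output_dir)) write_reports(out, config$output_dir)
  out
}

# Invert E = n(n-1)/2 to recover the node count of a feature table.
n_nodes_of <- function(features) {
  e <- ncol(features)
  n <- (1 + sqrt(1 + 8 * e)) / 2
  if (abs(n - round(n)) > 1e-9) stop("feature count is not n(n-1)/2")
  as.integer(round(n))
}

write_reports <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(run$qc))
    write.table(run$qc, file.path(dir, "qc_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(run$cognition)) {
    status <- cbind(run$cognition$status,
                    run$cognition$composites[, -1, drop = FALSE])
    write.table(status, file.path(dir, "cognitive_status.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$classification)) {
    cl <- run$classification
    jsonlite::write_json(
      list(per_repeat = cl$per_repeat, summary = cl$summary,
           n_repeats = cl$n_repeats),
      file.path(dir, "classification_report.json"),
      auto_unbox = TRUE, digits = NA)
    fn <- cl$funnel
    funnel_df <- data.frame(
      edge = seq_len(nrow(fn$counts)),
      tier_any = seq_len(nrow(fn$counts)) %in% fn$tier_any,
      tier_all_repeats = seq_len(nrow(fn$counts)) %in% fn$tier_all_repeats,
      tier_consensus = seq_len(nrow(fn$counts)) %in% fn$tier_consensus,
      selection_count = rowSums(fn$counts))
    write.table(funnel_df[funnel_df$tier_any, ],
                file.path(dir, "funnel.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$null1)) {
    write.table(data.frame(accuracy = run$null1$draws),
                file.path(dir, "null_model1.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
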