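# Experiment orchestration: the ablation runner and run reports. A single
# master seed derives per-component seeds (cohort, split, weight init,
# shuffling), so synth -> split -> train -> evaluate is reproducible end to
# end.

#' Run an ablation experiment over model variants
#'
#' Trains and evaluates each requested variant on identical data, split,
#' and seed, and returns a results table shaped like the published ablation
#' table: stage flags, band confusion cells, and overall metrics.
#'
#' @param cohort a rendered `dictation_cohort`.
#' @param split a split tibble from [stratified_split()].
#' @param variants character vector of variant names (default: all 16).
#' @param config a `train_config` (applied to every variant).
#' @param model_options named list of extra arguments for [model_config()]
#'   (e.g. smaller dimensions for quick runs).
#' @param partition partition evaluated for the results table.
#' @param verbose print per-epoch training lines.
#' @return A tibble with one row per variant: `variant`, `use_P`, `use_L`,
#'   `use_A`, `use_G`, band confusion cells, `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `epochs`, `best_epoch`.
#' @export
run_ablation <- function(cohort, split, variants = enumerate_variants()$name,
                         config = desk_train_config(),
                         model_options = list(), partition = "test",
                         verbose = FALSE) {
  valid <- enumerate_variants()$name
  bad <- setdiff(variants, valid)
  if (length(bad) > 0)
    stop("unknown variant name(s) ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(valid, collapse = ", "))
  px <- cohort$config$render$image_px
  purrr::map_dfr(variants, function(v) {
    mcfg <- do.call(variant_config,
                    c(list(name = v, image_px = px,
                           seq_len = cohort$config$n_items), model_options))
    fit <- train_model(mcfg, cohort, split, config, verbose = verbose)
    ev <- evaluate_fit(fit, cohort, split, partition = partition)
    cbind(tibble::tibble(variant = v, use_P = mcfg$use_P, use_L = mcfg$use_L,
                         use_A = mcfg$use_A, use_G = mcfg$use_G),
          ev$metrics[, c("tp_g23", "fp_g23", "fn_g23", "tn_g23",
                         "tp_g456", "fp_g456", "fn_g456", "tn_g456",
                         "accuracy", "sensitivity", "specificity", "auc")],
          tibble::tibble(epochs = nrow(fit$history),
                         best_epoch = fit$best_epoch))
  })
}

# canonical reporting order of the 16 variants (P outermost, G innermost)
variant_order <- function() enumerate_variants()$name

#' Summarize ablation runs as a markdown report
#'
#' Rows are sorted in the canonical flag order; missing variants are listed
#' as absent, and the report is still produced.
#'
#' @param results an ablation results tibble (possibly partial).
#' @param file optional path to write the report to.
#' @return The report as a character vector of markdown lines, invisibly
#'   if `file` is given.
#' @export
report_ablation <- function(results, file = NULL) {
  lines <- c("# DysDiTect ablation report", "")
  if (nrow(results) == 0) {
    lines <- c(lines, "_No completed runs._")
  } else {
    ord <- match(variant_order(), results$variant)
    present <- results[ord[!is.na(ord)], ]
    lines <- c(lines,
               "| variant | accuracy | sensitivity | specificity | AUC |",
               "|---|---|---|---|---|",
               sprintf("| %s | %.3f | %.3f | %.3f | %.3f |",
                       present$variant, present$accuracy,
                       present$sensitivity, present$specificity, present$auc))
    best <- present$variant[which.max(present$accuracy)]
    lines <- c(lines, "", sprintf("Best accuracy: **%s** (%.3f).",
                                  best, max(present$accuracy)))
    absent <- setdiff(variant_order(), results$variant)
    if (length(absent) > 0)
      lines <- c(lines, "", paste("Absent runs:",
                                  paste(absent, collapse = ", ")))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
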