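#' Run the full retrospective study pipeline on a record pool
#'
#' Filters incomplete questionnaires, assembles the three pairwise subsets
#' (consuming each record at most once), runs stratified k-fold
#' cross-validation of the four base classifiers and the fusion classifier
#' on each subset, aggregates the three rare-disease sensitivities into the
#' headline value, and finally refits the three (base bundle, fusion) model
#' pairs on their full subsets for prospective prediction.
#'
#' @param pool validated record data.frame.
#' @param designs list of `rd_subset_design` (default [default_designs()]).
#' @param k outer cross-validation folds (default 10).
#' @param k_inner inner stacking folds (default 5).
#' @param config an `rd_training_config`.
#' @param seed integer seed.
#' @return Object of class `rd_study`: `reports` (per-subset
#'   `rd_evaluation_report`), `rd_sensitivities` (the three truncated fusion
#'   sensitivities), `aggregate_rd_sensitivity`, `models` (three
#'   `rd_fusion_fit`), `subsets`, `n_training`, `n_remaining` (complete
#'   analysis-group records not consumed by training).
#' @export
run_study <- function(pool, designs = default_designs(), k = 10L,
                      k_inner = 5L, config = training_config(), seed = 1L) {
  kept <- completeness_filter(pool)$kept
  subsets <- assemble_subsets(kept, designs)
  reports <- lapply(seq_along(subsets), function(i) {
    cross_validate(subsets[[i]], k = k, k_inner = k_inner, config = config,
                   seed = derive_seed(seed, 1000L + i))
  })
  models <- lapply(seq_along(subsets), function(i) {
    train_fusion(subsets[[i]], config, k_inner = k_inner,
                 seed = derive_seed(seed, 2000L + i))
  })
  sens <- vapply(reports, function(r) r$results$FUSION$sensitivity_reported,
                 numeric(1L))
  n_training <- sum(vapply(subsets, function(s) nrow(s$x), numeric(1L)))
  eligible <- kept$group %in% c("RD", "NRO", "CD", "PSY")
  structure(list(reports = reports,
                 rd_sensitivities = sens,
                 aggregate_rd_sensitivity = aggregate_sensitivity(sens),
                 models = models, subsets = subsets,
                 n_training = n_training,
                 n_pool_eligible = sum(eligible),
                 n_remaining = sum(eligible) - n_training,
                 seed = as.integer(seed)),
            class = "rd_study")
}

#' @export
print.rd_study <- function(x, ...) {
  cat(sprintf("Study pipeline: %d training records, %d held out\n",
              x$n_training, x$n_remaining))
  for (i in seq_along(x$reports)) {
    r <- x$reports[[i]]$results$FUSION
    cat(sprintf("  subset %d: fusion sensitivity %.1f%%, specificity %.1f%%, AUC %.3f\n",
                x$reports[[i]]$subset_id, r$sensitivity_reported,
                r$specificity_reported, r$auc))
  }
  cat(sprintf("  aggregate RD sensitivity: %.1f%%\n",
              x$aggregate_rd_sensitivity))
  invisible(x)
}

#' Save / load the three trained subset model pairs
#'
#' Models are written in a versioned container (RDS) that embeds the
#' training configuration and seeds; [load_models()] refuses containers
#' written by an incompatible version.
#'
#' @param models list of `rd_fusion_fit`, e.g. `run_study(...)$models`.
#' @param path file path for the model container.
#' @return `save_models` returns `path` invisibly; `load_models` returns the
#'   model list.
#' @export
save_models <- function(models, path) {
  stopifnot(all(vapply(models, inherits, logical(1L), "rd_fusion_fit")))
  saveRDS(list(format = "rdscreen-models", version = 1L,
               package_version = as.character(utils::packageVersion("rdscreen")),
               models = models),
          path)
  invisible(path)
}

#' @rdname save_models
#' @export
load_models <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "rdscreen-models") || !identical(obj$version, 1L)) {
    stop("unrecognized model container format in ", path, call. = FALSE)
  }
  obj$models
}

#' Serialize an evaluation report (or study) to JSON
#'
#' Writes confusion matrices, reported metrics, AUCs, per-fold
#' sensitivities, fold provenance and the seed, so every stored percentage
#' is recomputable from the stored counts.
#'
#' @param report an `rd_evaluation_report` or `rd_study`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  to_list <- function(r) {
    list(subset_id = r$subset_id, class_labels = r$class_labels,
         n = r$n, k = r$k, k_inner = r$k_inner, seed = r$seed,
         folds = r$folds, record_ids = r$record_ids,
         classifiers = lapply(r$results, function(x) {
           list(classifier = x$classifier,
                confusion = unclass(x$cm),
                sensitivity = x$sensitivity_reported,
                specificity = x$specificity_reported,
                auc = x$auc,
                fold_sensitivity = x$fold_sensitivity)
         }))
  }
  payload <- if (inherits(report, "rd_study")) {
    list(subsets = lapply(report$reports, to_list),
         rd_sensitivities = report$rd_sensitivities,
         aggregate_rd_sensitivity = report$aggregate_rd_sensitivity,
         n_training = report$n_training,
         n_remaining = report$n_remaining,
         seed = report$seed)
  } else {
    to_list(report)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
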