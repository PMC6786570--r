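#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that per-class counts differ by
#' at most one across folds; deterministic for a fixed seed.
#'
#' @param y factor (or vector) of class labels.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return Integer vector of fold ids in 1..k, same length as `y`.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  y <- as.factor(y)
  if (k < 2L) stop("config error: k must be at least 2", call. = FALSE)
  tab <- table(y)
  if (any(tab < k)) {
    stop("stratification error: class '", names(tab)[which(tab < k)[1L]],
         "' has fewer than k = ", k, " members", call. = FALSE)
  }
  set.seed(seed)
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Binary confusion matrix with the rare-disease side as positive
#'
#' Counts true positives, false negatives, false positives and true
#' negatives, with the positive (TP) side assigned to class 1 — the
#' rare-disease composite — and the TN side to the alternative group.
#'
#' @param truth factor of true labels (class-1 level first) or logical
#'   "is class 1".
#' @param predicted_class1 logical vector: predicted as class 1.
#' @param TP,FN,FP,TN alternatively, construct directly from counts.
#' @return Object of class `rd_confusion` with integer fields `TP`, `FN`,
#'   `FP`, `TN`.
#' @export
confusion_matrix <- function(truth = NULL, predicted_class1 = NULL,
                             TP = NULL, FN = NULL, FP = NULL, TN = NULL) {
  if (is.null(TP)) {
    if (is.factor(truth)) truth <- truth == levels(truth)[1L]
    stopifnot(is.logical(truth), is.logical(predicted_class1),
              length(truth) == length(predicted_class1))
    TP <- sum(truth & predicted_class1)
    FN <- sum(truth & !predicted_class1)
    FP <- sum(!truth & predicted_class1)
    TN <- sum(!truth & !predicted_class1)
  }
  counts <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "rd_confusion")
}

#' @export
print.rd_confusion <- function(x, ...) {
  cat(sprintf("%d TP / %d FN / %d FP / %d TN\n", x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Sensitivity and specificity from a confusion matrix
#'
#' Sensitivity is `100 * TP / (TP + FN)` (the rare-disease detection rate);
#' specificity is `100 * TN / (TN + FP)`. Values are returned at full double
#' precision; use [truncate_pct()] for the one-decimal reporting convention.
#'
#' @param cm an `rd_confusion`.
#' @return Percentage in `[0, 100]`.
#' @export
sensitivity <- function(cm) {
  stopifnot(inherits(cm, "rd_confusion"))
  if (cm$TP + cm$FN == 0L) {
    stop("undefined metric: sensitivity requires TP + FN > 0", call. = FALSE)
  }
  100 * cm$TP / (cm$TP + cm$FN)
}

#' @rdname sensitivity
#' @export
specificity <- function(cm) {
  stopifnot(inherits(cm, "rd_confusion"))
  if (cm$TN + cm$FP == 0L) {
    stop("undefined metric: specificity requires TN + FP > 0", call. = FALSE)
  }
  100 * cm$TN / (cm$TN + cm$FP)
}

#' One-decimal truncation for reported percentages
#'
#' Reported sensitivities/specificities are truncated (not rounded) to one
#' decimal place: 87.78 prints as 87.7. A 1e-6 guard absorbs floating-point
#' representation error before truncation.
#'
#' @param x numeric vector of percentages.
#' @return `x` truncated to one decimal.
#' @export
truncate_pct <- function(x) floor(round(x * 10, 6)) / 10

#' ROC curve and AUC by threshold sweep
#'
#' Builds the ROC curve from class-1 probabilities by sweeping thresholds
#' over the unique scores and integrating by the trapezoidal rule. The
#' resulting AUC equals the Mann-Whitney concordance probability with ties
#' counted as one half.
#'
#' @param truth factor (class-1 level first) or logical "is class 1".
#' @param scores numeric P(class 1) per sample.
#' @return List of class `rd_roc` with `points` (data.frame `fpr`, `tpr`,
#'   `threshold`) and `auc`.
#' @export
roc_auc <- function(truth, scores) {
  if (is.factor(truth)) truth <- truth == levels(truth)[1L]
  truth <- as.logical(truth)
  stopifnot(length(truth) == length(scores), !anyNA(truth), !anyNA(scores))
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC error: both classes must be present", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(truth & scores >= t) / n_pos, numeric(1L))
  fpr <- vapply(thr, function(t) sum(!truth & scores >= t) / n_neg, numeric(1L))
  fpr <- c(0, fpr); tpr <- c(0, tpr); thr <- c(Inf, thr)
  if (fpr[length(fpr)] < 1 || tpr[length(tpr)] < 1) {
    fpr <- c(fpr, 1); tpr <- c(tpr, 1); thr <- c(thr, -Inf)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
                 auc = auc),
            class = "rd_roc")
}

#' @export
print.rd_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.3f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Aggregate the three subset sensitivities into the headline value
#'
#' The final aggregation across the three independent pairwise subsets is the
#' arithmetic mean of the three rare-disease sensitivities, reported to one
#' truncated decimal.
#'
#' @param values numeric vector of exactly three percentages.
#' @return The aggregate percentage (one truncated decimal).
#' @examples
#' aggregate_sensitivity(c(87.7, 93.3, 85.7)) # 88.9
#' @export
aggregate_sensitivity <- function(values) {
  if (length(values) != 3L) {
    stop("contract error: exactly three subset sensitivities required",
         call. = FALSE)
  }
  truncate_pct(mean(values))
}

#' Stratified k-fold cross-validation of base and fusion classifiers
#'
#' For each outer fold, the four base classifiers and the fusion
#' meta-classifier (stacked on inner out-of-fold predictions within the
#' training folds) are trained on k-1 folds and applied to the held-out
#' fold. Prediction counts are pooled into one confusion matrix per
#' classifier; held-out class-1 probabilities feed the ROC/AUC. Per-fold
#' sensitivities are stored alongside the pooled counts.
#'
#' @param dataset an `rd_subset_dataset`.
#' @param k number of outer folds (default 10).
#' @param k_inner inner stacking folds for the fusion stage.
#' @param config an `rd_training_config`.
#' @param seed integer seed.
#' @return Object of class `rd_evaluation_report`: per classifier (`FUSION`
#'   plus the four families) the confusion matrix, sensitivity/specificity
#'   (raw and truncated), ROC and AUC; plus fold assignment, per-fold
#'   sensitivities, held-out scores and the seed.
#' @export
cross_validate <- function(dataset, k = 10L, k_inner = 5L,
                           config = training_config(), seed = 1L) {
  stopifnot(inherits(dataset, "rd_subset_dataset"))
  n <- nrow(dataset$x)
  folds <- stratified_folds(dataset$y, k = k, seed = derive_seed(seed, 1L))
  classifiers <- c(base_families(), "FUSION")
  p1_all <- matrix(NA_real_, nrow = n, ncol = 5L,
                   dimnames = list(NULL, classifiers))
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    sub <- new_subset_dataset(dataset$subset_id,
                              dataset$x[train_idx, , drop = FALSE],
                              dataset$y[train_idx],
                              dataset$record_ids[train_idx],
                              dataset$class_labels, dataset$design)
    fit <- tryCatch(
      train_fusion(sub, config, k_inner = k_inner,
                   seed = derive_seed(seed, 10L + f)),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    x_test <- dataset$x[test_idx, , drop = FALSE]
    p1_all[test_idx, seq_len(4L)] <- base_class1_prob(fit$bundle, x_test)
    p1_all[test_idx, "FUSION"] <-
      predict_fusion(fit$bundle, fit$fusion, x_test)$p_class1
  }
  stopifnot(!anyNA(p1_all))
  truth <- dataset$y == levels(dataset$y)[1L]
  per_classifier <- lapply(classifiers, function(cl) {
    pred1 <- p1_all[, cl] >= 0.5
    cm <- confusion_matrix(truth, pred1)
    roc <- roc_auc(truth, p1_all[, cl])
    fold_sens <- vapply(seq_len(k), function(f) {
      i <- folds == f
      100 * sum(truth[i] & pred1[i]) / sum(truth[i])
    }, numeric(1L))
    list(classifier = cl, cm = cm,
         sensitivity = sensitivity(cm), specificity = specificity(cm),
         sensitivity_reported = truncate_pct(sensitivity(cm)),
         specificity_reported = truncate_pct(specificity(cm)),
         auc = roc$auc, roc = roc, fold_sensitivity = fold_sens)
  })
  names(per_classifier) <- classifiers
  structure(list(subset_id = dataset$subset_id,
                 class_labels = dataset$class_labels,
                 n = n, k = as.integer(k), k_inner = as.integer(k_inner),
                 seed = as.integer(seed),
                 folds = folds, record_ids = dataset$record_ids,
                 scores = p1_all, results = per_classifier),
            class = "rd_evaluation_report")
}

#' @export
print.rd_evaluation_report <- function(x, ...) {
  cat(sprintf("Stratified %d-fold cross-validation, subset %d (%s vs %s, n = %d)\n",
              x$k, x$subset_id, x$class_labels[1L], x$class_labels[2L], x$n))
  for (r in x$results) {
    cat(sprintf("  %-20s sens %5.1f%%  spec %5.1f%%  AUC %.3f  (%d TP / %d FN / %d FP / %d TN)\n",
                r$classifier, r$sensitivity_reported,
                r$specificity_reported, r$auc,
                r$cm$TP, r$cm$FN, r$cm$FP, r$cm$TN))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-patient probability triple and diagnostic suggestion
#'
#' Applies all three trained subset models to one completed questionnaire.
#' Each model yields the fused probability of its rare-disease side, giving
#' three probability pairs `(p_i, 1 - p_i)`. The suggestion rule: if the
#' largest rare-disease probability reaches 0.5 the suggestion is a rare
#' disease, pointing at the argmax subset, at that probability; otherwise
#' the suggestion is the alternative group (NRO/CD/PSY) whose complement
#' probability `1 - p_i` is largest.
#'
#' @param record one complete respondent record (1-row data.frame) or a
#'   55-element feature vector.
#' @param models list of three `rd_fusion_fit` (or `list(bundle, fusion)`)
#'   pairs, in subset order 1..3.
#' @param gender_codes passed to [encode_records()] when `record` is a
#'   data.frame.
#' @return Object of class `rd_probability_triple`: `p_rd` (length-3 vector),
#'   `suggestion` (list with `type` = `"RD"` or the alternative group label,
#'   `subset` pointer for RD suggestions, and headline `probability`).
#' @export
evaluate_questionnaire <- function(record, models,
                                   gender_codes = c(F = 0, M = 1)) {
  if (length(models) != 3L) {
    stop("contract error: three trained subset models required", call. = FALSE)
  }
  x <- if (is.data.frame(record)) {
    encode_records(record, gender_codes)
  } else {
    feature_matrix(record)
  }
  if (nrow(x) != 1L) {
    stop("contract error: evaluate_questionnaire takes a single record",
         call. = FALSE)
  }
  p_rd <- numeric(3L)
  alt_labels <- character(3L)
  for (i in 1:3) {
    m <- models[[i]]
    if (is.null(m$bundle) || is.null(m$fusion)) {
      stop("contract error: model for subset ", i, " is missing",
           call. = FALSE)
    }
    p_rd[i] <- predict_fusion(m$bundle, m$fusion, x)$p_class1
    alt_labels[i] <- m$fusion$class_labels[2L]
  }
  names(p_rd) <- paste0("p_rd", 1:3)
  sugg <- triple_suggestion(p_rd, alt_labels)
  structure(list(p_rd = p_rd, alt_labels = alt_labels, suggestion = sugg),
            class = "rd_probability_triple")
}

# decision rule shared by evaluate_questionnaire and the CLI report
triple_suggestion <- function(p_rd, alt_labels = c("NRO", "CD", "PSY")) {
  stopifnot(length(p_rd) == 3L, all(p_rd >= 0 & p_rd <= 1))
  if (max(p_rd) >= 0.5) {
    i <- which.max(p_rd)
    list(type = "RD", subset = i, probability = p_rd[[i]])
  } else {
    i <- which.min(p_rd)
    list(type = alt_labels[[i]], subset = NA_integer_,
         probability = 1 - p_rd[[i]])
  }
}

#' @export
print.rd_probability_triple <- function(x, ...) {
  cat(sprintf("Probability pairs (RD side): %s\n",
              paste(sprintf("subset %d: %.0f%%", 1:3, 100 * x$p_rd),
                    collapse = ", ")))
  s <- x$suggestion
  if (identical(s$type, "RD")) {
    cat(sprintf("Suggestion: rare disease (subset %d) at %.0f%%\n",
                s$subset, 100 * s$probability))
  } else {
    cat(sprintf("Suggestion: %s at %.0f%%\n", s$type, 100 * s$probability))
  }
  invisible(x)
}
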