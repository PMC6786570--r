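#' Build the 8-element fusion feature from four base classifier results
#'
#' Concatenates, in the fixed [base_families()] order, each family's coded
#' diagnosis and probability: `(index_1, p_1, index_2, p_2, index_3, p_3,
#' index_4, p_4)`. No renormalization is applied. A missing, duplicated or
#' out-of-order family is a contract error: the meta-classifier is only valid
#' when train- and predict-time features use the same ordering.
#'
#' @param results list of exactly four `rd_base_result` objects, one per
#'   family, in [base_families()] order.
#' @return Named numeric vector of length 8.
#' @examples
#' res <- mapply(function(f, i, p) structure(
#'     list(family = f, predicted_index = i, probability = p),
#'     class = "rd_base_result"),
#'   base_families(), c(0L, 0L, 1L, 0L), c(.9, .8, .6, .7),
#'   SIMPLIFY = FALSE)
#' make_fusion_feature(res) # 0 .9 0 .8 1 .6 0 .7
#' @export
make_fusion_feature <- function(results) {
  fams <- base_families()
  if (length(results) != 4L) {
    stop("contract error: exactly four base results required, got ",
         length(results), call. = FALSE)
  }
  got <- vapply(results, function(r) r$family, character(1L))
  if (!identical(got, fams)) {
    stop("contract error: base results must be one per family in the order ",
         paste(fams, collapse = ", "), " (got: ",
         paste(got, collapse = ", "), ")", call. = FALSE)
  }
  idx <- vapply(results, function(r) as.numeric(r$predicted_index), numeric(1L))
  p <- vapply(results, function(r) r$probability, numeric(1L))
  stopifnot(all(idx %in% c(0, 1)), all(p >= 0 & p <= 1))
  out <- as.numeric(rbind(idx, p))
  names(out) <- as.vector(rbind(paste0(fams, "_idx"), paste0(fams, "_prob")))
  out
}

# n x 8 fusion feature matrix from an n x 4 matrix of P(class 1)
fusion_feature_matrix <- function(p1) {
  idx <- ifelse(p1 >= 0.5, 0, 1)
  pp <- pmax(p1, 1 - p1)
  fams <- base_families()
  out <- matrix(0, nrow = nrow(p1), ncol = 8L)
  out[, seq(1L, 8L, by = 2L)] <- idx
  out[, seq(2L, 8L, by = 2L)] <- pp
  colnames(out) <- as.vector(rbind(paste0(fams, "_idx"),
                                   paste0(fams, "_prob")))
  out
}

#' Train the base bundle and the fusion meta-classifier without leakage
#'
#' The fusion ("super-fusion") classifier is a degree-3 polynomial-kernel SVM
#' over the 8-element fusion features. To avoid optimistic bias it is trained
#' on out-of-fold base predictions: the dataset is split into `k_inner`
#' stratified folds; base models fitted on the other folds predict each
#' held-out fold, and those predictions (one per record) form the fusion
#' training set. The final base bundle is then refit on all records.
#'
#' @param dataset an `rd_subset_dataset`.
#' @param config an `rd_training_config`.
#' @param k_inner number of inner stacking folds (>= 2; default 5, chosen so
#'   the smallest 80-record subset still trains base models on ~64 records
#'   per inner fold).
#' @param seed integer seed driving fold assignment and all stochastic fits.
#' @return List of class `rd_fusion_fit` with elements `bundle` (the refit
#'   `rd_base_bundle`), `fusion` (the meta-model), `oof` (the out-of-fold
#'   fusion feature matrix, row order = dataset order) and `provenance`
#'   (per-inner-fold train/held-out record ids, for leakage audits).
#' @export
train_fusion <- function(dataset, config = training_config(), k_inner = 5L,
                         seed = 1L) {
  stopifnot(inherits(dataset, "rd_subset_dataset"))
  if (k_inner < 2L) {
    stop("config error: k_inner must be at least 2", call. = FALSE)
  }
  dataset <- canonical_order(dataset)
  n <- nrow(dataset$x)
  folds <- stratified_folds(dataset$y, k = k_inner,
                            seed = derive_seed(seed, 101L))
  oof_p1 <- matrix(NA_real_, nrow = n, ncol = 4L,
                   dimnames = list(NULL, base_families()))
  provenance <- vector("list", k_inner)
  for (f in seq_len(k_inner)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    sub <- new_subset_dataset(dataset$subset_id,
                              dataset$x[train_idx, , drop = FALSE],
                              dataset$y[train_idx],
                              dataset$record_ids[train_idx],
                              dataset$class_labels, dataset$design)
    b <- train_base(sub, config, seed = derive_seed(seed, 200L + f))
    oof_p1[test_idx, ] <- base_class1_prob(b, dataset$x[test_idx, , drop = FALSE])
    provenance[[f]] <- list(fold = f,
                            train_ids = dataset$record_ids[train_idx],
                            heldout_ids = dataset$record_ids[test_idx])
  }
  stopifnot(!anyNA(oof_p1))
  meta_x <- fusion_feature_matrix(oof_p1)
  set.seed(derive_seed(seed, 300L))
  fusion_svm <- e1071::svm(x = meta_x, y = dataset$y, kernel = "polynomial",
                           degree = config$svm_degree, cost = config$svm_cost,
                           coef0 = config$svm_coef0, probability = TRUE,
                           scale = FALSE)
  bundle <- train_base(dataset, config, seed = derive_seed(seed, 400L))
  structure(list(bundle = bundle,
                 fusion = structure(list(subset_id = dataset$subset_id,
                                         model = fusion_svm,
                                         class_labels = dataset$class_labels,
                                         k_inner = as.integer(k_inner),
                                         seed = as.integer(seed)),
                                    class = "rd_fusion_model"),
                 oof = meta_x, provenance = provenance),
            class = "rd_fusion_fit")
}

#' @export
print.rd_fusion_fit <- function(x, ...) {
  cat(sprintf(
    "Fusion fit (subset %d): 4 base models + SVM meta-classifier (%d-fold stacking)\n",
    x$bundle$subset_id, x$fusion$k_inner))
  invisible(x)
}

#' Final fused prediction for feature vectors
#'
#' Runs the four base classifiers, assembles the 8-element fusion features,
#' and applies the fusion meta-classifier. The returned probability refers to
#' the class-1 (rare-disease) side; `final_index` is 1 iff that probability
#' is below 0.5, so an exact tie is resolved towards the rare-disease class
#' (the tool is an alarm, and ties err towards sensitivity).
#'
#' @param bundle an `rd_base_bundle`.
#' @param fusion_model an `rd_fusion_model` trained for the same subset.
#' @param x a 55-element vector or an n x 55 matrix.
#' @return data.frame with columns `p_class1` and `final_index` (0 = class 1).
#' @export
predict_fusion <- function(bundle, fusion_model, x) {
  stopifnot(inherits(bundle, "rd_base_bundle"),
            inherits(fusion_model, "rd_fusion_model"))
  if (!identical(bundle$subset_id, fusion_model$subset_id)) {
    stop("contract error: base bundle (subset ", bundle$subset_id,
         ") and fusion model (subset ", fusion_model$subset_id,
         ") were trained for different subsets", call. = FALSE)
  }
  x <- feature_matrix(x)
  p1 <- base_class1_prob(bundle, x)
  meta_x <- fusion_feature_matrix(p1)
  pred <- stats::predict(fusion_model$model, meta_x, probability = TRUE)
  p_class1 <- attr(pred, "probabilities")[, fusion_model$class_labels[1L]]
  data.frame(p_class1 = unname(p_class1),
             final_index = ifelse(p_class1 < 0.5, 1L, 0L),
             row.names = rownames(x))
}

#' Audit the stacking provenance for information leakage
#'
#' Asserts, from a fusion fit's provenance log, that within every inner fold
#' the record ids used to fit the base models are disjoint from the ids whose
#' predictions train the meta-classifier, and that every record is predicted
#' exactly once out-of-fold.
#'
#' @param fit an `rd_fusion_fit`.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
assert_no_leakage <- function(fit) {
  stopifnot(inherits(fit, "rd_fusion_fit"))
  heldout <- unlist(lapply(fit$provenance, `[[`, "heldout_ids"))
  for (p in fit$provenance) {
    if (length(intersect(p$train_ids, p$heldout_ids)) > 0L) {
      stop("leakage: fold ", p$fold,
           " trains base models on records it also predicts", call. = FALSE)
    }
  }
  if (anyDuplicated(heldout) || length(heldout) != nrow(fit$oof)) {
    stop("leakage: out-of-fold predictions do not cover each record exactly once",
         call. = FALSE)
  }
  invisible(TRUE)
}
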