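# importing the fitting functions (rather than only calling them via ::)
# guarantees the e1071/randomForest/MASS namespaces are loaded whenever
# rdscreen is, so predict() dispatch works on deserialized model bundles
#' @importFrom e1071 svm
#' @importFrom randomForest randomForest
#' @importFrom MASS lda
#' @importFrom stats predict glm binomial
NULL

#' The four base classifier families
#'
#' Fixed family order used everywhere a per-family result is produced:
#' degree-3 polynomial-kernel SVM, random forest, logistic regression,
#' linear discriminant analysis.
#' @return Character vector of the four family names.
#' @export
base_families <- function() {
  c("SVM_POLY3", "RANDOM_FOREST", "LOGISTIC_REGRESSION", "LDA")
}

#' Pinned training configuration for the base and fusion classifiers
#'
#' All hyperparameters are pinned explicitly rather than relying on library
#' defaults, so runs are reproducible and auditable. The SVM uses a degree-3
#' polynomial kernel with a fitted sigmoid (Platt-style) probability model;
#' the fusion meta-classifier uses the same kernel family.
#'
#' @param svm_degree polynomial kernel degree (3).
#' @param svm_cost SVM soft-margin cost C (1).
#' @param svm_coef0 polynomial kernel offset (0).
#' @param ntree number of random-forest trees (200; the out-of-bag error is
#'   flat well before this at 55 predictors).
#' @param lda_var_tol predictors whose pooled within-class variance falls
#'   below this are dropped from the LDA fit (guards against singular
#'   covariance on small subsets); the dropped set is stored in the bundle.
#' @param standardize center/scale the 55 features (fitted on the training
#'   split, applied identically at predict time) for the SVM, logistic and
#'   LDA fits; the random forest always sees raw features. Raw age (0--120)
#'   would otherwise dominate kernel distances.
#' @return A list of class `rd_training_config`.
#' @export
training_config <- function(svm_degree = 3L, svm_cost = 1, svm_coef0 = 0,
                            ntree = 200L, lda_var_tol = 1e-8,
                            standardize = TRUE) {
  structure(list(svm_degree = as.integer(svm_degree), svm_cost = svm_cost,
                 svm_coef0 = svm_coef0, ntree = as.integer(ntree),
                 lda_var_tol = lda_var_tol, standardize = isTRUE(standardize)),
            class = "rd_training_config")
}

#' Train the four base binary classifiers on one subset
#'
#' Fits one model per family on the same dataset. Stochastic fits (random
#' forest, the SVM's internal probability calibration) consume the seed, so
#' training is deterministic for a fixed seed.
#'
#' @param dataset an `rd_subset_dataset` with both classes present.
#' @param config an `rd_training_config`.
#' @param seed integer seed.
#' @return An `rd_base_bundle`: the four fitted models plus the fitted
#'   preprocessing state (centering/scaling, LDA column subset).
#' @export
train_base <- function(dataset, config = training_config(), seed = 1L) {
  stopifnot(inherits(dataset, "rd_subset_dataset"))
  dataset <- canonical_order(dataset)
  y <- droplevels(dataset$y)
  if (nlevels(y) < 2L) {
    stop("training error: dataset contains a single class (",
         levels(y), ")", call. = FALSE)
  }
  y <- dataset$y
  x <- dataset$x
  set.seed(seed)
  prep <- fit_standardizer(x, enabled = config$standardize)
  xs <- apply_standardizer(prep, x)

  svm_fit <- e1071::svm(x = xs, y = y, kernel = "polynomial",
                        degree = config$svm_degree, cost = config$svm_cost,
                        coef0 = config$svm_coef0, probability = TRUE,
                        scale = FALSE)
  rf_fit <- randomForest::randomForest(x = x, y = y, ntree = config$ntree)
  lr_df <- data.frame(.y = y, xs, check.names = FALSE)
  lr_fit <- suppressWarnings(
    stats::glm(.y ~ ., data = lr_df, family = stats::binomial())
  )
  lda_cols <- lda_usable_columns(xs, y, config$lda_var_tol)
  lda_fit <- suppressWarnings(
    MASS::lda(x = xs[, lda_cols, drop = FALSE], grouping = y)
  )
  structure(list(subset_id = dataset$subset_id,
                 class_labels = levels(y),
                 models = list(SVM_POLY3 = svm_fit, RANDOM_FOREST = rf_fit,
                               LOGISTIC_REGRESSION = lr_fit, LDA = lda_fit),
                 prep = prep, lda_cols = lda_cols,
                 config = config, seed = as.integer(seed)),
            class = "rd_base_bundle")
}

fit_standardizer <- function(x, enabled = TRUE) {
  if (!enabled) return(list(enabled = FALSE))
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(enabled = TRUE, center = ctr, scale = scl)
}

apply_standardizer <- function(prep, x) {
  if (!isTRUE(prep$enabled)) return(x)
  scale(x, center = prep$center, scale = prep$scale)[, , drop = FALSE]
}

# columns with non-degenerate pooled within-class variance
lda_usable_columns <- function(x, y, tol) {
  wv <- rep(0, ncol(x))
  for (lv in levels(y)) {
    xi <- x[y == lv, , drop = FALSE]
    if (nrow(xi) > 1L) wv <- wv + apply(xi, 2L, stats::var) * (nrow(xi) - 1L)
  }
  wv <- wv / max(1L, nrow(x) - nlevels(y))
  keep <- which(wv > tol)
  if (length(keep) == 0L) {
    stop("training error: no usable predictors for LDA ",
         "(all constant within classes)", call. = FALSE)
  }
  keep
}

# P(class 1) for every family on an n x 55 matrix; rows = samples,
# columns = base_families()
base_class1_prob <- function(bundle, x) {
  x <- feature_matrix(x)
  xs <- apply_standardizer(bundle$prep, x)
  lvl1 <- bundle$class_labels[1L]
  svm_pred <- stats::predict(bundle$models$SVM_POLY3, xs, probability = TRUE)
  p_svm <- attr(svm_pred, "probabilities")[, lvl1]
  p_rf <- stats::predict(bundle$models$RANDOM_FOREST, x, type = "prob")[, lvl1]
  nd <- data.frame(xs, check.names = FALSE)
  # rank-deficiency warnings are expected for near-saturated fits on the
  # smaller subsets; predictions remain usable as probability scores
  p_lr <- 1 - suppressWarnings(
    stats::predict(bundle$models$LOGISTIC_REGRESSION,
                   newdata = nd, type = "response"))
  p_lda <- stats::predict(bundle$models$LDA,
                          xs[, bundle$lda_cols, drop = FALSE])$posterior[, lvl1]
  p <- cbind(SVM_POLY3 = unname(p_svm), RANDOM_FOREST = unname(p_rf),
             LOGISTIC_REGRESSION = unname(p_lr), LDA = unname(p_lda))
  pmin(pmax(p, 0), 1)
}

#' Apply the four base classifiers to one feature vector
#'
#' Each model emits a coded diagnosis (`predicted_index`: 0 = class 1, the
#' rare-disease side; 1 = class 2) and the calibrated probability of its own
#' predicted class (hence always >= 0.5). A probability tie is resolved
#' towards class 1, the alarm side.
#'
#' @param bundle an `rd_base_bundle`.
#' @param vector a 55-element feature vector (or 1-row matrix).
#' @return List of four `rd_base_result` objects in [base_families()] order,
#'   each with `family`, `predicted_index` and `probability`.
#' @export
predict_base <- function(bundle, vector) {
  x <- feature_matrix(vector)
  p1 <- base_class1_prob(bundle, x)[1L, ]
  lapply(base_families(), function(fam) {
    p <- p1[[fam]]
    structure(list(family = fam,
                   predicted_index = if (p >= 0.5) 0L else 1L,
                   probability = max(p, 1 - p)),
              class = "rd_base_result")
  })
}

#' @export
print.rd_base_result <- function(x, ...) {
  cat(sprintf("%s: class index %d, probability %.3f\n",
              x$family, x$predicted_index, x$probability))
  invisible(x)
}

#' @export
print.rd_base_bundle <- function(x, ...) {
  cat(sprintf("Base classifier bundle (subset %d): %s; classes %s vs %s\n",
              x$subset_id, paste(base_families(), collapse = ", "),
              x$class_labels[1L], x$class_labels[2L]))
  invisible(x)
}
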