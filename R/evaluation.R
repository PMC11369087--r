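#' Stratified fold assignment
#'
#' Shuffles each class independently and deals its members round-robin
#' across `k` folds, so per-fold class counts differ from the global ratio
#' by at most one instance. Deterministic given the seed.
#'
#' @param labels 0/1 vector.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids (1..k), one per instance.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  classes <- unique(labels)
  if (length(classes) < 2L) stop("both classes must be present", call. = FALSE)
  if (any(table(labels) < k))
    stop("a class has fewer members than k = ", k, call. = FALSE)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in sort(classes)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Binary classification metrics from confusion counts
#'
#' Accuracy, precision, recall, F1 and Matthews correlation coefficient
#' computed literally from TP/TN/FP/FN. Degenerate denominators (e.g. no
#' predicted positives) yield 0 for the affected metric, flagged in the
#' `degenerate` attribute.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return named numeric vector `c(accuracy, precision, recall, f1, mcc)`.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  degenerate <- character(0)
  div <- function(num, den, what) {
    if (den == 0) { degenerate <<- c(degenerate, what); 0 } else num / den
  }
  accuracy <- div(tp + tn, tp + tn + fp + fn, "accuracy")
  precision <- div(tp, tp + fp, "precision")
  recall <- div(tp, tp + fn, "recall")
  f1 <- div(2 * precision * recall, precision + recall, "f1")
  mcc_den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- div(tp * tn - fp * fn, mcc_den, "mcc")
  out <- c(accuracy = accuracy, precision = precision, recall = recall,
           f1 = f1, mcc = mcc)
  attr(out, "degenerate") <- degenerate
  out
}

#' Area under the ROC curve
#'
#' The Mann-Whitney form: the probability that a uniformly drawn positive
#' receives a higher score than a uniformly drawn negative, ties counting
#' one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

MODEL_NAMES <- c("logistic", "svm", "ann", "rf", "xgb")

fit_model <- function(model_name, x, y, seed = 1L) {
  set.seed(seed)
  switch(model_name,
    logistic = {
      # ridge-penalized logistic regression at fixed lambda = 1/n,
      # mirroring the common default of an L2 penalty with C = 1
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                            lambda = 1 / nrow(x), standardize = TRUE)
      list(kind = "logistic", fit = fit)
    },
    svm = list(kind = "svm",
               fit = e1071::svm(x, factor(y, levels = c(0, 1)),
                                kernel = "radial", probability = TRUE)),
    ann = {
      size <- min(10L, max(1L, ceiling(ncol(x) / 2)))
      list(kind = "ann",
           fit = nnet::nnet(x, y, size = size, decay = 0, maxit = 200,
                            trace = FALSE, MaxNWts = 100000))
    },
    rf = list(kind = "rf",
              fit = randomForest::randomForest(x, factor(y, levels = c(0, 1)))),
    xgb = list(kind = "xgb",
               fit = xgboost::xgb.train(
                 params = list(objective = "binary:logistic", nthread = 1),
                 data = xgboost::xgb.DMatrix(x, label = y), nrounds = 100)),
    lgbm = stop("model 'lgbm' (LightGBM) is not available in this build; ",
                "choose one of: ", paste(MODEL_NAMES, collapse = ", "),
                call. = FALSE),
    stop("unknown model '", model_name, "'; choose one of: ",
         paste(MODEL_NAMES, collapse = ", "), call. = FALSE))
}

predict_prob <- function(model, x) {
  switch(model$kind,
    logistic = as.numeric(stats::predict(model$fit, newx = x, type = "response")),
    svm = {
      p <- stats::predict(model$fit, x, probability = TRUE)
      as.numeric(attr(p, "probabilities")[, "1"])
    },
    ann = as.numeric(stats::predict(model$fit, x)),
    rf = as.numeric(stats::predict(model$fit, x, type = "prob")[, "1"]),
    xgb = as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(x))))
}

#' Stratified k-fold cross-validated evaluation
#'
#' For each fold: fit the chosen classifier on the other k-1 folds and
#' score the held-out fold. When the configuration includes `"pro2vec"`
#' features, embedding models are re-trained per fold on the training-fold
#' sequences only, so no held-out information leaks into the
#' representation. Confusion counts use the 0.5 probability threshold;
#' AUC uses the raw probabilities. Aggregate metrics are fold means.
#'
#' @param peptides peptide data.frame with `sequence` and `label`.
#' @param spec a `feature_spec`.
#' @param model_name one of `"logistic"`, `"svm"`, `"ann"`, `"rf"`,
#'   `"xgb"`.
#' @param k number of folds.
#' @param seed RNG seed controlling folds, model fitting and embedding
#'   training.
#' @return an `eval_report`: list with `model`, `spec`, `k`, `seed`,
#'   `folds` (assignment vector), `per_fold` (data.frame of metrics per
#'   fold) and `aggregate` (named mean metric vector).
#' @export
run_cv <- function(peptides, spec, model_name, k = 10L, seed = 1L) {
  stopifnot(inherits(spec, "feature_spec"))
  labels <- peptides$label
  folds <- stratified_folds(labels, k = k, seed = seed)
  uses_embedding <- "pro2vec" %in% spec$feature_types
  fm_all <- if (!uses_embedding) extract_matrix(peptides, spec)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (uses_embedding) {
      models <- train_spec_embeddings(peptides$sequence[tr], spec, seed = seed)
      x_tr <- extract_matrix(peptides[tr, , drop = FALSE], spec, models)$x
      x_te <- extract_matrix(peptides[!tr, , drop = FALSE], spec, models)$x
    } else {
      x_tr <- fm_all$x[tr, , drop = FALSE]
      x_te <- fm_all$x[!tr, , drop = FALSE]
    }
    fit <- fit_model(model_name, x_tr, labels[tr], seed = seed + f)
    p <- predict_prob(fit, x_te)
    y <- labels[!tr]
    pred <- as.integer(p >= 0.5)
    m <- classification_metrics(tp = sum(pred == 1 & y == 1),
                                tn = sum(pred == 0 & y == 0),
                                fp = sum(pred == 1 & y == 0),
                                fn = sum(pred == 0 & y == 1))
    per_fold[[f]] <- c(fold = f, m, auc_roc = auc_roc(p, y))
  }
  per_fold <- as.data.frame(do.call(rbind, per_fold))
  aggregate <- colMeans(per_fold[, -1, drop = FALSE])
  structure(list(model = model_name, spec = spec, k = k, seed = seed,
                 folds = folds, per_fold = per_fold, aggregate = aggregate),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$model, "-", x$k, "folds, seed", x$seed, "\n")
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Stratified train/test split
#'
#' @param labels 0/1 vector.
#' @param test_fraction held-out share (default 0.2, the 80:20 protocol).
#' @param seed RNG seed.
#' @return logical vector, TRUE = test instance.
#' @export
train_test_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  test <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- round(length(idx) * test_fraction)
    test[sample(idx, n_test)] <- TRUE
  }
  test
}

#' Serialize an evaluation report
#'
#' One row in the layout of a results table: model, representations,
#' feature types, offsets, feature count and aggregate metrics.
#'
#' @param report an `eval_report` (or list of them).
#' @return data.frame with one row per report.
#' @export
report_row <- function(report) {
  if (inherits(report, "eval_report")) report <- list(report)
  do.call(rbind, lapply(report, function(r) {
    data.frame(
      Model = r$model,
      Representations = paste(names(r$spec$alphabets), collapse = ","),
      Feat_types = paste(r$spec$feature_types, collapse = ","),
      Offsets = paste(r$spec$offsets, collapse = ","),
      Nfeat = feature_dimension(r$spec),
      Accuracy = r$aggregate[["accuracy"]],
      Precision = r$aggregate[["precision"]],
      Recall = r$aggregate[["recall"]],
      F1_score = r$aggregate[["f1"]],
      AUC_ROC = r$aggregate[["auc_roc"]],
      MCC = r$aggregate[["mcc"]],
      stringsAsFactors = FALSE)
  }))
}
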