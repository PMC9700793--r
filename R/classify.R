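#' Build a participant-independent cross-validation plan
#'
#' Stratified-by-label partition of participants into `n_outer` disjoint
#' folds; every participant appears in exactly one outer fold, so their
#' retellings are used for either training or testing in each iteration,
#' never both. Deterministic given `seed`.
#'
#' @param participant_ids character vector of unique participant ids.
#' @param labels binary labels, named by or aligned with `participant_ids`.
#' @param seed integer seed.
#' @param n_outer number of outer folds (default 5).
#' @param n_inner number of inner folds for hyperparameter tuning (default 4).
#' @return object of class `prsf_cvplan`: list with `outer_folds` (list of id
#'   vectors), `labels`, `seed`, `n_inner`.
#' @export
make_cv_plan <- function(participant_ids, labels, seed, n_outer = 5L,
                         n_inner = 4L) {
  stopifnot(length(participant_ids) == length(labels),
            !anyDuplicated(participant_ids))
  labels <- as.character(labels)
  names(labels) <- participant_ids
  classes <- unique(labels)
  if (length(classes) != 2)
    abort("cross-validation plan needs exactly 2 classes", "prsf_cv_error")
  tab <- table(labels)
  if (any(tab < n_outer))
    abort(sprintf(
      "class '%s' has %d member(s); cannot stratify into %d folds",
      names(tab)[which.min(tab)], min(tab), n_outer), "prsf_cv_error")
  folds <- vector("list", n_outer)
  withr::with_seed(seed, {
    for (cl in classes) {
      ids <- sample(participant_ids[labels == cl])
      assign_to <- rep(seq_len(n_outer), length.out = length(ids))
      for (f in seq_len(n_outer))
        folds[[f]] <- c(folds[[f]], ids[assign_to == f])
    }
  })
  structure(list(outer_folds = folds, labels = labels, seed = as.integer(seed),
                 n_inner = as.integer(n_inner)),
            class = "prsf_cvplan")
}

# stratified split of ids into k folds, deterministic given seed
stratified_folds <- function(ids, labels, k, seed) {
  folds <- vector("list", k)
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      cl_ids <- sample(ids[labels[ids] == cl])
      assign_to <- rep(seq_len(k), length.out = length(cl_ids))
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], cl_ids[assign_to == f])
    }
  })
  folds
}

svm_fit_predict <- function(x_train, y_train, x_test, C, gamma, positive) {
  fit <- suppressWarnings(e1071::svm(
    x = x_train, y = y_train, kernel = "radial", cost = C, gamma = gamma,
    scale = FALSE))
  pred <- stats::predict(fit, x_test, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # orient decision values so larger = positive class
  cn <- colnames(dv)[1]
  sides <- strsplit(cn, "/")[[1]]
  score <- as.numeric(dv[, 1])
  if (sides[1] != positive) score <- -score
  list(pred = as.character(pred), score = score)
}

# z-scale columns with training statistics; constant columns pass through
scale_train_test <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sd <- apply(x_train, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(train = sweep(sweep(x_train, 2, mu), 2, sd, `/`),
       test = sweep(sweep(x_test, 2, mu), 2, sd, `/`))
}

#' Nested cross-validated Gaussian-kernel SVM classification
#'
#' Per outer fold: hyperparameters (cost `C`, kernel bandwidth `gamma`) are
#' tuned by randomized search - `search_budget` candidate pairs drawn
#' log-uniformly from `C_range` and `gamma_range` - scored by mean accuracy
#' over `n_inner` stratified inner folds of the training participants. The
#' best pair is refit on the full training fold and applied to the held-out
#' fold. Features are extracted per outer fold by `feature_fn`, fitted on
#' training participants only, so no information from held-out participants
#' reaches the model. Held-out decision scores are pooled across outer folds
#' into a single ROC / AUC, and the confusion matrix is aggregated.
#'
#' @param feature_fn function `(train_ids, test_ids)` returning a list with
#'   `train` and `test` numeric feature matrices whose rownames are the ids
#'   (e.g., a closure over [fit_transform_fold()]).
#' @param plan a `prsf_cvplan`.
#' @param positive label of the positive (patient) class.
#' @param search_budget number of random hyperparameter candidates
#'   (default 50).
#' @param C_range,gamma_range log-uniform sampling ranges.
#' @return object of class `prsf_report`: list with `accuracy`, `sensitivity`,
#'   `specificity`, `f_score` (percent), `auc`, `confusion`, `roc` (data
#'   frame of fpr/tpr), `scores`, `truth`, `per_fold`.
#' @export
nested_cv <- function(feature_fn, plan, positive, search_budget = 50L,
                      C_range = c(1e-2, 1e3), gamma_range = c(1e-4, 1e1)) {
  stopifnot(inherits(plan, "prsf_cvplan"))
  labels <- plan$labels
  classes <- unique(labels)
  if (!(positive %in% classes))
    abort(sprintf("positive class '%s' not among labels", positive),
          "prsf_cv_error")
  negative <- setdiff(classes, positive)
  lev <- c(negative, positive)
  all_scores <- numeric(0)
  all_truth <- character(0)
  all_pred <- character(0)
  per_fold <- list()
  for (f in seq_along(plan$outer_folds)) {
    test_ids <- plan$outer_folds[[f]]
    train_ids <- setdiff(names(labels), test_ids)
    feats <- feature_fn(train_ids, test_ids)
    x_train <- feats$train[train_ids, , drop = FALSE]
    x_test <- feats$test[test_ids, , drop = FALSE]
    y_train <- factor(labels[train_ids], levels = lev)
    # candidate hyperparameters: one draw per outer fold, derived from the
    # plan seed so the search never sees held-out data
    cand <- withr::with_seed(plan$seed + 104729L * f, data.frame(
      C = exp(stats::runif(search_budget, log(C_range[1]), log(C_range[2]))),
      gamma = exp(stats::runif(search_budget, log(gamma_range[1]),
                               log(gamma_range[2])))
    ))
    inner <- stratified_folds(train_ids, labels, plan$n_inner,
                              plan$seed + 7919L * f)
    sc <- scale_train_test(x_train, x_test)
    inner_acc <- vapply(seq_len(search_budget), function(ci) {
      accs <- vapply(seq_along(inner), function(ii) {
        val_ids <- inner[[ii]]
        tr_ids <- setdiff(train_ids, val_ids)
        res <- tryCatch(
          svm_fit_predict(sc$train[tr_ids, , drop = FALSE],
                          factor(labels[tr_ids], levels = lev),
                          sc$train[val_ids, , drop = FALSE],
                          cand$C[ci], cand$gamma[ci], positive),
          error = function(e) NULL)
        if (is.null(res)) return(NA_real_)
        mean(res$pred == labels[val_ids])
      }, numeric(1))
      mean(accs, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(inner_acc)
    res <- tryCatch(
      svm_fit_predict(sc$train, y_train, sc$test,
                      cand$C[best], cand$gamma[best], positive),
      error = function(e) NULL)
    if (is.null(res)) {
      warning(sprintf("fold %d: SVM fit failed; predicting majority class", f))
      maj <- names(which.max(table(labels[train_ids])))
      res <- list(pred = rep(maj, length(test_ids)),
                  score = rep(0, length(test_ids)))
    }
    all_scores <- c(all_scores, res$score)
    all_truth <- c(all_truth, labels[test_ids])
    all_pred <- c(all_pred, res$pred)
    per_fold[[f]] <- list(C = cand$C[best], gamma = cand$gamma[best],
                          inner_accuracy = inner_acc[best],
                          test_accuracy = mean(res$pred == labels[test_ids]),
                          test_ids = test_ids)
  }
  confusion <- table(factor(all_pred, levels = lev),
                     factor(all_truth, levels = lev),
                     dnn = c("predicted", "truth"))
  metrics <- compute_metrics(confusion, all_scores, all_truth, positive)
  structure(c(metrics, list(
    confusion = confusion,
    roc = roc_points(all_scores, all_truth, positive),
    scores = all_scores, truth = all_truth, predicted = all_pred,
    per_fold = per_fold, positive = positive
  )), class = "prsf_report")
}

#' Classification metrics from a confusion matrix and pooled scores
#'
#' Accuracy, sensitivity (recall of the positive/patient class), specificity,
#' and F-score (harmonic mean of precision and sensitivity) as percentages;
#' AUC as the Mann-Whitney rank statistic on the pooled decision scores (ties
#' count one half).
#'
#' @param confusion 2x2 table, predicted x truth, negative class first.
#' @param scores pooled decision scores (larger = more positive).
#' @param truth true labels aligned with `scores`.
#' @param positive positive-class label.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `f_score`
#'   (percent), `auc`.
#' @export
compute_metrics <- function(confusion, scores, truth, positive) {
  lev <- rownames(confusion)
  stopifnot(positive %in% lev, length(lev) == 2)
  negative <- setdiff(lev, positive)
  tp <- confusion[positive, positive]
  tn <- confusion[negative, negative]
  fp <- confusion[positive, negative]
  fn <- confusion[negative, positive]
  n <- tp + tn + fp + fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  fsc <- if (is.na(sens) || prec + sens == 0) 0
         else 2 * prec * sens / (prec + sens)
  if (!all(c(positive, negative) %in% unique(truth)))
    abort("AUC undefined: a class is absent from the truth labels",
          "prsf_cv_error")
  pos <- truth == positive
  r <- rank(scores)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(accuracy = 100 * (tp + tn) / n, sensitivity = 100 * sens,
       specificity = 100 * spec, f_score = 100 * fsc, auc = auc)
}

#' ROC points from pooled decision scores
#'
#' @inheritParams compute_metrics
#' @return data frame with `fpr`, `tpr`, `threshold`, from (0,0) to (1,1).
#' @export
roc_points <- function(scores, truth, positive) {
  pos <- truth == positive
  ord <- order(scores, decreasing = TRUE)
  thr <- unique(scores[ord])
  n1 <- sum(pos)
  n0 <- sum(!pos)
  tpr <- vapply(thr, function(t) sum(pos & scores >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(!pos & scores >= t) / n0, numeric(1))
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
             threshold = c(Inf, thr, -Inf))
}
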