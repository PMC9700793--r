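test_that("cross-validation plans are stratified, disjoint, deterministic", {
  ids10 <- sprintf("p%02d", 1:10)
  lab10 <- rep(c("pos", "neg"), 5)
  plan <- make_cv_plan(ids10, lab10, seed = 3)
  expect_length(plan$outer_folds, 5)
  for (f in plan$outer_folds) {
    expect_length(f, 2)
    expect_setequal(unname(plan$labels[f]), c("pos", "neg"))
  }
  expect_setequal(unlist(plan$outer_folds), ids10)
  plan2 <- make_cv_plan(ids10, lab10, seed = 3)
  expect_identical(plan, plan2)
  expect_false(identical(plan, make_cv_plan(ids10, lab10, seed = 4)))

  ids80 <- sprintf("q%02d", 1:80)
  lab80 <- rep(c("pos", "neg"), each = 40)
  plan80 <- make_cv_plan(ids80, lab80, seed = 11)
  for (f in plan80$outer_folds) {
    expect_length(f, 16)
    expect_equal(as.vector(table(plan80$labels[f])), c(8L, 8L))
  }

  expect_error(make_cv_plan(sprintf("r%d", 1:8), c(rep("a", 4), rep("b", 4)),
                            seed = 1),
               class = "prsf_cv_error")
})

make_gaussian_features <- function(n_per_class, delta, seed) {
  withr::with_seed(seed, {
    x <- c(rnorm(n_per_class, 0), rnorm(n_per_class, delta))
    ids <- sprintf("g%03d", seq_len(2 * n_per_class))
    labels <- rep(c("neg", "pos"), each = n_per_class)
    names(labels) <- ids
    feats <- matrix(x, ncol = 1, dimnames = list(ids, "f1"))
    list(features = feats, labels = labels)
  })
}

test_that("well-separated classes are classified nearly perfectly", {
  gs <- make_gaussian_features(40, delta = 5, seed = 61)
  plan <- make_cv_plan(names(gs$labels), gs$labels, seed = 61)
  rep_ <- nested_cv(matrix_feature_fn(gs$features), plan, positive = "pos",
                    search_budget = 10)
  expect_gte(rep_$accuracy, 95)
  expect_gte(rep_$auc, 0.99)
  expect_equal(sum(rep_$confusion), 80)
})

test_that("randomly permuted labels classify at chance", {
  gs <- make_gaussian_features(40, delta = 5, seed = 62)
  perm_labels <- withr::with_seed(62, {
    p <- sample(gs$labels)
    names(p) <- names(gs$labels)
    p
  })
  plan <- make_cv_plan(names(perm_labels), perm_labels, seed = 62)
  rep_ <- nested_cv(matrix_feature_fn(gs$features), plan, positive = "pos",
                    search_budget = 10)
  expect_gte(rep_$auc, 0.35)
  expect_lte(rep_$auc, 0.65)
})

test_that("nested CV is a pure function of data, plan and seeds", {
  gs <- make_gaussian_features(15, delta = 1.5, seed = 63)
  plan <- make_cv_plan(names(gs$labels), gs$labels, seed = 63)
  r1 <- nested_cv(matrix_feature_fn(gs$features), plan, positive = "pos",
                  search_budget = 8)
  r2 <- nested_cv(matrix_feature_fn(gs$features), plan, positive = "pos",
                  search_budget = 8)
  expect_identical(r1, r2)
})

test_that("classification metrics match their arithmetic definitions", {
  conf_perfect <- matrix(c(10L, 0L, 0L, 10L), 2,
                         dimnames = list(c("neg", "pos"), c("neg", "pos")))
  scores <- c(rnorm(10, -2), rnorm(10, 2))
  truth <- rep(c("neg", "pos"), each = 10)
  m <- compute_metrics(conf_perfect, scores, truth, positive = "pos")
  expect_equal(m$accuracy, 100)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$f_score, 100)
  expect_equal(m$auc, 1.0)

  # constant scores: every pair is a tie, AUC = 0.5
  m_tie <- compute_metrics(conf_perfect, rep(0, 20), truth, positive = "pos")
  expect_equal(m_tie$auc, 0.5)

  # TP=8 FN=2 FP=3 TN=7 -> acc 75, sens 80, spec 70
  conf <- matrix(c(7L, 3L, 2L, 8L), 2,
                 dimnames = list(c("neg", "pos"), c("neg", "pos")))
  m2 <- compute_metrics(conf, scores, truth, positive = "pos")
  expect_equal(m2$accuracy, 75)
  expect_equal(m2$sensitivity, 80)
  expect_equal(m2$specificity, 70)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(64, {
    scores <- rnorm(30)
    truth <- sample(c("pos", "neg"), 30, replace = TRUE, prob = c(0.4, 0.6))
    conf <- matrix(c(1L, 1L, 1L, 1L), 2,
                   dimnames = list(c("neg", "pos"), c("neg", "pos")))
    a1 <- compute_metrics(conf, scores, truth, "pos")$auc
    a2 <- compute_metrics(conf, exp(3 * scores) + 5, truth, "pos")$auc
    expect_equal(a1, a2)
  })
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  withr::with_seed(65, {
    scores <- rnorm(60)
    truth <- c(rep("pos", 25), rep("neg", 35))
    scores[truth == "pos"] <- scores[truth == "pos"] + 1
    conf <- table(factor(ifelse(scores > 0, "pos", "neg"),
                         levels = c("neg", "pos")),
                  factor(truth, levels = c("neg", "pos")))
    auc <- compute_metrics(conf, scores, truth, "pos")$auc
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = truth, predictor = scores, levels = c("neg", "pos"),
      direction = "<")))
    expect_equal(auc, as.numeric(ref), tolerance = 1e-12)
  })
})

test_that("ROC points start at (0,0), end at (1,1), and are monotone", {
  withr::with_seed(66, {
    scores <- rnorm(40)
    truth <- sample(c("pos", "neg"), 40, replace = TRUE)
    roc <- roc_points(scores, truth, "pos")
    expect_equal(roc$fpr[1], 0)
    expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1)
    expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
  })
})

test_that("mutating held-out data never changes train-fitted choices", {
  withr::with_seed(67, {
    study <- generate_study(default_pd_scenario(
      67, c("HC" = 10L, "PD-nMCI" = 10L)))
    docs <- process_corpus(study$transcripts, study$backend)
    ids <- vapply(docs, `[[`, character(1), "participant_id")
    labels <- stats::setNames(
      ifelse(study$metadata$group == "HC", "control", "patient"),
      study$metadata$participant_id)
    plan <- make_cv_plan(names(labels), labels, seed = 67)
    test_ids <- plan$outer_folds[[1]]
    train_ids <- setdiff(names(labels), test_ids)
    is_test <- ids %in% test_ids & vapply(docs, `[[`, character(1),
                                          "condition") == "AT"
    fn <- prsf_feature_fn(docs, study$reference_verbs$AT, "AT")
    f1 <- fn(train_ids, test_ids)
    # scramble every held-out document
    docs_mut <- docs
    for (i in which(is_test)) {
      docs_mut[[i]]$lemmas <- c("zzz", "qqq")
      docs_mut[[i]]$verbs <- "zzz"
    }
    fn_mut <- prsf_feature_fn(docs_mut, study$reference_verbs$AT, "AT")
    f2 <- fn_mut(train_ids, test_ids)
    expect_identical(f1$train, f2$train)
  })
})
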