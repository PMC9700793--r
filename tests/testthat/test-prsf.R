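test_that("reference verbs are the attested intersection in story order", {
  rv <- select_reference_verbs(c("v1", "v2", "v3"), c("v1", "v3", "x"), "AT")
  expect_equal(rv$verbs, c("v1", "v3"))
  rv_full <- select_reference_verbs(c("v2", "v1"), c("v1", "v2"), "nAT")
  expect_equal(rv_full$verbs, c("v2", "v1"))
  expect_error(select_reference_verbs(c("v9"), c("a", "b"), "AT"),
               class = "prsf_refverbs_error")
  # an unattested verb shrinks the set by one
  rv_less <- select_reference_verbs(c("v1", "v2", "v3"), c("v1", "v2"), "AT")
  expect_length(rv_less$verbs, 2)
})

test_that("verb importance is the mean cosine similarity to the vocabulary", {
  # vocabulary of one word: the verb itself
  m1 <- fake_lsa(matrix(2, 1, 1, dimnames = list("vb", NULL)))
  rv1 <- structure(list(condition = "AT", verbs = "vb"),
                   class = "prsf_refverbs")
  expect_equal(unname(verb_importance(m1, rv1)), 1.0)

  # verb orthogonal to every other word; hand-computed 4-word mean
  D <- rbind(vb = c(1, 0), u1 = c(0, 1), u2 = c(0, 2), u3 = c(1, 1))
  m4 <- fake_lsa(D)
  rv4 <- structure(list(condition = "AT", verbs = "vb"),
                   class = "prsf_refverbs")
  # cos(vb, vb)=1, cos(vb,u1)=0, cos(vb,u2)=0, cos(vb,u3)=1/sqrt(2)
  expect_equal(unname(verb_importance(m4, rv4)),
               (1 + 0 + 0 + 1 / sqrt(2)) / 4)
})

test_that("zero-norm vocabulary vectors contribute similarity 0", {
  D <- rbind(vb = c(1, 0), zero = c(0, 0))
  rv <- structure(list(condition = "AT", verbs = "vb"),
                  class = "prsf_refverbs")
  expect_equal(unname(verb_importance(fake_lsa(D), rv)), (1 + 0) / 2)
})

test_that("occurrence matrix counts exact hits and credits near misses", {
  D <- rbind(v1 = c(1, 0), v2 = c(0, 1),
             syn = c(0.6, 0.8),    # cos to v2 = 0.8, to v1 = 0.6
             far = c(-1, 0))       # cos to v1 = -1, to v2 = 0
  rv <- structure(list(condition = "AT", verbs = c("v1", "v2")),
                  class = "prsf_refverbs")
  model <- fake_lsa(D)

  occ <- occurrence_matrix(list(d1 = c("v1", "v2")), rv, model)
  expect_equal(unname(occ$O["d1", ]), c(1, 1))
  expect_equal(unname(occ$credit["d1", ]), c(0, 0))

  expect_equal(unname(occurrence_matrix(list(d1 = character()), rv,
                                        model)$O["d1", ]), c(0, 0))

  occ_syn <- occurrence_matrix(list(d1 = "syn"), rv, model)
  expect_equal(unname(occ_syn$O["d1", ]), c(0, 0.8))
  expect_equal(unname(occ_syn$exact["d1", ]), c(0L, 0L))

  # negative similarity is clipped at zero in the default mode ...
  occ_far <- occurrence_matrix(list(d1 = "far"), rv, model)
  expect_equal(unname(occ_far$O["d1", ]), c(0, 0))
  # ... and kept raw in the sensitivity mode
  occ_raw <- occurrence_matrix(list(d1 = "far"), rv, model,
                               credit_mode = "one_minus_distance_raw")
  expect_equal(unname(occ_raw$O["d1", ]), c(0, 0))
  expect_equal(sum(occ_raw$credit), 0)

  # per-token semantics: duplicates accumulate credit
  occ_dup <- occurrence_matrix(list(d1 = c("syn", "syn")), rv, model)
  expect_equal(unname(occ_dup$O["d1", ]), c(0, 1.6))

  # OOV verbs contribute nothing and are counted
  occ_oov <- occurrence_matrix(list(d1 = c("ghost", "v1")), rv, model)
  expect_equal(unname(occ_oov$O["d1", ]), c(1, 0))
  expect_equal(unname(occ_oov$n_oov["d1"]), 1L)
})

test_that("nearest-verb ties break toward the earliest reference verb", {
  D <- rbind(v1 = c(1, 0), v2 = c(0, 1), mid = c(1, 1))
  rv <- structure(list(condition = "AT", verbs = c("v1", "v2")),
                  class = "prsf_refverbs")
  occ <- occurrence_matrix(list(d1 = "mid"), rv, fake_lsa(D))
  expect_equal(unname(occ$O["d1", ]), c(cos(pi / 4), 0), tolerance = 1e-12)
})

test_that("P-RSF matrix is the Hadamard product and scores are row means", {
  pm <- prsf_scores(matrix(c(1, 0, 1, 0), 2, dimnames = list(c("a", "b"),
                                                             c("v1", "v2"))),
                    c(0.5, 0.25))
  expect_equal(unname(pm$P["a", ]), c(0.5, 0.25))
  expect_equal(unname(pm$score), c(0.375, 0))
  expect_error(prsf_scores(matrix(0, 2, 3), c(1, 2)),
               class = "prsf_shape_error")

  withr::with_seed(31, {
    O <- matrix(runif(12), 3, 4)
    w <- runif(4)
    pm2 <- prsf_scores(O, w)
    # brute-force loop oracle
    for (i in 1:3) {
      acc <- 0
      for (j in 1:4) {
        expect_equal(pm2$P[i, j], O[i, j] * w[j])
        acc <- acc + O[i, j] * w[j]
      }
      expect_equal(unname(pm2$score[i]), acc / 4)
    }
  })
})

test_that("an extra exact occurrence of a positive-weight verb raises the score", {
  withr::with_seed(33, {
    tc <- random_tiny_corpus()
    fit <- fit_transform_fold(make_docs(tc$doc_lemmas, tc$doc_verbs),
                              list(), tc$original_verbs, "AT")
    vb <- fit$ref_verbs$verbs[which.max(fit$w)]
    expect_gt(fit$w[which.max(fit$w)], 0)
    aug_lemmas <- tc$doc_lemmas
    aug_verbs <- tc$doc_verbs
    aug_lemmas[[1]] <- c(aug_lemmas[[1]], vb)
    aug_verbs[[1]] <- c(aug_verbs[[1]], vb)
    fit2 <- fit_transform_fold(make_docs(aug_lemmas, aug_verbs),
                               list(), tc$original_verbs, "AT")
    # same fitted space is not guaranteed, so compare through the train fit's
    # own occurrence arithmetic: score with the original model and weights
    occ1 <- occurrence_matrix(setNames(tc$doc_verbs, tc$ids),
                              fit$ref_verbs, fit$model)
    occ2 <- occurrence_matrix(setNames(aug_verbs, tc$ids),
                              fit$ref_verbs, fit$model)
    s1 <- prsf_scores(occ1, fit$w)$score[1]
    s2 <- prsf_scores(occ2, fit$w)$score[1]
    expect_gt(s2, s1)
  })
})

test_that("scores are invariant under permutation of a document's verbs", {
  withr::with_seed(35, {
    tc <- random_tiny_corpus()
    docs <- make_docs(tc$doc_lemmas, tc$doc_verbs)
    fit <- fit_transform_fold(docs, list(), tc$original_verbs, "AT")
    perm_verbs <- lapply(tc$doc_verbs, sample)
    occ_a <- occurrence_matrix(setNames(tc$doc_verbs, tc$ids),
                               fit$ref_verbs, fit$model)
    occ_b <- occurrence_matrix(setNames(perm_verbs, tc$ids),
                               fit$ref_verbs, fit$model)
    expect_equal(prsf_scores(occ_a, fit$w)$score,
                 prsf_scores(occ_b, fit$w)$score, tolerance = 1e-12)
  })
})

test_that("fold fitting uses training documents only", {
  withr::with_seed(37, {
    tc <- random_tiny_corpus()
    train <- make_docs(tc$doc_lemmas, tc$doc_verbs)
    test_a <- list(list(participant_id = "t01", condition = "AT",
                        lemmas = c("w1", "w2"), verbs = "w1"))
    test_b <- list(list(participant_id = "t01", condition = "AT",
                        lemmas = rep("zzz", 5), verbs = rep("zzz", 3)))
    fit_a <- fit_transform_fold(train, test_a, tc$original_verbs, "AT")
    fit_b <- fit_transform_fold(train, test_b, tc$original_verbs, "AT")
    expect_identical(fit_a$w, fit_b$w)
    expect_identical(fit_a$model$vocabulary, fit_b$model$vocabulary)
    expect_identical(fit_a$model$k, fit_b$model$k)
    expect_identical(fit_a$ref_verbs$verbs, fit_b$ref_verbs$verbs)
    expect_identical(fit_a$train$score, fit_b$train$score)
    # all-OOV held-out document scores zero
    expect_equal(unname(fit_b$test$score["t01"]), 0)
  })
})

test_that("a held-out copy of a training document gets the same feature", {
  withr::with_seed(39, {
    tc <- random_tiny_corpus()
    train <- make_docs(tc$doc_lemmas, tc$doc_verbs)
    twin <- list(list(participant_id = "twin", condition = "AT",
                      lemmas = tc$doc_lemmas[[1]],
                      verbs = tc$doc_verbs[[1]]))
    fit <- fit_transform_fold(train, twin, tc$original_verbs, "AT")
    expect_equal(unname(fit$test$score["twin"]),
                 unname(fit$train$score[1]), tolerance = 1e-12)
  })
})

test_that("train/test participant overlap is rejected", {
  tc <- withr::with_seed(41, random_tiny_corpus())
  docs <- make_docs(tc$doc_lemmas, tc$doc_verbs)
  expect_error(fit_transform_fold(docs, docs[1], tc$original_verbs, "AT"),
               class = "prsf_fold_error")
})
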