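#' Select the reference verbs for a condition
#'
#' The reference semantic field is anchored on the original story's verbs,
#' restricted to those attested in the retelling corpus (equivalently, in the
#' training fold's vocabulary): only verbs that both belong to the source
#' story and appear among retellings can be scored. Original-story order is
#' preserved and duplicates dropped.
#'
#' @param original_story_verbs character vector of lemmatized verbs of the
#'   original story.
#' @param corpus_vocabulary vocabulary of the same condition's corpus (or
#'   training fold).
#' @param condition `"AT"` or `"nAT"`.
#' @return object of class `prsf_refverbs`: list with `condition` and `verbs`.
#' @export
select_reference_verbs <- function(original_story_verbs, corpus_vocabulary,
                                   condition) {
  condition <- match.arg(condition, CONDITIONS)
  verbs <- unique(original_story_verbs)
  verbs <- verbs[verbs %in% corpus_vocabulary]
  if (length(verbs) == 0)
    abort(sprintf(
      "no original-story verb of the %s is attested in the corpus vocabulary; the metric is undefined",
      condition), "prsf_refverbs_error")
  structure(list(condition = condition, verbs = verbs),
            class = "prsf_refverbs")
}

#' Verb importance: semantic-field weight of each reference verb
#'
#' For each reference verb, the mean cosine similarity between its topic-space
#' vector and the vectors of *all* vocabulary words (the verb itself
#' included). A verb living near the corpus's semantic mass gets a high
#' weight; an isolated verb a low one. Zero-norm vectors contribute
#' similarity 0.
#'
#' @param model a `prsf_lsa`.
#' @param ref_verbs a `prsf_refverbs` (all verbs must be in the vocabulary).
#' @return numeric vector `w` of length `n`, named by verb.
#' @export
verb_importance <- function(model, ref_verbs) {
  stopifnot(inherits(model, "prsf_lsa"), inherits(ref_verbs, "prsf_refverbs"))
  missing <- setdiff(ref_verbs$verbs, model$vocabulary)
  if (length(missing) > 0)
    abort(sprintf("reference verb(s) not in vocabulary: %s",
                  paste(missing, collapse = ", ")), "prsf_oov_error")
  D <- model$dictionary
  w <- vapply(ref_verbs$verbs, function(vb) {
    mean(cosine_similarity_rows(D, D[vb, ]))
  }, numeric(1))
  names(w) <- ref_verbs$verbs
  w
}

#' Occurrence matrix with similarity credit
#'
#' Rows are retelling documents, columns reference verbs. A cell starts as the
#' exact count of that reference verb in the document. Every retelling verb
#' token that is *not* a reference verb is then credited to its semantically
#' nearest reference verb: the token's cosine similarity to the closest
#' reference verb (ties broken toward the earliest verb in story order) is
#' added to that verb's column. Credit runs per token, so repeated
#' near-synonyms accumulate, mirroring frequency semantics. Tokens without an
#' LSA vector (out of vocabulary) contribute nothing and are counted.
#'
#' @param docs_verbs named list: per document, the character vector of its
#'   verb lemmas (duplicates preserved).
#' @param ref_verbs a `prsf_refverbs`.
#' @param model the `prsf_lsa` fitted on the same corpus (or training fold).
#' @param credit_mode `"similarity"` (cosine similarity clipped at 0, the
#'   default), `"one_minus_distance_raw"` (unclipped cosine, may be negative),
#'   or `"none"` (exact counts only).
#' @return object of class `prsf_occurrence`: list with `O` (m x n matrix),
#'   `exact` (integer matrix of exact counts), `credit` (credited similarity
#'   mass), `n_oov` (per-document count of skipped OOV verb tokens), and
#'   `ref_verbs`.
#' @export
occurrence_matrix <- function(docs_verbs, ref_verbs, model,
                              credit_mode = c("similarity",
                                              "one_minus_distance_raw",
                                              "none")) {
  credit_mode <- match.arg(credit_mode)
  stopifnot(inherits(ref_verbs, "prsf_refverbs"), inherits(model, "prsf_lsa"))
  verbs <- ref_verbs$verbs
  n <- length(verbs)
  m <- length(docs_verbs)
  ref_vecs <- model$dictionary[verbs, , drop = FALSE]
  exact <- matrix(0L, m, n, dimnames = list(names(docs_verbs), verbs))
  credit <- matrix(0, m, n, dimnames = list(names(docs_verbs), verbs))
  n_oov <- integer(m)
  names(n_oov) <- names(docs_verbs)
  for (i in seq_len(m)) {
    toks <- docs_verbs[[i]]
    if (length(toks) == 0) next
    is_ref <- toks %in% verbs
    if (any(is_ref)) {
      tab <- table(factor(toks[is_ref], levels = verbs))
      exact[i, ] <- as.integer(tab)
    }
    others <- toks[!is_ref]
    if (credit_mode == "none" || length(others) == 0) {
      n_oov[i] <- n_oov[i] + sum(!(others %in% model$vocabulary))
      next
    }
    for (t in others) {
      if (!(t %in% model$vocabulary)) {
        n_oov[i] <- n_oov[i] + 1L
        next
      }
      sims <- cosine_similarity_rows(ref_vecs, model$dictionary[t, ])
      j_star <- which.max(sims)  # which.max takes the lowest index on ties
      val <- if (credit_mode == "similarity") max(0, sims[j_star])
             else sims[j_star]
      credit[i, j_star] <- credit[i, j_star] + val
    }
  }
  structure(list(O = exact + credit, exact = exact, credit = credit,
                 n_oov = n_oov, ref_verbs = ref_verbs),
            class = "prsf_occurrence")
}

#' P-RSF matrix and per-document scores
#'
#' The proximity-to-reference-semantic-field matrix is the Hadamard
#' (element-wise) product of the occurrence matrix with the verb-importance
#' vector: `P[i, j] = O[i, j] * w[j]`. A document's scalar P-RSF score is the
#' mean of its row, so scores stay comparable when the number of attested
#' reference verbs differs across folds. Lower scores mean weaker evocation
#' of the reference story's semantic field.
#'
#' @param occurrence a `prsf_occurrence`, or a bare m x n matrix.
#' @param w verb-importance vector of length n.
#' @return object of class `prsf_matrix`: list with `P` (m x n), `score`
#'   (length m), and `w`.
#' @export
prsf_scores <- function(occurrence, w) {
  O <- if (inherits(occurrence, "prsf_occurrence")) occurrence$O else occurrence
  stopifnot(is.matrix(O), is.numeric(w))
  if (ncol(O) != length(w))
    abort(sprintf("occurrence matrix has %d columns but w has length %d",
                  ncol(O), length(w)), "prsf_shape_error")
  P <- sweep(O, 2, w, `*`)
  structure(list(P = P, score = rowMeans(P), w = w), class = "prsf_matrix")
}

#' Fit the P-RSF pipeline on training documents, transform train and test
#'
#' Fold-aware feature extraction for participant-independent validation: the
#' vocabulary, LSA model, reference-verb set, and importance weights are all
#' fitted on the training documents only; both training and held-out documents
#' are then scored with those train-fitted objects. Held-out verbs outside the
#' training vocabulary are out of vocabulary: they earn no credit and are
#' counted.
#'
#' @param train_docs,test_docs `prsf_docs` lists for a single text condition
#'   (participant-disjoint; `test_docs` may be empty).
#' @param original_story_verbs lemmatized verbs of the condition's original
#'   story.
#' @param condition `"AT"` or `"nAT"`.
#' @param variance_threshold LSA topic-selection threshold (default 0.95).
#' @param credit_mode see [occurrence_matrix()].
#' @return list with `train` and `test` (each a `prsf_matrix` plus a
#'   `features` data frame), and the fitted `model`, `ref_verbs`, `w`.
#' @export
fit_transform_fold <- function(train_docs, test_docs, original_story_verbs,
                               condition, variance_threshold = 0.95,
                               credit_mode = "similarity") {
  condition <- match.arg(condition, CONDITIONS)
  if (length(train_docs) == 0)
    abort("empty training corpus", "prsf_fold_error")
  train_ids <- vapply(train_docs, `[[`, character(1), "participant_id")
  test_ids <- vapply(test_docs, `[[`, character(1), "participant_id")
  overlap <- intersect(train_ids, test_ids)
  if (length(overlap) > 0)
    abort(sprintf("train and test share participant(s): %s",
                  paste(overlap, collapse = ", ")), "prsf_fold_error")
  dtm <- build_dtm(train_docs, condition = condition)
  model <- fit_lsa(dtm, variance_threshold = variance_threshold)
  ref_verbs <- select_reference_verbs(original_story_verbs, model$vocabulary,
                                      condition)
  w <- verb_importance(model, ref_verbs)
  score_set <- function(docs) {
    docs <- Filter(function(d) d$condition == condition, docs)
    if (length(docs) == 0) return(NULL)
    dv <- lapply(docs, `[[`, "verbs")
    names(dv) <- vapply(docs, `[[`, character(1), "participant_id")
    occ <- occurrence_matrix(dv, ref_verbs, model, credit_mode = credit_mode)
    pm <- prsf_scores(occ, w)
    pm$features <- data.frame(
      participant_id = names(dv),
      condition = condition,
      prsf_score = unname(pm$score),
      n_reference_verbs = length(ref_verbs$verbs),
      n_exact = unname(rowSums(occ$exact)),
      n_credited = unname(rowSums(occ$credit > 0)),
      n_oov = unname(occ$n_oov),
      stringsAsFactors = FALSE
    )
    pm$occurrence <- occ
    pm
  }
  list(train = score_set(train_docs), test = score_set(test_docs),
       model = model, ref_verbs = ref_verbs, w = w)
}

#' Score a whole corpus (descriptive, no fold structure)
#'
#' Convenience wrapper fitting the pipeline on all documents of a condition
#' and returning the per-participant feature table.
#'
#' @param docs a `prsf_docs` list.
#' @param original_story_verbs lemmatized verbs of the condition's original
#'   story.
#' @param condition `"AT"` or `"nAT"`.
#' @param ... passed to [fit_transform_fold()].
#' @return data frame: `participant_id`, `condition`, `prsf_score`,
#'   `n_reference_verbs`, `n_exact`, `n_credited`, `n_oov`.
#' @export
score_corpus <- function(docs, original_story_verbs, condition, ...) {
  fit <- fit_transform_fold(docs, list(), original_story_verbs, condition, ...)
  fit$train$features
}

#' Fold-aware P-RSF feature extractor for nested cross-validation
#'
#' Returns a closure `(train_ids, test_ids)` that refits the whole P-RSF
#' pipeline on the training participants' documents and returns the per-verb
#' P-RSF rows as feature matrices for both sides - the shape [nested_cv()]
#' expects.
#'
#' @param docs a `prsf_docs` list covering all participants.
#' @param original_story_verbs lemmatized verbs of the condition's original
#'   story.
#' @param condition `"AT"` or `"nAT"`.
#' @param ... passed to [fit_transform_fold()].
#' @return function `(train_ids, test_ids) -> list(train, test)`.
#' @export
prsf_feature_fn <- function(docs, original_story_verbs, condition, ...) {
  condition <- match.arg(condition, CONDITIONS)
  docs <- Filter(function(d) d$condition == condition, docs)
  ids <- vapply(docs, `[[`, character(1), "participant_id")
  function(train_ids, test_ids) {
    fit <- fit_transform_fold(docs[ids %in% train_ids],
                              docs[ids %in% test_ids],
                              original_story_verbs, condition, ...)
    list(train = fit$train$P,
         test = if (is.null(fit$test)) NULL else fit$test$P)
  }
}

#' Precomputed-matrix feature extractor
#'
#' Wraps an already-computed feature matrix (e.g., baseline embedding
#' features, which involve no corpus-level fitting) into the closure shape
#' [nested_cv()] expects; folds simply select rows.
#'
#' @param features numeric matrix with participant ids as rownames.
#' @return function `(train_ids, test_ids) -> list(train, test)`.
#' @export
matrix_feature_fn <- function(features) {
  stopifnot(is.matrix(features), !is.null(rownames(features)))
  function(train_ids, test_ids) {
    list(train = features[rownames(features) %in% train_ids, , drop = FALSE],
         test = features[rownames(features) %in% test_ids, , drop = FALSE])
  }
}
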