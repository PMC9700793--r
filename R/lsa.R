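#' Build a bag-of-words document-term matrix
#'
#' Raw occurrence counts, one row per document, one column per vocabulary
#' lemma. The vocabulary is the sorted set of unique lemmas across the
#' supplied documents. Corpora for the two text conditions are built
#' separately - each retelling set has its own vocabulary - so pass documents
#' from a single condition (or use `condition` to filter).
#'
#' @param docs a `prsf_docs` list (see [process_corpus()]), or any list of
#'   documents each carrying `participant_id`, `condition`, `lemmas`.
#' @param condition optional condition filter (`"AT"` or `"nAT"`).
#' @return object of class `prsf_dtm`: list with `counts` (m x v integer
#'   matrix), `vocabulary`, and `doc_ids` (data frame `participant_id`,
#'   `condition`).
#' @export
build_dtm <- function(docs, condition = NULL) {
  if (!is.null(condition)) {
    condition <- match.arg(condition, CONDITIONS)
    docs <- Filter(function(d) d$condition == condition, docs)
  }
  lemma_lists <- lapply(docs, `[[`, "lemmas")
  nonempty <- vapply(lemma_lists, length, integer(1)) > 0
  if (!any(nonempty))
    abort("cannot build a document-term matrix from an all-empty corpus",
          "prsf_dtm_error")
  if (!all(nonempty)) {
    warning(sprintf("%d document(s) with no surviving lemmas excluded from DTM",
                    sum(!nonempty)))
    docs <- docs[nonempty]
    lemma_lists <- lemma_lists[nonempty]
  }
  if (length(docs) < 2)
    abort("a document-term matrix needs at least 2 non-empty documents",
          "prsf_dtm_error")
  vocabulary <- sort(unique(unlist(lemma_lists)))
  m <- length(docs)
  v <- length(vocabulary)
  counts <- matrix(0L, nrow = m, ncol = v,
                   dimnames = list(NULL, vocabulary))
  for (i in seq_len(m)) {
    tab <- table(factor(lemma_lists[[i]], levels = vocabulary))
    counts[i, ] <- as.integer(tab)
  }
  doc_ids <- data.frame(
    participant_id = vapply(docs, `[[`, character(1), "participant_id"),
    condition = vapply(docs, `[[`, character(1), "condition"),
    stringsAsFactors = FALSE
  )
  rownames(counts) <- paste(doc_ids$participant_id, doc_ids$condition,
                            sep = "_")
  structure(list(counts = counts, vocabulary = vocabulary, doc_ids = doc_ids),
            class = "prsf_dtm")
}

#' Fit a latent semantic analysis model
#'
#' Singular value decomposition of the raw count matrix (no centering, no
#' tf-idf): `counts = U diag(s) V'`. The explained-variance ratio of component
#' j is `s_j^2 / sum(s^2)`, and the number of retained topics `k` is the
#' smallest integer whose cumulative ratio reaches `variance_threshold`
#' (default 0.95). The encoding matrix (documents x topics) is `U_k diag(s_k)`
#' and the dictionary matrix (words x topics) is `V_k diag(s_k)`; word vectors
#' are dictionary rows. Each component's sign is fixed so its
#' largest-magnitude dictionary loading is positive; cosine geometry between
#' word vectors is unaffected by this choice.
#'
#' @param dtm a `prsf_dtm`.
#' @param variance_threshold cumulative explained-variance target in (0, 1].
#' @return object of class `prsf_lsa`: list with `encoding`, `dictionary`,
#'   `singular_values`, `variance_ratio`, `k`, `variance_threshold`,
#'   `vocabulary`, `doc_ids`.
#' @export
fit_lsa <- function(dtm, variance_threshold = 0.95) {
  stopifnot(inherits(dtm, "prsf_dtm"))
  if (!is_scalar_number(variance_threshold) ||
      variance_threshold <= 0 || variance_threshold > 1)
    abort("variance_threshold must be a number in (0, 1]", "prsf_lsa_error")
  X <- dtm$counts
  sv <- svd(X)
  s <- sv$d
  total <- sum(s^2)
  ratio <- if (total > 0) s^2 / total else rep(0, length(s))
  k <- select_k(ratio, variance_threshold)
  # numerical rank guard: never retain components with (near-)zero variance
  rank_tol <- max(dim(X)) * max(s) * .Machine$double.eps
  num_rank <- sum(s > rank_tol)
  if (k > num_rank) {
    message(sprintf(
      "variance threshold %.3f needs %d components but numerical rank is %d; using %d",
      variance_threshold, k, num_rank, num_rank))
    k <- num_rank
  }
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  sk <- s[seq_len(k)]
  encoding <- sweep(U, 2, sk, `*`)
  dictionary <- sweep(V, 2, sk, `*`)
  rownames(dictionary) <- dtm$vocabulary
  rownames(encoding) <- rownames(X)
  structure(list(
    encoding = encoding, dictionary = dictionary, singular_values = s,
    variance_ratio = ratio, k = k, variance_threshold = variance_threshold,
    vocabulary = dtm$vocabulary, doc_ids = dtm$doc_ids
  ), class = "prsf_lsa")
}

# smallest k with cumulative explained variance >= threshold (tolerant to
# floating-point shortfall at threshold 1)
select_k <- function(ratio, threshold) {
  cum <- cumsum(ratio)
  hit <- which(cum >= threshold - 1e-12)
  if (length(hit) == 0) length(ratio) else hit[1]
}

#' Test vocabulary membership
#' @param model a `prsf_lsa`.
#' @param words character vector.
#' @return logical vector.
#' @export
in_vocabulary <- function(model, words) {
  words %in% model$vocabulary
}

#' Retrieve a word's topic-space vector
#'
#' Returns the word's row of the dictionary matrix. Querying a word outside
#' the vocabulary raises a classed error (`prsf_oov_error`) rather than
#' returning zeros: absence from the vocabulary and the zero vector are
#' different facts, and callers decide the fallback.
#'
#' @param model a `prsf_lsa`.
#' @param word a single lemma.
#' @return numeric vector of length `model$k`.
#' @export
word_vector <- function(model, word) {
  stopifnot(inherits(model, "prsf_lsa"), is.character(word),
            length(word) == 1L)
  if (!(word %in% model$vocabulary))
    abort(sprintf("word '%s' is not in the model vocabulary", word),
          "prsf_oov_error")
  model$dictionary[word, ]
}
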