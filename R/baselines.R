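#' Verb-to-verb distance baseline features
#'
#' For each document, a length-n vector: the mean cosine distance between the
#' retelling's verb tokens and each original-story verb, computed in a
#' user-supplied embedding space (e.g., pre-trained GloVe vectors). Retelling
#' verbs missing from the embedding vocabulary are skipped and counted; a
#' document with no usable verb gets a missing row (`NA`), flagged for
#' exclusion.
#'
#' @param docs_verbs named list of per-document verb lemma vectors.
#' @param original_verbs character vector of original-story verbs; all must
#'   have embeddings.
#' @param embeddings a `prsf_embeddings`.
#' @return list with `features` (m x n matrix, `NA` rows for excluded
#'   documents), `n_oov_skipped` (per document), `excluded` (document names).
#' @export
verb_distance_features <- function(docs_verbs, original_verbs, embeddings) {
  stopifnot(inherits(embeddings, "prsf_embeddings"))
  lk <- embedding_lookup(embeddings, original_verbs)
  if (length(lk$oov) > 0)
    abort(sprintf("original-story verb(s) without embeddings: %s",
                  paste(lk$oov, collapse = ", ")), "prsf_oov_error")
  ref <- lk$vectors
  n <- nrow(ref)
  m <- length(docs_verbs)
  feats <- matrix(NA_real_, m, n,
                  dimnames = list(names(docs_verbs), original_verbs))
  n_oov <- integer(m)
  names(n_oov) <- names(docs_verbs)
  for (i in seq_len(m)) {
    toks <- docs_verbs[[i]]
    inv <- toks %in% rownames(embeddings$vectors)
    n_oov[i] <- sum(!inv)
    toks <- toks[inv]
    if (length(toks) == 0) next
    # distance of token t to original verb j, averaged over tokens
    dmat <- vapply(toks, function(t) {
      1 - cosine_similarity_rows(ref, embeddings$vectors[t, ])
    }, numeric(n))
    feats[i, ] <- if (n == 1L) mean(dmat) else rowMeans(matrix(dmat, nrow = n))
  }
  excluded <- names(docs_verbs)[rowSums(is.na(feats)) > 0]
  if (length(excluded) > 0)
    warning(sprintf("document(s) with no usable verb excluded: %s",
                    paste(excluded, collapse = ", ")))
  list(features = feats, n_oov_skipped = n_oov, excluded = excluded)
}

#' Mean-embedding baseline features
#'
#' Each document is represented by the arithmetic mean of the embeddings of
#' all its (post-preprocessing) lemmas. Out-of-vocabulary lemmas are skipped
#' and counted; documents with no in-vocabulary lemma get a missing row.
#'
#' @param docs_lemmas named list of per-document lemma vectors.
#' @param embeddings a `prsf_embeddings`.
#' @return list with `features` (m x d matrix), `n_oov_skipped`, `excluded`.
#' @export
mean_embedding_features <- function(docs_lemmas, embeddings) {
  stopifnot(inherits(embeddings, "prsf_embeddings"))
  m <- length(docs_lemmas)
  d <- embeddings$d
  feats <- matrix(NA_real_, m, d, dimnames = list(names(docs_lemmas), NULL))
  n_oov <- integer(m)
  names(n_oov) <- names(docs_lemmas)
  for (i in seq_len(m)) {
    toks <- docs_lemmas[[i]]
    inv <- toks %in% rownames(embeddings$vectors)
    n_oov[i] <- sum(!inv)
    toks <- toks[inv]
    if (length(toks) == 0) next
    feats[i, ] <- colMeans(embeddings$vectors[toks, , drop = FALSE])
  }
  excluded <- names(docs_lemmas)[rowSums(is.na(feats)) > 0]
  if (length(excluded) > 0)
    warning(sprintf("document(s) with no in-vocabulary lemma excluded: %s",
                    paste(excluded, collapse = ", ")))
  list(features = feats, n_oov_skipped = n_oov, excluded = excluded)
}
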