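# Independent brute-force oracles: explicit loops and full decompositions,
# written against the definitions, not against the package internals.

oracle_cos <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# full-SVD topic count: smallest k whose cumulative variance ratio reaches
# the threshold, found by explicit accumulation
oracle_k <- function(counts, threshold) {
  s <- svd(counts)$d
  ratios <- s^2 / sum(s^2)
  acc <- 0
  for (k in seq_along(ratios)) {
    acc <- acc + ratios[k]
    if (acc >= threshold - 1e-12) return(k)
  }
  length(ratios)
}

# end-to-end P-RSF scores recomputed step by step with loops and a full SVD
oracle_prsf <- function(doc_lemmas, doc_verbs, original_verbs,
                        threshold = 0.95) {
  vocab <- sort(unique(unlist(doc_lemmas)))
  m <- length(doc_lemmas)
  v <- length(vocab)
  counts <- matrix(0, m, v)
  for (i in seq_len(m))
    for (tok in doc_lemmas[[i]])
      counts[i, which(vocab == tok)] <- counts[i, which(vocab == tok)] + 1
  sv <- svd(counts)
  k <- oracle_k(counts, threshold)
  # guard against retaining numerically-zero components, as the pipeline does
  rank_tol <- max(dim(counts)) * max(sv$d) * .Machine$double.eps
  k <- min(k, sum(sv$d > rank_tol))
  D <- matrix(0, v, k)
  for (j in seq_len(k)) D[, j] <- sv$v[, j] * sv$d[j]
  vec_of <- function(word) D[which(vocab == word), ]
  ref <- character(0)
  for (vb in original_verbs)
    if (vb %in% vocab && !(vb %in% ref)) ref <- c(ref, vb)
  if (length(ref) == 0) stop("oracle: no attested reference verb")
  n <- length(ref)
  w <- numeric(n)
  for (j in seq_len(n)) {
    acc <- 0
    for (u in vocab) acc <- acc + oracle_cos(vec_of(ref[j]), vec_of(u))
    w[j] <- acc / v
  }
  O <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (tok in doc_verbs[[i]]) {
      hit <- which(ref == tok)
      if (length(hit) == 1) {
        O[i, hit] <- O[i, hit] + 1
      } else if (tok %in% vocab) {
        sims <- numeric(n)
        for (j in seq_len(n)) sims[j] <- oracle_cos(vec_of(tok), vec_of(ref[j]))
        j_star <- 1
        for (j in seq_len(n)) if (sims[j] > sims[j_star]) j_star <- j
        O[i, j_star] <- O[i, j_star] + max(0, sims[j_star])
      }
    }
  }
  P <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) P[i, j] <- O[i, j] * w[j]
  score <- numeric(m)
  for (i in seq_len(m)) score[i] <- sum(P[i, ]) / n
  list(score = score, w = w, k = k, ref = ref, O = O)
}

# random tiny corpus: <= 6 documents over a <= 12-word universe with a
# designated verb subset; guarantees >= 2 non-empty docs and >= 1 attested
# original verb
random_tiny_corpus <- function() {
  v_universe <- sample(6:12, 1)
  words <- paste0("w", letters[seq_len(v_universe)])
  verbs <- sample(words, sample(2:4, 1))
  m <- sample(2:6, 1)
  doc_lemmas <- lapply(seq_len(m), function(i)
    sample(words, sample(3:10, 1), replace = TRUE))
  # make sure at least one original verb is attested
  doc_lemmas[[1]] <- c(doc_lemmas[[1]], verbs[1])
  doc_verbs <- lapply(doc_lemmas, function(l) l[l %in% verbs])
  original_verbs <- unique(c(verbs[1], sample(words, 2)))
  ids <- sprintf("s%02d", seq_len(m))
  docs <- lapply(seq_len(m), function(i)
    list(participant_id = ids[i], condition = "AT",
         lemmas = doc_lemmas[[i]], verbs = doc_verbs[[i]]))
  list(docs = docs, doc_lemmas = doc_lemmas, doc_verbs = doc_verbs,
       original_verbs = original_verbs, ids = ids)
}

# fake LSA model with hand-set word vectors, for exact-value tests
fake_lsa <- function(dictionary) {
  structure(list(dictionary = dictionary, vocabulary = rownames(dictionary),
                 k = ncol(dictionary)),
            class = "prsf_lsa")
}

make_docs <- function(lemmas_list, verbs_list = NULL, condition = "AT") {
  n <- length(lemmas_list)
  docs <- lapply(seq_len(n), function(i)
    list(participant_id = sprintf("d%02d", i), condition = condition,
         lemmas = lemmas_list[[i]],
         verbs = if (is.null(verbs_list)) character() else verbs_list[[i]]))
  structure(docs, class = "prsf_docs")
}
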