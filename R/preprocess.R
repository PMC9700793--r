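#' Linguistic backends
#'
#' Normalization and verb extraction are parameterized by a *backend*: a small
#' object bundling a lemmatizer, a part-of-speech tagger, and a stopword list.
#' Backends are deterministic by contract, and injectable so analyses can run
#' with a dictionary backend (exact, no external models) or a heuristic
#' Spanish backend.
#'
#' @param lemma_map named character vector mapping normalized surface forms to
#'   lemmas; unmapped forms lemmatize to themselves.
#' @param verbs character vector of forms tagged `VERB` (matched on the
#'   lowercased, accent-stripped token); everything else is tagged `NOUN`.
#' @param stopwords character vector of stopwords (lowercase, accent-free).
#' @param name backend label, recorded in outputs.
#' @return An object of class `prsf_backend` with elements `lemmatize`
#'   (character vector in, character vector out), `pos_tag` (tokens in, tags
#'   out), `stopwords`, and `name`.
#' @export
backend_dictionary <- function(lemma_map = character(), verbs = character(),
                               stopwords = prsf_stopwords(),
                               name = "dictionary") {
  stopifnot(is.character(lemma_map), is.character(verbs))
  verb_set <- strip_accents(tolower(verbs))
  structure(list(
    name = name,
    lemmatize = function(words) {
      key <- strip_accents(tolower(words))
      out <- unname(lemma_map[key])
      out[is.na(out)] <- key[is.na(out)]
      out
    },
    pos_tag = function(tokens) {
      ifelse(strip_accents(tolower(tokens)) %in% verb_set, "VERB", "NOUN")
    },
    stopwords = stopwords
  ), class = "prsf_backend")
}

#' Heuristic Spanish backend
#'
#' A rule-based fallback: words ending in common Spanish verbal suffixes are
#' tagged `VERB` and mapped to a crude infinitive; everything else is left as
#' its own lemma. Intended for exploratory runs on real Spanish transcripts
#' when no trained tagger is wired in; all quantitative validation in this
#' package uses dictionary backends, where lemmas and tags are exact.
#'
#' @param stopwords stopword list, default the builtin Spanish list.
#' @return A `prsf_backend`.
#' @export
backend_spanish_heuristic <- function(stopwords = prsf_stopwords()) {
  infinitive_guess <- function(w) {
    if (grepl("(ar|er|ir)$", w)) return(w)
    if (grepl("(aba|aban|amos|aron|ando|ada|ado|ara|o)$", w))
      return(sub("(aba|aban|amos|aron|ando|ada|ado|ara|o)$", "ar", w))
    if (grepl("(ieron|iendo|ido|ida|imos|io|e|en)$", w))
      return(sub("(ieron|iendo|ido|ida|imos|io|e|en)$", "er", w))
    w
  }
  looks_verbal <- function(w) {
    grepl("(ar|er|ir|aba|aban|amos|aron|ando|iendo|ado|ido|ieron|io)$", w) &
      nchar(w) > 3
  }
  structure(list(
    name = "spanish_heuristic",
    lemmatize = function(words) {
      vapply(strip_accents(tolower(words)), infinitive_guess, character(1),
             USE.NAMES = FALSE)
    },
    pos_tag = function(tokens) {
      key <- strip_accents(tolower(tokens))
      ifelse(looks_verbal(key) & !(key %in% stopwords), "VERB", "NOUN")
    },
    stopwords = stopwords
  ), class = "prsf_backend")
}

#' Strip accents and diacritics
#'
#' Unicode NFD decomposition followed by removal of combining marks. The
#' letter "n-tilde" is preserved by default: it is a distinct letter of the
#' Spanish alphabet, not an accented variant.
#'
#' @param x character vector.
#' @param keep_enye keep "ñ" / "Ñ" intact (default `TRUE`).
#' @return character vector with base letters only.
#' @export
strip_accents <- function(x, keep_enye = TRUE) {
  if (keep_enye) {
    x <- stringi::stri_replace_all_fixed(x, c("ñ", "Ñ"),
                                         c("\uE000", "\uE001"),
                                         vectorize_all = FALSE)
  }
  x <- stringi::stri_trans_general(x, "NFD; [:Nonspacing Mark:] Remove; NFC")
  if (keep_enye) {
    x <- stringi::stri_replace_all_fixed(x, c("\uE000", "\uE001"),
                                         c("ñ", "Ñ"),
                                         vectorize_all = FALSE)
  }
  x
}

# Unicode word tokenization: runs of letters/marks/digits; punctuation is
# discarded by construction.
tokenize <- function(text) {
  toks <- stringi::stri_extract_all_regex(text, "[\\p{L}\\p{M}\\p{N}]+")[[1]]
  if (length(toks) == 1L && is.na(toks[1])) character() else toks
}

#' Normalize raw text to a lemma sequence
#'
#' Fixed pipeline order: (1) lowercase, (2) strip accents, (3) delete tokens
#' containing digits, (4) delete punctuation (implicit in tokenization),
#' (5) delete stopwords, (6) lemmatize the survivors. An empty result is
#' legal (a transcript of nothing but noise).
#'
#' @param raw_text a single string.
#' @param backend a `prsf_backend`.
#' @param keep_enye see [strip_accents()].
#' @return character vector of lemmas (lowercase, accent-free).
#' @export
normalize_text <- function(raw_text, backend, keep_enye = TRUE) {
  stopifnot(inherits(backend, "prsf_backend"),
            is.character(raw_text), length(raw_text) == 1L)
  x <- strip_accents(tolower(raw_text), keep_enye = keep_enye)
  toks <- tokenize(x)
  toks <- toks[!grepl("[0-9]", toks)]
  toks <- toks[!(toks %in% backend$stopwords)]
  if (length(toks) == 0L) return(character())
  lemmas <- backend$lemmatize(toks)
  lemmas <- strip_accents(tolower(lemmas), keep_enye = keep_enye)
  lemmas[nzchar(lemmas)]
}

#' Extract verb lemmas from raw text
#'
#' The tagger runs on the raw token stream (before normalization) so it sees
#' case, accents and context; the returned verb lemmas are then normalized
#' into the same space as [normalize_text()] output. Order of occurrence and
#' duplicates are preserved - occurrence counts matter downstream.
#'
#' @inheritParams normalize_text
#' @return character vector of normalized verb lemmas.
#' @export
extract_verbs <- function(raw_text, backend, keep_enye = TRUE) {
  stopifnot(inherits(backend, "prsf_backend"),
            is.character(raw_text), length(raw_text) == 1L)
  toks <- tokenize(raw_text)
  toks <- toks[!grepl("[0-9]", toks)]
  if (length(toks) == 0L) return(character())
  tags <- backend$pos_tag(toks)
  vtoks <- toks[tags == "VERB"]
  # verbs whose surface form is a stopword were removed from the lemma stream,
  # so they are excluded here too, keeping verbs within the lemma space
  keep <- !(strip_accents(tolower(vtoks), keep_enye = keep_enye) %in%
              backend$stopwords)
  vtoks <- vtoks[keep]
  if (length(vtoks) == 0L) return(character())
  lemmas <- backend$lemmatize(vtoks)
  lemmas <- strip_accents(tolower(lemmas), keep_enye = keep_enye)
  lemmas[nzchar(lemmas)]
}

#' Process a transcript corpus into lemma/verb documents
#'
#' @param transcripts data frame with columns `participant_id`, `condition`,
#'   `raw_text` (as returned by [read_corpus()] or [generate_study()]).
#' @param backend a `prsf_backend`.
#' @param keep_enye see [strip_accents()].
#' @return list of processed documents, each a list with `participant_id`,
#'   `condition`, `lemmas`, `verbs`; class `prsf_docs`.
#' @export
process_corpus <- function(transcripts, backend, keep_enye = TRUE) {
  stopifnot(is.data.frame(transcripts),
            all(c("participant_id", "condition", "raw_text") %in%
                  names(transcripts)))
  docs <- lapply(seq_len(nrow(transcripts)), function(i) {
    list(
      participant_id = transcripts$participant_id[i],
      condition = transcripts$condition[i],
      lemmas = normalize_text(transcripts$raw_text[i], backend, keep_enye),
      verbs = extract_verbs(transcripts$raw_text[i], backend, keep_enye)
    )
  })
  names(docs) <- paste(transcripts$participant_id, transcripts$condition,
                       sep = "_")
  structure(docs, class = "prsf_docs")
}
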