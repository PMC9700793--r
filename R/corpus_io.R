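GROUP_LEVELS <- c("HC", "PD-nMCI", "PD-MCI")
CONDITIONS <- c("AT", "nAT")

canon_group <- function(x) {
  y <- gsub("_", "-", trimws(x))
  y[toupper(y) == "HC"] <- "HC"
  y[toupper(y) == "PD-NMCI"] <- "PD-nMCI"
  y[toupper(y) == "PD-MCI"] <- "PD-MCI"
  y
}

#' Read a participant metadata table
#'
#' Comma-delimited UTF-8 CSV with required columns `participant_id`, `group`,
#' `moca`, `ifs`, `updrs3`; a missing UPDRS-III value is an empty field.
#' Optional descriptor columns (`sex`, `age`, `education`, ...) are carried
#' through untouched. Group labels must be one of `HC`, `PD-nMCI`, `PD-MCI`
#' (underscores accepted and canonicalized).
#'
#' @param path CSV file path.
#' @return data frame of participant records.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path))
    abort(sprintf("metadata file not found: %s", path), "prsf_io_error")
  md <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("participant_id", "group", "moca", "ifs", "updrs3")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols) > 0)
    abort(sprintf("metadata is missing required columns: %s",
                  paste(missing_cols, collapse = ", ")), "prsf_io_error")
  md$participant_id <- trimws(as.character(md$participant_id))
  if (any(!nzchar(md$participant_id)))
    abort("metadata contains empty participant_id values", "prsf_io_error")
  if (anyDuplicated(md$participant_id))
    abort(sprintf("duplicate participant_id in metadata: %s",
                  paste(unique(md$participant_id[duplicated(md$participant_id)]),
                        collapse = ", ")), "prsf_io_error")
  md$group <- canon_group(md$group)
  bad <- !(md$group %in% GROUP_LEVELS)
  if (any(bad))
    abort(sprintf(
      "unknown group label(s) %s in metadata row(s) %s (participant %s)",
      paste(unique(md$group[bad]), collapse = ", "),
      paste(which(bad), collapse = ", "),
      paste(md$participant_id[bad], collapse = ", ")), "prsf_io_error")
  for (col in c("moca", "ifs", "updrs3")) md[[col]] <- as.numeric(md[[col]])
  md
}

#' Read a transcript corpus and its metadata
#'
#' Transcripts live one per file in `directory_path`, named
#' `<participant_id>_<condition>.txt` with condition `AT` or `nAT`. Every
#' transcript must match exactly one metadata row; a transcript whose
#' participant is absent from the metadata is a hard error listing the ids.
#'
#' @param directory_path directory containing `.txt` transcript files.
#' @param metadata_path path to the metadata CSV (see [read_metadata()]).
#' @return list with `transcripts` (data frame: `participant_id`, `condition`,
#'   `raw_text`) and `metadata` (data frame of participant records).
#' @export
read_corpus <- function(directory_path, metadata_path) {
  if (!dir.exists(directory_path))
    abort(sprintf("corpus directory not found: %s", directory_path),
          "prsf_io_error")
  metadata <- read_metadata(metadata_path)
  files <- list.files(directory_path, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0)
    abort(sprintf("no .txt transcripts in %s", directory_path),
          "prsf_io_error")
  base <- sub("\\.txt$", "", basename(files))
  m <- regmatches(base, regexec("^(.+)_(AT|nAT)$", base))
  bad_name <- vapply(m, length, integer(1)) != 3L
  if (any(bad_name))
    abort(sprintf("transcript filename(s) not of form <id>_<AT|nAT>.txt: %s",
                  paste(basename(files)[bad_name], collapse = ", ")),
          "prsf_io_error")
  ids <- vapply(m, `[`, character(1), 2L)
  conds <- vapply(m, `[`, character(1), 3L)
  key <- paste(ids, conds, sep = "_")
  if (anyDuplicated(key))
    abort(sprintf("duplicate (participant, condition) transcript(s): %s",
                  paste(key[duplicated(key)], collapse = ", ")),
          "prsf_io_error")
  texts <- vapply(files, function(f)
    paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n"),
    character(1), USE.NAMES = FALSE)
  empty <- !nzchar(trimws(texts))
  if (any(empty))
    abort(sprintf("empty transcript file(s): %s",
                  paste(basename(files)[empty], collapse = ", ")),
          "prsf_io_error")
  unmatched <- setdiff(ids, metadata$participant_id)
  if (length(unmatched) > 0)
    abort(sprintf("transcript(s) with no metadata row: %s",
                  paste(sort(unique(unmatched)), collapse = ", ")),
          "prsf_io_error")
  transcripts <- data.frame(
    participant_id = ids, condition = conds, raw_text = texts,
    stringsAsFactors = FALSE
  )
  transcripts <- transcripts[order(transcripts$participant_id,
                                   transcripts$condition), ]
  rownames(transcripts) <- NULL
  no_transcript <- setdiff(metadata$participant_id, ids)
  if (length(no_transcript) > 0)
    warning(sprintf("metadata row(s) with no transcript: %s",
                    paste(no_transcript, collapse = ", ")))
  list(transcripts = transcripts, metadata = metadata)
}

#' Write a corpus in the on-disk layout [read_corpus()] expects
#'
#' @param transcripts transcript data frame.
#' @param metadata participant metadata data frame.
#' @param directory_path output directory (created if needed).
#' @param metadata_file name of the metadata CSV within the directory.
#' @return invisibly, the metadata file path.
#' @export
write_corpus <- function(transcripts, metadata, directory_path,
                         metadata_file = "metadata.csv") {
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(transcripts))) {
    f <- file.path(directory_path, sprintf("%s_%s.txt",
                                           transcripts$participant_id[i],
                                           transcripts$condition[i]))
    writeLines(transcripts$raw_text[i], f, useBytes = TRUE)
  }
  mpath <- file.path(directory_path, metadata_file)
  utils::write.csv(metadata, mpath, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(mpath)
}

#' Read word vectors in GloVe / word2vec plain-text format
#'
#' Each line is a token followed by `d` whitespace-separated numbers. An
#' optional first line `"<vocab_size> <d>"` (the word2vec-text header) is
#' auto-detected. Duplicated tokens keep the first occurrence with a warning;
#' inconsistent vector lengths are a hard error naming the line.
#'
#' @param path vector file path.
#' @return object of class `prsf_embeddings`: list with `vectors` (matrix,
#'   rownames = tokens) and `d`.
#' @export
read_word_vectors <- function(path) {
  if (!file.exists(path))
    abort(sprintf("embedding file not found: %s", path), "prsf_io_error")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    abort("embedding file is empty", "prsf_io_error")
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  offset <- 0L
  if (length(first) == 2 && !anyNA(suppressWarnings(as.numeric(first)))) {
    offset <- 1L  # word2vec-style "<vocab> <dim>" header
    lines <- lines[-1]
  }
  if (length(lines) == 0)
    abort("embedding file has a header but no vectors", "prsf_io_error")
  parts <- strsplit(trimws(lines), "\\s+")
  d <- length(parts[[1]]) - 1L
  if (d < 1)
    abort(sprintf("line %d: no vector components", 1L + offset),
          "prsf_io_error")
  lens <- vapply(parts, length, integer(1)) - 1L
  bad <- which(lens != d)
  if (length(bad) > 0)
    abort(sprintf("line %d: expected %d vector components, found %d",
                  bad[1] + offset, d, lens[bad[1]]), "prsf_io_error")
  tokens <- vapply(parts, `[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  vecs <- if (d == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(vecs))
    abort("embedding file contains non-numeric vector components",
          "prsf_io_error")
  if (anyDuplicated(tokens)) {
    dup <- unique(tokens[duplicated(tokens)])
    warning(sprintf("duplicate token(s) in embedding file, keeping first: %s",
                    paste(utils::head(dup, 5), collapse = ", ")))
    keep <- !duplicated(tokens)
    tokens <- tokens[keep]
    vecs <- vecs[keep, , drop = FALSE]
  }
  rownames(vecs) <- tokens
  structure(list(vectors = vecs, d = d), class = "prsf_embeddings")
}

#' Build an embedding table from a token-by-dimension matrix
#'
#' @param vectors numeric matrix with one row per token; rownames are tokens.
#' @return A `prsf_embeddings` object.
#' @export
embedding_table <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)),
            ncol(vectors) >= 1)
  structure(list(vectors = vectors, d = ncol(vectors)),
            class = "prsf_embeddings")
}

#' Look up embeddings, distinguishing out-of-vocabulary tokens
#'
#' @param embeddings a `prsf_embeddings`.
#' @param words character vector.
#' @return list with `vectors` (matrix for in-vocabulary words) and `oov`
#'   (character vector of absent words). The zero vector is a legal embedding;
#'   absence is signalled by membership in `oov`, never by zeros.
#' @export
embedding_lookup <- function(embeddings, words) {
  stopifnot(inherits(embeddings, "prsf_embeddings"))
  inv <- words %in% rownames(embeddings$vectors)
  list(vectors = embeddings$vectors[words[inv], , drop = FALSE],
       oov = words[!inv])
}
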