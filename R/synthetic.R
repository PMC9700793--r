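# Synthetic tokens are letter-only (digits are deleted by normalization).
letter_code <- function(i) {
  paste0(letters[(i - 1) %/% 26 + 1], letters[(i - 1) %% 26 + 1])
}

random_unit <- function(d) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2))
}

# unit vector at a prescribed cosine to v
vector_at_cosine <- function(v, cos_target) {
  d <- length(v)
  u <- stats::rnorm(d)
  u <- u - sum(u * v) * v
  u <- u / sqrt(sum(u^2))
  cos_target * v + sqrt(1 - cos_target^2) * u
}

#' Configure a synthetic retelling study
#'
#' The generator emulates the study design the scoring pipeline targets: two
#' reference stories with disjoint verb inventories - an action story (27
#' verbs) and a non-action story (23 verbs) - retold by participants from
#' three groups (`HC`, `PD-nMCI`, `PD-MCI`). Each participant retells both
#' stories; each reference verb is reproduced with a group- and
#' condition-dependent retention probability (jittered per participant on the
#' logit scale), may be paraphrased into a near-synonym (latent cosine >=
#' 0.7), and is interleaved with theme nouns, off-field filler words, and
#' stopwords. Covariates (MoCA, IFS) are drawn from group-dependent normals;
#' UPDRS-III only for patient groups.
#'
#' @param n_per_group named counts for `HC`, `PD-nMCI`, `PD-MCI` (any subset).
#' @param retention matrix of retention probabilities, rownames = groups,
#'   colnames = `AT`, `nAT`.
#' @param retention_sd per-participant logit-scale jitter of retention
#'   (default 0.6), giving realistic between-subject spread.
#' @param paraphrase_rate probability a retained verb surfaces as a
#'   near-synonym instead of the original form (default 0.2).
#' @param distractor_rate expected number of filler words per retelling
#'   (default 12).
#' @param noun_rate probability each theme noun is mentioned (default 0.6).
#' @param n_ref reference-verb counts per condition (default `c(AT = 27,
#'   nAT = 23)`, the attested inventory sizes of the target design).
#' @param n_synonyms near-synonyms generated per reference verb (default 2).
#' @param n_nouns theme nouns per condition (default 18).
#' @param n_fillers size of the shared off-field filler pool (default 120).
#' @param latent_dim dimensionality of the latent semantic vectors
#'   (default 8).
#' @param covariate_model list of per-group `mean`/`sd` for `moca`, `ifs`,
#'   `updrs3` (see [default_pd_scenario()] for the shape).
#' @param confound_covariates if `TRUE`, MoCA is additionally tied to the
#'   participant's realized retention, creating a confounded design for
#'   stress-testing covariate adjustment (default `FALSE`).
#' @param seed integer seed; generation is deterministic given the config.
#' @return object of class `prsf_simconfig`.
#' @export
sim_config <- function(n_per_group, retention, retention_sd = 0.6,
                       paraphrase_rate = 0.2, distractor_rate = 12,
                       noun_rate = 0.6, n_ref = c(AT = 27, nAT = 23),
                       n_synonyms = 2L, n_nouns = 18L, n_fillers = 120L,
                       latent_dim = 8L, covariate_model = NULL,
                       confound_covariates = FALSE, seed = 1L) {
  stopifnot(all(names(n_per_group) %in% GROUP_LEVELS),
            is.matrix(retention),
            all(colnames(retention) == CONDITIONS) ||
              all(CONDITIONS %in% colnames(retention)))
  missing_cells <- setdiff(names(n_per_group), rownames(retention))
  if (length(missing_cells) > 0)
    abort(sprintf("retention matrix lacks row(s) for group(s): %s",
                  paste(missing_cells, collapse = ", ")), "prsf_sim_error")
  if (any(retention < 0 | retention > 1))
    abort("retention probabilities must lie in [0, 1]", "prsf_sim_error")
  if (any(n_ref < 5))
    abort("each condition needs at least 5 reference verbs", "prsf_sim_error")
  if (is.null(covariate_model)) covariate_model <- default_covariate_model()
  structure(list(
    n_per_group = n_per_group, retention = retention,
    retention_sd = retention_sd, paraphrase_rate = paraphrase_rate,
    distractor_rate = distractor_rate, noun_rate = noun_rate, n_ref = n_ref,
    n_synonyms = as.integer(n_synonyms), n_nouns = as.integer(n_nouns),
    n_fillers = as.integer(n_fillers), latent_dim = as.integer(latent_dim),
    covariate_model = covariate_model,
    confound_covariates = confound_covariates, seed = as.integer(seed)
  ), class = "prsf_simconfig")
}

default_covariate_model <- function() {
  list(
    moca = list("HC" = c(26.7, 1.6), "PD-nMCI" = c(26.3, 1.5),
                "PD-MCI" = c(21.5, 2.0)),
    ifs = list("HC" = c(22.9, 2.7), "PD-nMCI" = c(20.5, 3.0),
               "PD-MCI" = c(18.0, 3.0)),
    updrs3 = list("HC" = NULL, "PD-nMCI" = c(29.0, 12.0),
                  "PD-MCI" = c(34.0, 12.0))
  )
}

#' Default clinical scenario
#'
#' Retention probabilities encode the expected dissociation: controls retain
#' verbs of both stories well (0.8); patients without mild cognitive
#' impairment lose action verbs selectively (AT 0.5, nAT 0.8); patients with
#' mild cognitive impairment lose verbs of both stories (AT 0.5, nAT 0.55).
#' MoCA means are ordered HC > PD-nMCI > PD-MCI.
#'
#' @param seed integer seed.
#' @param n_per_group group sizes; default mirrors a 40 / 24 / 16 cohort.
#' @return a `prsf_simconfig`.
#' @export
default_pd_scenario <- function(seed = 1L,
                                n_per_group = c("HC" = 40L, "PD-nMCI" = 24L,
                                                "PD-MCI" = 16L)) {
  retention <- matrix(
    c(0.80, 0.80,
      0.50, 0.80,
      0.50, 0.55),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("HC", "PD-nMCI", "PD-MCI"), CONDITIONS))
  sim_config(n_per_group = n_per_group,
             retention = retention[names(n_per_group), , drop = FALSE],
             seed = seed)
}

#' Null scenario: no group effect
#'
#' All groups share the same retention probabilities; covariate models keep
#' their group differences, so adjusted analyses can be checked for false
#' positives.
#'
#' @inheritParams default_pd_scenario
#' @param retention_value common retention probability (default 0.65).
#' @return a `prsf_simconfig`.
#' @export
null_scenario <- function(seed = 1L,
                          n_per_group = c("HC" = 40L, "PD-nMCI" = 40L),
                          retention_value = 0.65) {
  retention <- matrix(retention_value, nrow = length(n_per_group), ncol = 2,
                      dimnames = list(names(n_per_group), CONDITIONS))
  sim_config(n_per_group = n_per_group, retention = retention, seed = seed)
}

#' Generate a complete synthetic study
#'
#' Produces transcripts and metadata in exactly the corpus layout the readers
#' expect, plus the generating truth, a dictionary linguistic backend for the
#' synthetic language (identity lemmas, exact verb tags), the latent
#' embedding table, and the per-condition reference-verb inventories.
#'
#' @param config a `prsf_simconfig`.
#' @return object of class `prsf_study`: list with `transcripts`, `metadata`,
#'   `truth`, `backend`, `embeddings`, `reference_verbs`, `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "prsf_simconfig"))
  withr::with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(config) {
  d <- config$latent_dim
  inv <- list()
  vectors <- list()
  for (cond in CONDITIONS) {
    prefix <- if (cond == "AT") "atv" else "ntv"
    nref <- config$n_ref[[cond]]
    verbs <- paste0(prefix, vapply(seq_len(nref), letter_code, character(1)))
    vverbs <- lapply(verbs, function(x) random_unit(d))
    syns <- list()
    for (j in seq_len(nref)) {
      for (s in seq_len(config$n_synonyms)) {
        nm <- paste0(verbs[j], "x", letters[s])
        syns[[nm]] <- vector_at_cosine(vverbs[[j]],
                                       stats::runif(1, 0.75, 0.95))
      }
    }
    nprefix <- if (cond == "AT") "atn" else "ntn"
    nouns <- paste0(nprefix,
                    vapply(seq_len(config$n_nouns), letter_code, character(1)))
    vnouns <- lapply(nouns, function(x) random_unit(d))
    names(vverbs) <- verbs
    names(vnouns) <- nouns
    inv[[cond]] <- list(verbs = verbs,
                        synonyms = split(names(syns),
                                         rep(verbs, each = config$n_synonyms)),
                        nouns = nouns)
    vectors <- c(vectors, vverbs, syns, vnouns)
  }
  fillers <- paste0("fil", vapply(seq_len(config$n_fillers), letter_code,
                                  character(1)))
  for (f in fillers) vectors[[f]] <- random_unit(d)
  emb <- embedding_table(do.call(rbind, vectors))

  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  n_total <- length(groups)
  ids <- sprintf("p%03d", seq_len(n_total))
  sw <- prsf_stopwords()

  transcripts <- vector("list", 2L * n_total)
  truth <- list()
  ti <- 0L
  for (i in seq_len(n_total)) {
    # participant-level ability jitter, shared across conditions
    ability <- stats::rnorm(1, 0, config$retention_sd)
    for (cond in CONDITIONS) {
      p_base <- config$retention[groups[i], cond]
      p_i <- stats::plogis(stats::qlogis(min(max(p_base, 1e-6), 1 - 1e-6)) +
                             ability)
      if (p_base == 0) p_i <- 0
      if (p_base == 1) p_i <- 1
      verbs <- inv[[cond]]$verbs
      retained <- stats::runif(length(verbs)) < p_i
      surface <- character(0)
      paraphrased <- logical(length(verbs))
      for (j in which(retained)) {
        if (stats::runif(1) < config$paraphrase_rate) {
          surface <- c(surface, sample(inv[[cond]]$synonyms[[verbs[j]]], 1))
          paraphrased[j] <- TRUE
        } else {
          surface <- c(surface, verbs[j])
        }
      }
      nouns <- inv[[cond]]$nouns[stats::runif(config$n_nouns) <
                                  config$noun_rate]
      n_fill <- stats::rpois(1, config$distractor_rate)
      fill <- if (n_fill > 0) sample(fillers, n_fill, replace = TRUE)
              else character(0)
      content <- sample(c(surface, nouns, fill))
      if (length(content) == 0) content <- sample(fillers, 1)
      # interleave stopwords and punctuation into a plausible surface form
      toks <- character(0)
      for (t in content) {
        if (stats::runif(1) < 0.35) toks <- c(toks, sample(sw, 1))
        toks <- c(toks, t)
      }
      sent_len <- 8L
      n_sent <- ceiling(length(toks) / sent_len)
      pieces <- character(n_sent)
      for (s in seq_len(n_sent)) {
        chunk <- toks[((s - 1) * sent_len + 1):min(s * sent_len,
                                                   length(toks))]
        chunk[1] <- paste0(toupper(substr(chunk[1], 1, 1)),
                           substr(chunk[1], 2, nchar(chunk[1])))
        pieces[s] <- paste0(paste(chunk, collapse = " "), ".")
      }
      ti <- ti + 1L
      transcripts[[ti]] <- data.frame(
        participant_id = ids[i], condition = cond,
        raw_text = paste(pieces, collapse = " "), stringsAsFactors = FALSE)
      truth[[paste(ids[i], cond, sep = "_")]] <- list(
        retention_prob = p_i, retained = stats::setNames(retained, verbs),
        paraphrased = stats::setNames(paraphrased, verbs))
    }
  }
  transcripts <- do.call(rbind, transcripts)

  cm <- config$covariate_model
  draw_cov <- function(spec_g) {
    if (is.null(spec_g)) return(NA_real_)
    round(stats::rnorm(1, spec_g[1], spec_g[2]), 1)
  }
  metadata <- data.frame(
    participant_id = ids, group = groups,
    moca = NA_real_, ifs = NA_real_, updrs3 = NA_real_,
    sex = sample(c("F", "M"), n_total, replace = TRUE, prob = c(0.4, 0.6)),
    age = round(stats::rnorm(n_total, 62, 8)),
    education = pmax(0, round(stats::rnorm(n_total, 12, 4.6))),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n_total)) {
    metadata$moca[i] <- min(30, max(0, draw_cov(cm$moca[[groups[i]]])))
    metadata$ifs[i] <- min(30, max(0, draw_cov(cm$ifs[[groups[i]]])))
    u <- draw_cov(cm$updrs3[[groups[i]]])
    metadata$updrs3[i] <- if (is.na(u)) NA_real_ else max(0, u)
  }
  if (config$confound_covariates) {
    at_rate <- vapply(ids, function(id)
      mean(truth[[paste(id, "AT", sep = "_")]]$retained), numeric(1))
    metadata$moca <- pmin(30, pmax(0, round(
      metadata$moca + 6 * (at_rate - mean(at_rate)), 1)))
  }

  structure(list(
    transcripts = transcripts, metadata = metadata, truth = truth,
    backend = backend_dictionary(
      verbs = unlist(lapply(inv, function(x) c(x$verbs,
                                               unlist(x$synonyms)))),
      stopwords = sw, name = "synthetic_dictionary"),
    embeddings = emb,
    reference_verbs = list(AT = inv$AT$verbs, nAT = inv$nAT$verbs),
    config = config
  ), class = "prsf_study")
}
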