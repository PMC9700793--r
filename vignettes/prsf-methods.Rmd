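---
title: "Scoring the semantic field of retold stories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the semantic field of retold stories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsf)
```

## The problem

When a person retells a story, the words they choose reveal which of the
story's concepts they encoded and can reactivate. In Parkinson's disease
(PD), concepts denoting bodily action (*run*, *jump*, *dance*) are of
particular interest: their processing recruits motor circuitry, so
action-semantic impoverishment in free speech is a candidate digital marker
of the disease and of its cognitive phenotypes (with and without mild
cognitive impairment, PD-MCI and PD-nMCI).

`prsf` implements a fully automated pipeline for this question. Participants
retell two matched reference stories — an action text (AT) rich in bodily
movement and a non-action text (nAT) centered on feelings, thoughts and
perceptions — and each retelling receives a
**proximity-to-reference-semantic-field (P-RSF)** score: how strongly the
retelling evokes the semantic field anchored on the reference story's verbs.
The package then supports the two evaluation arms such a marker needs:
covariate-adjusted group inference (ANCOVA with cognitive-screening scores as
covariates, partial eta squared as effect size) and participant-independent
nested cross-validated classification (Gaussian-kernel SVM with randomized
hyperparameter search).

## The P-RSF metric

For one text condition, let the retellings form a corpus of $m$ documents
over vocabulary of size $v$ (each condition has its own corpus and
vocabulary).

1. **Normalization.** Each transcript is lowercased; accents are stripped
   (Unicode NFD, combining marks removed; "ñ" is kept — it is a letter, not
   an accent); tokens containing digits, punctuation, and stopwords are
   deleted; survivors are lemmatized. Verbs are found by part-of-speech
   tagging on the *raw* token stream (taggers need case and context), then
   mapped into the same normalized lemma space.
2. **Latent semantic analysis.** The $m \times v$ bag-of-words count matrix
   $X$ is factorized by SVD, $X = U \Sigma V^\top$, with no centering and no
   tf-idf reweighting — the document representation is plain term frequency.
   Component $j$ explains $\sigma_j^2 / \sum_i \sigma_i^2$ of the variance,
   and the model keeps the smallest $k$ whose cumulative share reaches the
   variance threshold (default 0.95). Word vectors are rows of the
   dictionary matrix $V_k \Sigma_k$; document vectors are rows of the
   encoding matrix $U_k \Sigma_k$.
3. **Reference verbs.** The scored verb set is the intersection of the
   original story's verbs with the corpus vocabulary (in training-fold
   vocabulary terms when folds are used), in story order.
4. **Verb importance.** Each reference verb's weight $w_j$ is the mean
   cosine similarity between its vector and the vectors of *all* vocabulary
   words: the weight of the verb's semantic field within the field spanned
   by what participants actually said.
5. **Occurrence with similarity credit.** $O_{ij}$ starts as the exact count
   of reference verb $j$ in document $i$. Every retelling verb token that is
   not itself a reference verb is then credited to its nearest reference
   verb (by cosine similarity; ties go to the earliest verb in story order),
   adding $\max(0, \text{cos})$ to that column. Credit is per token, so
   repeated near-synonyms accumulate, mirroring frequency semantics.
6. **P-RSF.** $P = O \circ w$ (Hadamard product, each column scaled by
   $w_j$); a document's scalar score is the mean of its row. Lower scores
   mean weaker evocation of the reference field.

### Interpretive choices held fixed

Three places in this construction admit more than one defensible reading;
each is resolved once, exposed in configuration, and kept fixed:

- **Importance as mean cosine *similarity*.** Weighting by similarity (not
  distance) makes higher $w$ mean semantically closer, so that lower P-RSF
  consistently means less target-concept weight.
- **Fallback credit.** Crediting a non-reference verb with its cosine
  similarity to the *nearest* reference verb (clipped at zero) keeps $O$
  non-negative and monotone in semantic closeness. The unclipped variant and
  a no-credit variant are available as `credit_mode =
  "one_minus_distance_raw"` / `"none"` for sensitivity analysis.
- **Row mean, not row sum.** Averaging over the $n$ reference-verb columns
  keeps scores comparable when $n$ differs between training folds (folds
  attest different verb subsets).

Two numerical conventions matter for reproducibility. The SVD sign ambiguity
is fixed by making each component's largest-magnitude dictionary loading
positive (cosine geometry is unaffected). When the requested variance
threshold would require components beyond the numerical rank, the model
falls back to the numerical rank and says so.

## Fold-aware feature extraction

Classification features must not leak the held-out participants into the
fitted objects. `fit_transform_fold()` therefore refits *everything* —
vocabulary, SVD, reference-verb set, importance weights — on training
documents only, and scores held-out documents with the train-fitted objects;
held-out verbs outside the training vocabulary are out-of-vocabulary and
earn nothing. The SVM features are the per-verb P-RSF rows (not just the
scalar score). `nested_cv()` runs five outer folds stratified by label and
split by participant; within each outer training set, cost and kernel
bandwidth are tuned by randomized search (default 50 candidates, $C$
log-uniform on $[10^{-2}, 10^3]$, $\gamma$ log-uniform on
$[10^{-4}, 10^1]$) scored by mean accuracy over four stratified inner
folds. Held-out decision scores are pooled across outer folds into one ROC
and one rank-based (Mann–Whitney) AUC; the confusion matrix is aggregated
the same way. Candidate draws and fold splits are derived deterministically
from the plan seed, so a report is a pure function of data, labels, seeds
and configuration. No resampling or class weighting is applied to unbalanced
tandems; folds are stratified only.

## Statistical arm

Group comparisons are one-way ANCOVAs of mean P-RSF scores with MoCA and IFS
as covariates: the linear model `score ~ moca + ifs + group`, the group
effect tested by comparing against the model without `group` (with a single
factor plus covariates this is the Type II sum-of-squares test that common
statistical packages produce). The effect size is partial eta squared,
$SS_{group}/(SS_{group}+SS_{resid})$, which for a single-df effect equals
$F \cdot df_1 / (F \cdot df_1 + df_2)$ — the package verifies this identity
on every result it produces. Story-construction tallies are compared with an
equal-expectation goodness-of-fit chi-square on the two counts. Exploratory
correlations against motor severity (UPDRS-III) use Pearson's method when
both variables pass Shapiro–Wilk normality at $\alpha = 0.05$, Spearman's
otherwise, and record which was used.

Constant covariates are dropped (the ANCOVA degrades gracefully to an
ANOVA); genuinely collinear designs are an error naming the offending
columns rather than a silent alias.

## The synthetic-study generator

No clinical data ships with the package; `generate_study()` produces
complete studies in exactly the corpus layout the readers expect. What it
emulates:

- two reference stories with disjoint verb inventories (27 action verbs, 23
  non-action verbs — the attested inventory sizes of the target design),
  each verb carrying a latent unit vector;
- per participant and condition, each reference verb is reproduced with
  probability set by group and condition. `default_pd_scenario()` encodes
  the designed dissociation: HC retain 0.8/0.8 (AT/nAT), PD-nMCI 0.5/0.8
  (selective action loss), PD-MCI 0.5/0.55 (loss in both);
- a retained verb is paraphrased into a near-synonym (latent cosine within
  [0.75, 0.95] of its source) with probability 0.2; theme nouns appear with
  probability 0.6 each; Poisson(12) off-field fillers and interleaved
  stopwords complete the surface text, with sentence casing and punctuation
  so the normalizer has real work to do;
- retention is jittered per participant on the logit scale (SD 0.6). This
  between-subject heterogeneity is calibrated so the latent separability of
  HC vs PD-nMCI on the action text sits near an AUC of 0.9 — the
  discriminability regime the emulated design targets — rather than the
  near-perfect separation unjittered Bernoulli draws would give;
- covariates from group-dependent normals (MoCA means ordered HC 26.7 >
  PD-nMCI 26.3 > PD-MCI 21.5; IFS similarly ordered; UPDRS-III for patients
  only), independent of retention by default. A `confound_covariates` switch
  ties MoCA to realized retention for stress-testing covariate adjustment.

The synthetic language is tokens with assigned latent vectors, not natural
Spanish: the matching dictionary backend gives exact lemmas and verb tags,
so no external NLP model is a test dependency and every pipeline stage can
be validated against closed-form oracles. What passing tests on this
generator do **not** show: robustness to tagger and lemmatizer errors,
morphological variation, disfluencies, or topic drift in real retellings —
on real Spanish transcripts those enter through the injected backend, and
the bundled suffix-heuristic Spanish backend is a coarse fallback meant for
exploration, not validation.

## Problem sizes used in validation

The test suite validates the pipeline against brute-force oracles on random
tiny corpora (up to 6 documents over up to 12-word vocabularies, where full
decompositions and explicit loops are exact), checks topic-count selection
on 100 random matrices across four thresholds, and exercises the full
synthetic scenario at 40 + 40 participants: 20 replicates for the
effect-recovery checks and 10 replicates of a null scenario, with nested-CV
search budgets of 30 candidates; ANCOVA calibration uses 1000 simulated null
datasets of n = 80. These sizes were chosen as the smallest at which the
checked properties are stable across seeds.

## Known limitations

- LSA vectors from small corpora are noisy; with very few documents the
  topic space can collapse to one component, making similarity credit
  coarse. The numerical-rank fallback logs when this happens.
- The fallback-credit arithmetic is an interpretive decision (see above);
  results can be checked under `credit_mode` variants.
- The heuristic Spanish backend over-tags nouns ending in verb-like
  suffixes; for real studies, inject a trained tagger/lemmatizer as a
  backend.
- Classification tandems with very small patient subgroups (e.g. 16) give
  high-variance fold metrics; the reported pooled ROC is the stable summary.
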