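---
title: "Predicting disease-related metabolites with similarity-completed latent factor models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting disease-related metabolites with similarity-completed latent factor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmlfm)
```

## The problem

Metabolite profiles link genotypes to disease phenotypes, but experimentally
confirmed disease–metabolite associations are sparse: a curated corpus of a
few hundred diseases and metabolites typically covers well under 1% of all
possible pairs. `dmlfm` treats candidate-metabolite prioritization as a
bipartite link-prediction problem in the collaborative-filtering style: the
known associations form a 0–1 matrix, side information (disease similarity
and literature-based metabolite similarity) densifies it, and a low-rank
factorization generalizes from the densified matrix to score every
unobserved pair.

The package covers the full path from raw inputs to ranked candidates:

1. **Vocabulary** — free-text disease names from metabolite records are
   mapped to ontology accessions via an expanded synonym vocabulary.
2. **Completion** — the 0–1 matrix's unknown cells are filled from two
   similarity channels and combined as a noisy-OR.
3. **Factorization** — the completed matrix is approximated by the product
   of two latent factor matrices trained with stochastic gradient descent.
4. **Validation** — data-increment test sets (diffing two release versions
   of the association source), leave-one-out cross-validation, per-disease
   AUC, and an ablation harness.

## Disease name normalization

Names for the same disease differ across sources in five recurring ways:
singular/plural/possessive forms, semantically irrelevant symbols,
abbreviations, word order ("Diabetes Mellitus, Type 1" vs. "type 1 diabetes
mellitus"), and plain synonymy. The vocabulary builder

* takes every ontology term name and synonym,
* attaches MEDIC-style names and synonyms to ontology terms through their
  MeSH/OMIM cross-references, and
* stores every surface form under a deterministic normalization:
  lowercasing, possessive stripping, symbol-to-space collapse, a
  first-comma two-segment inversion, and inventory-guarded
  depluralization.

Design choices where the sources are silent:

* **Collisions** (two accessions claiming one normalized surface) are
  resolved by source priority — ontology name > ontology synonym >
  MEDIC-via-xref — with ties to the lexicographically smaller accession;
  every collision is logged in the returned object, never silently dropped.
* **Depluralization** strips a trailing "s" from a token only when the
  stripped token occurs elsewhere in the vocabulary's token inventory.
  This keeps "diabetes" intact while mapping "neoplasms" to "neoplasm".
* **Abbreviations** are matched only when a source lists them as explicit
  synonyms; generating acronyms algorithmically would create massive
  collisions.
* **Comma inversion** applies to the first comma only and produces a single
  reordered candidate; full rotations of three-segment names are not
  generated because multi-segment inversions are not observed in the
  sources this models.

No fuzzy matching is performed: a name either normalizes onto a stored
surface form or is reported unmatched.

## Matrix completion

With `A[m, d] = 1` for known pairs, two fill channels are computed:

* **Disease channel**: `DF[m, d]` is 1 where the pair is known, otherwise
  the *maximum* similarity between `d` and any disease already known for
  `m` (0 if `m` has no known disease). Disease similarity is an external
  input — typically a gene-functional-network semantic similarity — read
  as a labeled matrix; it is not computed here.
* **Metabolite channel**: symmetric, using literature co-occurrence
  similarity between metabolites.

The channels are treated as independent evidence and combined per cell as a
noisy-OR, `mdr = 1 − (1 − DF)(1 − MF)`, which is bounded below by
`max(DF, MF)` and above by `DF + MF`, and equals 1 exactly when either
channel is 1 — so known cells are fixed points of the completion.

Metabolite similarity is a min–max standardization of raw literature
co-occurrence scores. Two directions are provided because the published
form of this standardization, `(ST_max − ST)/(ST_max − ST_min)`, assigns
similarity 1 to the *lowest* score, while text-mining scores grow with
association strength. The package defaults to the `ascending` direction
(`(ST − ST_min)/(ST_max − ST_min)`), which matches the semantics of the
scores; `as_printed` reproduces the inverted form literally. Both are
exposed, and the choice is recorded in every pipeline run log. No score
threshold is applied before the channel maxima; pairs absent from the score
table get similarity 0.

A metabolite or disease with no known partner leaves the corresponding max
over an empty set, which is defined as 0: the cell simply stays
unpredicted. The coverage rate reports the percentage of initially-unknown
cells that received a nonzero fill; when there are no unknown cells the
rate is reported as 100% with a `degenerate` flag rather than dividing by
zero.

## The latent factor model

The completed matrix `MDR` (|M| × |D|) is approximated as
`MDR* = MLF %*% t(DLF)` with `DLF` (|D| × F) and `MLF` (|M| × F). The cost
is the sum of squared residuals over **all** cells plus an L2 penalty,
`λ/2 (‖DLF‖² + ‖MLF‖²)`, accumulated once per row. Training is plain
stochastic gradient descent: each epoch visits every cell in a freshly
shuffled (seeded) order and updates the two touched rows with

```
row += α (2 · err · other_row − λ · row)
```

i.e. a step *against* the per-cell gradient
`−2 · err · other_row + λ · row`. The update direction is a deliberate
design decision: a recursion that *adds* the gradient ascends the cost, so
the package implements standard descent, which is what minimizing the cost
requires. The per-cell update applies λ at every visit (the stochastic
convention), while the reported cost applies λ/2 once per row; both
conventions are stated here because they differ by a factor of the number
of cells sharing a row, and the tests pin each one separately against
brute-force and finite-difference oracles.

Choices the model leaves open, fixed as package defaults:

* `n_factors = 20`, `reg_lambda = 0.01`, `learning_rate = 0.01`,
  `max_epochs = 200`, `tol = 1e-5`, `init_scale = 0.1`. These give stable,
  monotone convergence on the synthetic fixtures; all are overridable.
* Initialization is uniform on `(0, init_scale/√F)` under the config seed,
  so runs are bit-reproducible.
* Convergence is declared when the relative cost change between epochs
  drops below `tol` (denominator guarded by `1e-12`).
* The sum in the cost runs over all cells — zeros of the completed matrix
  are genuine training targets, since the completion already encoded the
  available evidence. A `nonzero_only` switch restricts SGD to nonzero
  cells for ablation.
* Divergence (non-finite cost or factors) raises an error suggesting a
  smaller learning rate rather than returning garbage. Note that with
  per-cell L2 applied at every visit, `α · λ > 2` is structurally divergent.

Final predictions overlay the reconstruction with the initial matrix:
known cells are forced to exactly 1; optionally the rest are clamped to
`[0, 1]` (clamping cannot reorder unclamped cells). A truncated-SVD
backend provides the dimensionality-reduction baseline at rank
`n_factors`, with the same overlay; the unregularized variant is simply
`reg_lambda = 0`, and the tests assert it is bit-identical to a zero-λ
configuration rather than a separate code path.

The SGD inner loop is implemented in C++ (via Rcpp) because it touches
|M|·|D| cells per epoch one at a time; epoch order, shuffling, cost
evaluation and convergence logic stay in R.

## Validation schemes

**Data-increment test sets.** Given two versions of the association map
(older `v1`, newer `v2`), a disease qualifies when at least one metabolite
in both metabolite universes is associated with it in *both* versions; its
positives are metabolites in the intersection associated in `v2` but not
`v1`, and its negatives are all `v1` metabolites never associated with it
in either version. Two readings left open by the scheme's quantifier
structure are resolved as follows: previously-known pairs re-appearing in
`v2` are treated as training knowledge (the qualifying condition), not as
test positives — scoring training pairs would inflate AUC; and the negative
set follows the standard link-prediction convention, since the scheme
defines only the positives. Diseases with zero positives are dropped, and
per-disease positive counts are always reported next to the AUC because
single-positive test sets dominate in sparse corpora.

**AUC** is the normalized Mann–Whitney U — the probability that a random
positive outranks a random negative, ties credited one half — computed from
ranks, and cross-checked in the tests against exhaustive pairwise counting
and against `wilcox.test`. The summary is the unweighted mean over
diseases.

**LOOCV** removes each known pair in turn and rebuilds the *entire*
pipeline — completion and factorization — on the remaining pairs, because
the removed pair changes the known-disease and known-metabolite sets the
fills maximize over. The held-out metabolite is scored against all
metabolites never associated with that disease. Note that LOOCV is only
meaningful when entities retain other associations after the removal: on
extremely sparse subsamples a held-out pair can leave its disease with no
known metabolite at all, which systematically depresses the fold AUC.

**Ablations** re-run the fit with the completion restricted to one channel
(`disease_only`, `metabolite_only`), disabled (`init`), or with the
factorization swapped (`svd`, `lfm_nr`), all under one seed so the
comparisons are paired.

## The synthetic data generator

Every external input is emulated so the whole pipeline is testable without
downloads. One latent structure generates everything: non-negative factor
matrices of a configurable rank give association probabilities (inner
products scaled to `[0, 1]`), and the similarity matrices are the cosine
similarities of the *same* factor rows, perturbed by symmetric uniform
noise and clipped. This encodes, in a controllable form, the modelling
assumption that metabolites with literature links tend to share diseases —
the very signal the completion step exploits.

Observations are sampled without replacement from the top-quartile
probability cells (giving reproducible pair counts, unlike Bernoulli
sampling): version 2 at `observation_density + version2_extra_density`,
version 1 as a subsample of version 2 at `observation_density`, so
version 1 ⊂ version 2 by construction. Defaults — 40 diseases, 60
metabolites, rank 3, densities 0.05 + 0.03, similarity noise 0.05 — give a
corpus sparsity (~5%) and increment size in the regime the method targets,
while staying small enough that the full suite of property tests runs in
seconds; the tests and the acceptance script use these defaults, with the
ordering and recovery properties checked across 10–20 seeds.

The toy vocabulary written by `write_fixture()` covers all synthetic
diseases (canonical name, word-order MEDIC variant, abbreviation synonym)
plus one instance of each of the five naming cases, and the metabolite XML
encodes the version-2 pairs through rotating surface variants — so the
fixture exercises the vocabulary logic end to end, and
`build_associations()` on the fixture must recover the version-2 pair set
exactly.

What the generator does *not* emulate: realistic disease-name frequency
distributions, the heavy-tailed score distribution of text-mining corpora,
hub structure in the bipartite graph, or version drift in identifiers.
Passing tests on synthetic data therefore demonstrate correctness of the
algorithms and the claimed orderings under the model's own assumptions,
not performance on any real corpus.

## A worked example

```{r example}
ds <- generate_synthetic(synthetic_config(seed = 7))
fit <- dmlfm(ds$version1$pair_df, ds$disease_similarity,
             ds$metabolite_similarity,
             metabolite_labels = ds$metabolite_ids,
             disease_labels = ds$disease_ids,
             config = lfm_config(n_factors = 10, max_epochs = 150, seed = 7))
summary(fit)

ts <- extract_incremental_test_sets(ds$version1, ds$version2)
evaluate_predictions(fit$predictions, ts)

head(predict(fit, diseases = ds$disease_ids[1], ranked = TRUE), 3)
```

## Numerical and degenerate-input conventions

* Serialized matrices always carry explicit row (metabolite) and column
  (disease) labels; numerics are written with 6 decimals, so round-trips
  are exact to `1e-6` and reruns under one seed are byte-identical.
* Ranking ties are broken by metabolite accession so output is stable.
* Score normalization refuses a degenerate range (`ST_max = ST_min`) and
  negative raw scores.
* Similarity matrices must be symmetric within `1e-8` and inside `[0, 1]`;
  entities absent from a similarity input are treated as all-zero rows
  with self-similarity 1.
* An all-known association matrix reports 100% coverage with a flag; an
  empty positive or negative score list is an error at the AUC level
  because such diseases should have been dropped during extraction.

## Known limitations

* Published corpus-scale results depend on specific, version-drifted
  releases of the external databases and cannot be reproduced from code
  alone; the package therefore validates arithmetic identities, oracle
  equivalence, algebraic invariants and synthetic-data orderings instead.
* The factorization has no bias terms and no implicit-feedback weighting;
  hyperparameters are fixed defaults, not searched.
* Vocabulary matching is exact after normalization — no edit-distance
  rescue for typos.
* LOOCV retrains the full pipeline per fold and is quadratic-ish in the
  number of known pairs; it is intended for corpora of hundreds, not
  millions, of pairs.
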