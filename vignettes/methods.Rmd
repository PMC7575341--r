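---
title: "Methods: language surveillance of online support groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: language surveillance of online support groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mindlang` quantifies how language changes across labeled online
communities around a disruptive event. This vignette is the package's own
account of its models, the choices behind them, and what its tests do and
do not establish.

## The data model

The unit of analysis is a *post*: an id, an author id, a group label (the
forum a post was made in), a calendar date, and free text. A corpus
carries a group registry and three named, non-overlapping periods:
`baseline_year` (the same calendar window one year before the analysis
window), `pre_event`, and `mid_event` (the analysis window split at the
event onset). The interchange format is JSON lines with a sidecar period
file; `load_corpus()` counts malformed lines and refuses files with more
than 1% of them.

One deliberate constraint appears throughout: analyses that could leak
information across units deduplicate to one post per author before
sampling, and TF-IDF vocabularies are fitted on the pre-event period only
and then applied unchanged to later periods, so that data-set-shift and
convergence measurements are not contaminated by mid-event vocabulary.

## Feature families

The fixed feature vector has 90 dimensions in six families
(62 + 4 + 8 + 1 + 9 + 6):

* **Category lexicons (62).** An open category-lexicon engine: entries are
  literal tokens, terminal-`*` stem wildcards, or `_`-joined phrases;
  phrases are matched greedily left-to-right with each consumed token
  counted once, and the feature is the matched proportion of tokens. The
  shipped 62 category word lists (affective, social, cognitive,
  perceptual, biological, and topical categories such as work, money,
  home, religion, death, sleep, school) are editable TSV data; the engine,
  not any particular word list, is the contract. Proprietary dictionaries
  in this family are deliberately not reproduced; the bundled lists are
  small and documented, which means absolute category scores are not
  comparable to scores from proprietary tools — only the pipeline's
  behavior on top of them is.
* **Sentiment (4).** Negative/neutral/positive proportions and a compound
  score from a bundled valence table: each positive-valence token
  contributes its valence + 1 to the positive mass, negative tokens
  |valence| + 1 to the negative mass, unmatched tokens 1 to the neutral
  mass; the three proportions sum to 1. The compound score is the raw
  valence sum S mapped through S/&radic;(S&sup2;+15), the standard
  saturating normalization, so concatenating a text with itself never
  changes the sign.
* **Surface counts (8) and punctuation (1).** Token, character, sentence,
  syllable, complex-word (&ge; 3 syllables) and type/token statistics, and
  the punctuation-per-token rate. Syllables come from a vowel-group
  heuristic (final silent `e` subtracted, minimum 1) with a small
  exceptions table — deterministic and dependency-free.
* **Readability (9).** Flesch reading ease, Flesch–Kincaid grade, Gunning
  fog, SMOG, ARI, Coleman–Liau, LIX, RIX, FORCAST, each computed by its
  published closed form from this package's own token/syllable/sentence
  counts (the tests pin them to hand-computed values on fixture
  sentences).
* **Custom lexicons (6).** Suicidality, economic stress, isolation,
  substance use, domestic stress, guns — the topical lists a surveillance
  analysis of this kind tracks; bundled as editable files.

TF-IDF n-grams extend the vector: tokens are stemmed with a hand-written
Porter-style suffix stripper (so *purging*/*purged* → `purg`), n-grams
(default 1–2) are ranked by document frequency with lexicographic
tie-breaks, the top V form the vocabulary (V is clamped to [256, 1024],
the working range for this kind of corpus; toy runs can unlock it), idf is
the smooth log((1+N)/(1+df)) + 1, and document vectors are L2-normalized.
No stop-word list is applied: at these vocabulary sizes the df ranking
itself decides, which keeps the transform free of a second word-list
dependency.

## Synthetic corpora as the validation instrument

Real forum data cannot ship with a package, and no fixed corpus could
carry ground truth anyway. The generator therefore *is* the validation
instrument: it emits corpora whose every planted parameter is recorded.

Token emission is i.i.d. within a post given (group, theme, date) — the
simplest model consistent with the bag-of-words assumptions every
downstream stage makes. Each token comes from a categorical mixture over:
a shared vocabulary (Zipf–Mandelbrot weights, 1/(r + 2.7)^1.05, which puts
the head word near 5% of tokens as in natural text; the vocabulary mixes
generic filler with bundled-lexicon words so lexicon features have
realistic nonzero noise), the group's marker vocabulary (rate 0.05), the
post's latent theme vocabulary, any drifting lexicon (base rate plus a
linear slope per day over the analysis year), and after onset the event
vocabulary, whose rate follows a logistic ramp (per-group ceiling and
onset, so a reference group can emit event language from the start).
Sentence terminators are inserted every 12 tokens so readability formulas
are well defined; post lengths are negative binomial (mean 120); authors
post a geometric number of times (mean 1.6) to exercise one-post-per-user
deduplication. Defaults — 16 groups × 400 posts per period — are the
package's standard study conditions; the tests use documented smaller
slices of the same model (typically 4–10 groups × 50–200 posts per
period) so the whole suite runs on a desk machine.

What the generator does **not** emulate: grammar, discourse structure,
author-level style, topic correlation across posts by the same author, and
bursty news cycles. Recovery tests therefore show that the pipeline's
statistics do what they claim under the model the stages assume — they do
not certify performance on real forum text.

## Trend analysis

Per (group, feature), posts are averaged in 2-day bins over the analysis
window; empty bins are dropped and series with fewer than 3 bins are
excluded. OLS of bin mean on bin index gives slope, R², and a two-sided
slope t-test p-value; zero-variance series get slope 0, p 1, and a
degenerate flag. The trend score is `change = slope × R²` — by
construction |change| ≤ |slope|, with equality only for perfect fits. BH
correction is applied jointly over the whole group × feature family (the
per-group alternative is a config switch); bins are unweighted by default
(a post-count-weighted option exists). Regressing on bin index rather than
calendar day tolerates sparse groups; slopes are per bin, so per-day
rates divide by the bin width.

The negative-semantic-change score for a group sums significant changes
over 13 negatively valenced features (negative sentiment, the six custom
lexicons, and the anger, anxiety, death, negations, negative-emotion and
sadness categories) minus the changes of 3 positive features (compound
sentiment, positive sentiment, positive emotion). Year-over-year change is
compared by Mann–Whitney U on |change| collections, pooling all pairs by
default (significant-only pooling is an option).

Event posting is tracked two ways: the proportion of posts containing at
least one event token (the headline display measure) and the mean
per-post event-token share, which does not saturate once event language
becomes ubiquitous and is therefore the series used for correlation
analyses.

## Statistical primitives

The rank and enrichment tests are implemented in the package and verified
against exhaustive enumeration: Mann–Whitney U uses midranks with exact
two-sided p by enumeration of all labelings up to combined n = 12, then a
tie-corrected normal approximation with continuity correction; the
signed-rank test drops zeros (standard practice), enumerates all sign
patterns up to n = 15; Spearman's ρ is the Pearson correlation of
midranks with an exact permutation p up to n = 8 and the t approximation
above; the hypergeometric upper tail is an exact log-space sum; BH is the
standard step-up with monotone q-values and Bonferroni clamps at 1.
Degenerate inputs (all-tied samples, zero variance) are flagged, never
returned as NaN. The exact/approximate thresholds sit near the pipeline's
typical group counts, so both code paths are exercised in normal use.

## Classification

A binary task takes the target group's author-deduplicated posts against a
control pool in which the remaining groups are first equalized and then
sampled, n per class (2700 by default, shrunk with a warning), with an
80-20 split and two extra test regimes: a later-period shift set
(excluding training authors) and transfer sets scored via
`apply_classifiers_to_group()`. Features are standardized on training data
only. Model kinds: L1-regularized logistic regression (default, for sparse
signed coefficients), elastic-net, linear SVM, extremely randomized trees,
and gradient boosting; the linear kinds expose one signed coefficient per
feature and the importance tables rank by |coefficient| within sign, ties
by name. Regularization strength and iteration settings are fixed,
recorded defaults — the aim is interpretable comparison, not tuned peak
accuracy. Broad catch-all groups can be excluded from the control pool via
a config argument.

## Spectral clustering

The pipeline is pinned down so results are reproducible: balanced sample
(1500 per group by default, shrunk uniformly if needed) → standardize
(dropping constant columns) → 30 principal components → symmetric
union-kNN connectivity affinity (k = 10) → normalized Laplacian
L = I − D^(−1/2) A D^(−1/2) → the k = 20 smallest eigenvectors → k-means
with a fixed seed and 10 restarts. Disconnected affinity graphs are
bridged through their nearest cross-component pair with a warning.
Characteristic features use the same tie-corrected rank-sum statistic as
the stats module (vectorized over clusters; the tests pin the equality on
a toy), Bonferroni-corrected over clusters × features and ranked by
rank-biserial effect size. Enrichment is the upper-tail hypergeometric
test with population = the clustered sample. Cross-period matching is
greedy one-to-one on the Jaccard similarity of top-25
characteristic-feature name sets with threshold τ = 0.2 — a deliberate
formalization of "closest match" with all three knobs configurable;
matched pairs report mid/pre size ratios, and unmatched mid clusters are
flagged emergent. Cluster naming remains a human step: the model stores
free-text annotations and offers top characteristic features as
candidates. k is a parameter, not automatically selected.

## Topic modeling

LDA is estimated by a collapsed Gibbs sampler written for this package
(compiled, own mt19937 stream, hence bit-reproducible for a given seed;
any Dirichlet-prior estimator meeting the determinism and recovery
properties would satisfy the same contract). Defaults: K = 10, α = 0.1,
β = 0.01, 300 sweeps with 150 burn-in, posterior means accumulated after
burn-in. Documents live on the TF-IDF module's stemmed n-gram vocabulary;
the default input weighting is integer counts — applying LDA to TF-IDF
weights is statistically nonstandard, so the `tfidf` mode (scaled, rounded
weights) exists for comparability but is not the default. Inference for
new posts is a deterministic fixed-point fold-in with the topic-term table
held fixed; posts with no in-vocabulary tokens are flagged NA. Per-group
prevalence is the mean of per-post topic distributions (the
hard-assignment share is the recorded alternative), and pre-vs-mid shifts
are tested per topic by two-sided signed-rank across groups with BH over
topics. Note the test's resolution: with G groups the smallest two-sided
exact p is 2/2^G, so single-topic shifts need roughly G ≥ 8 paired groups
to survive BH at K = 10. Stability across seeds is reported as the mean
greedy best-match cosine between topic-term rows.

## Convergence

For each 15-day window and each of 50 bootstrap subsamples (without
replacement, balanced per group), the window's posts are embedded to 2D
and the directed Hausdorff distance h(A→B) = max over a∈A of the distance
to the closest b∈B is taken from every group cloud to each reference
cloud; the per-window statistic is the bootstrap median.

The embedding is a supervised neighbor-graph projection in the Isomap
family: metric distances (euclidean or cosine), between-class distances
inflated by a supervision factor, union-kNN graph with edge lengths
floored at `min_dist`, geodesic distances by graph shortest paths, and
classical MDS to 2D with a deterministic sign convention. This satisfies
the "labeled neighbor-graph nonlinear 2D projection" contract while being
exactly reproducible; hyperparameters are chosen by silhouette score over
a grid (`select_embedding_params()`), and the recorded large-corpus
defaults are n_neighbors = 200, min_dist = 0, cosine.

Two choices deserve emphasis. First, each window is embedded
independently, and nonlinear embeddings have arbitrary per-window scale,
so every window's directed-distance matrix is normalized by its median
off-diagonal entry before cross-window comparison — trajectories are
scale-free ratios, not absolute distances. Second, the asymmetric
direction is h(group → reference); the opposite direction is computable
from the same matrices. The baseline band is the empirical 5th–95th
percentile of the same statistic on the stationary baseline year (widened
to min/max with a warning when fewer than 5 baseline windows exist) —
with an ~8–16-window baseline this band carries real estimation error on
top of its nominal 10% exceedance, which the null tests acknowledge by
asserting a 30% ceiling rather than 10%. For the band to be meaningful at
all, the baseline and analysis runs must use the same per-window cloud
size, because the Hausdorff statistic's law depends on it. Per-reference
trajectories (across-group median per window) are correlated with the
event-token share series by Spearman's ρ with BH over references;
constant trajectories are excluded from the family as degenerate.

## Pipeline and reproducibility

`run_full()` executes simulate → features → trends / classify / cluster /
topics / converge from one validated config, writing CSVs and a manifest.
One global seed is fanned out to per-stage child seeds through a stable
string hash, so disabling one stage never shifts another stage's random
stream — the determinism tests assert byte-identical CSVs across repeated
runs and across stage-toggled runs. The CLI (`inst/cli/mindlang.R`) is a
thin wrapper over the same functions.

## Problem sizes used by the test suite

Generation and feature extraction dominate runtime, so the suite
standardizes on: 6 groups × 150 posts per period for the marker and drift
corpora; 6 groups × 250 for the planted-convergence corpus (denser
windows, because the directed Hausdorff statistic is an extreme-value
statistic whose noise shrinks with cloud size); 10 groups × 100 for the
theme corpus (ten groups because of the signed-rank resolution noted
above); 4 groups × 200 for the stationary null; 20 independent 3-group
corpora for the null trend-calibration sweep; 1000-case enumeration
sweeps for the statistics and Hausdorff; and bootstrap counts of 8–14 in
tests versus the default 50 in the acceptance script's convergence run.
In the planted-convergence scenario the reference group emits the event
vocabulary from the start and the other groups follow a shallow logistic
ramp spanning the whole analysis window (token-share ceiling 0.35,
steepness 0.03/day, onset March 1), an acute-takeover regime in which the
planted signal clearly exceeds the Hausdorff noise floor; the convergence
embedding uses a dense neighbor graph (n_neighbors 120 on ~300-point
windows) with supervision weight 3 after the same standardize-then-30-PC
reduction the clustering stage uses. These sizes are the package's
validation conditions; all recovery margins quoted in the tests (≤ 30%
drift slope error, F1 ≥ 0.9, ARI ≥ 0.8, cosine ≥ 0.9, ρ ≤ −0.8) are met
with room at these scales.

## Known limitations

* Lexicon word lists are compact and editable, not normed instruments;
  absolute category scores should not be compared across dictionaries.
* The generator's i.i.d. token model understates real-text burstiness, so
  null calibrations here are a necessary, not sufficient, check for real
  corpora.
* Directed Hausdorff is an extreme-value statistic; with small per-window
  clouds its bootstrap median remains noisy, which is why trajectories are
  medians of 50 bootstraps at production scale.
* The matching rule for clusters (top-m Jaccard, greedy, τ = 0.2) is a
  formalization choice; alternative assignments (e.g. Hungarian) could
  differ for near-tied pairs.
* p-value approximations switch to normal/t forms beyond the exact-regime
  thresholds; at those sizes the approximations, not enumeration, define
  the reported values.
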