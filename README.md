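# mindlang

Language surveillance for online mental-health support communities.

Online support forums leave a continuous written record of how people with
different mental-health concerns talk about their lives. When a disruptive
event hits — a pandemic, an economic shock — that record shifts: new
vocabulary floods in, negative-affect language rises in some communities
more than others, discussion themes change prevalence, and previously
distinct communities can start to sound alike. `mindlang` implements a
complete, tested pipeline for quantifying those shifts from timestamped,
group-labeled post corpora, aimed at computational researchers in
infodemiology and digital mental health.

## What the package computes

Every post is mapped to a **90-dimensional psycholinguistic feature
vector** — 62 open category lexicons (affect, social, biological,
cognitive, time/work/money/religion categories and so on), 4 sentiment
outputs from a valence lexicon with the saturating compound score
S/&radic;(S&sup2;+15), 8 word/syllable surface counts, 1 punctuation rate,
9 readability formulas (Gunning fog, Flesch–Kincaid, SMOG, ARI, …), and 6
topical custom lexicons (suicidality, economic stress, isolation, substance
use, domestic stress, guns) — plus `V` TF-IDF-weighted stemmed n-grams
fitted on a reference period (90 + 256 = 346 dimensions in the smallest
configuration). On top of that feature matrix:

- **Trend analysis** — per (group, feature): posts are averaged in 2-day
  bins, OLS of bin mean on bin index gives a slope and R², and the trend is
  scored with `change = slope × R²` (the rate of change weighed by goodness
  of fit), with Benjamini–Hochberg control (α = 0.05) over the full
  group × feature family. A valence-weighted sum of significant changes
  (13 negative features, 3 positive features inversely weighed) ranks
  groups by *negative semantic change*; a Mann–Whitney U test compares
  |change| between years; event-vocabulary posting is tracked per bin and
  correlated (Spearman) with an external case-count series.
- **Classification** — each group versus a balanced multi-group control
  (n per class, one post per author, 80-20 split), default model an
  L1-regularized linear classifier, evaluated by weighted F1 on held-out,
  later-period (data-set shift) and transfer sets, with ranked signed
  coefficients for interpretation.
- **Clustering** — balanced samples are standardized, projected to 30
  principal components, connected by a symmetric 10-nearest-neighbor
  affinity, and cut into k = 20 clusters via the normalized graph Laplacian
  plus seeded k-means. Cluster-characteristic features come from rank-sum
  tests (Bonferroni), cluster–group associations from upper-tail
  hypergeometric enrichment (Bonferroni), cross-period cluster identity
  from greedy Jaccard matching of characteristic-feature sets (with
  mid/pre size ratios), plus Shannon composition diversity and
  homogeneity/completeness/V-measure/adjusted-Rand agreement scores.
- **Topic modeling** — latent Dirichlet allocation (collapsed Gibbs,
  compiled, seed-deterministic) with K = 10 topics on balanced samples;
  per-post topic distributions for any period are inferred under the
  pre-event model, and per-topic prevalence shifts across groups are tested
  with two-sided Wilcoxon signed-rank + Benjamini–Hochberg.
- **Convergence** — per 15-day window and bootstrap subsample, posts are
  projected to 2D with a supervised neighbor-graph embedding and the
  directed Hausdorff distance h(A→B) = max_a min_b ‖a−b‖ from each group's
  cloud to a reference group's cloud is recorded (median of 50 bootstraps,
  normalized per window). A stationary baseline year supplies a 5th–95th
  percentile null band, and each reference's distance trajectory is
  correlated (Spearman, BH) with event-vocabulary posting.

A first-class **synthetic corpus generator** produces reproducible
multi-group corpora with known ground truth — group marker vocabularies,
geometric author multiplicity, negative-binomial post lengths, linear
lexicon-prevalence drifts, latent themes with period-specific prevalences,
and a logistic event-vocabulary ramp — so that every stage is validated by
parameter recovery, not by eyeballing.

## Worked example

```r
library(mindlang)

cfg <- synthetic_config(
  n_groups = 6, posts_per_group_per_period = 150,
  drift_specs = data.frame(group = "grp01", lexicon = "isolation",
                           base_rate = 0.02, slope = 5e-4),
  event_spec = list(onset = as.Date("2020-03-01"),
                    steepness = 0.1, ceiling = 0.12),
  seed = 42)
sim <- generate_corpus(cfg)
ana <- corpus_subset(sim$corpus, period = c("pre_event", "mid_event"))
feats <- extract_features(ana, feature_spec(tfidf_v = 0))
trends <- fit_trends(bin_series(feats, ana, bin_days = 2))
subset(trends, group == "grp01" & feature == "custom:isolation",
       select = c(slope, r2, q, change, significant))
#>            slope        r2            q       change significant
#> 391 0.0009974662 0.8162453 8.768532e-19 0.0008141771        TRUE
```

The planted isolation drift was 5e-4 per day; bins are 2 days wide, so the
fitted slope of ~0.000997 per bin recovers it to within 0.3%, the fit is
tight (R² = 0.82), and the trend survives BH correction across all 540
group × feature hypotheses. `rank_semantic_change(trends)` then aggregates
such significant changes into the per-group negativity ranking, and the
other stages (`build_binary_task`/`train_classifier`,
`fit_cluster_model`, `fit_topic_model`, `distance_trajectory`) consume the
same corpus and feature matrix.

A thin command-line wrapper over the full pipeline lives at
`inst/cli/mindlang.R` (subcommands `simulate`, `features`, `trends`,
`classify`, `cluster`, `topics`, `converge`, `run-all`); `run_full()` is
the equivalent R entry point and writes a CSV bundle plus a run manifest.

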