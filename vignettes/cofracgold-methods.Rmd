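---
title: "Methods: benchmarking gold-standard complexes with co-fractionation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking gold-standard complexes with co-fractionation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofracgold)
```

## Scope and model

Curated complex databases compile protein-protein interactions across
thousands of experiments. In any one co-fractionation (CF) experiment
only a subset of those interactions is intact, so treating the full
database as a gold standard both mislabels classifier training data and
inflates error-rate estimates. This package quantifies the mismatch at
three levels — pair, complex, and database — and derives
experiment-specific gold-standard subsets that repair it.

The primitive observable is the chromatogram: one protein's SILAC ratio
over successive fractions of a separation gradient, with missing values
where the protein was not quantified. All downstream statistics reduce
to two pair similarities and their aggregates.

### Pair similarity

* `pearson_zero_fill(x, y)`: missing values are replaced by zeros and
  the ordinary Pearson correlation is computed over the full fraction
  axis. Zero-filling reads non-quantification as absence, which is the
  conservative choice for ratio data. Profiles that are constant after
  filling have no defined correlation; such pairs are excluded from
  tables and counted (`n_excluded`), never imputed.
* `euclidean_minmax(x, y)`: each profile is zero-filled, then rescaled
  to min 0 / max 1, and the Euclidean distance taken. Zero-filling
  precedes normalization: the missing-value rule is a global
  preprocessing step, and filling after rescaling would let the
  missingness pattern shift a profile's dynamic range.

A pair with correlation below zero is called *anti-correlated* — a
deliberately conservative signature of non-interaction, since truly
co-eluting proteins essentially never anti-correlate while unrelated
proteins with disjoint elution peaks usually do.

### Complex-level permutation test

For each complex, the statistic is the mean of all within-complex
pairwise correlations, pooled *flatly over comparisons* across datasets
(each pairwise comparison weighs the same, so a dataset quantifying more
members contributes more). The null resamples protein identities: each
permutation draws, from every dataset's quantified roster, a random set
the same size as the complex's observed membership in that dataset, and
recomputes the pooled mean. Resampling identities rather than shuffling
fractions preserves each dataset's marginal profile structure — the
question is "is this *set* more internally correlated than a random set
of the same size?", not "are these profiles non-random?".

P-values use the add-one rule, `p = (1 + #{null >= obs}) / (1 + n_perm)`
(default `n_perm = 1000`), so no finite permutation run reports zero.
The high (enriched) and low (depleted) tails form two separate families,
each Benjamini-Hochberg corrected across observed complexes; a complex
is classed at `q < alpha` (default 0.05) and can never be both enriched
and depleted. Housekeeping calls across tissues deliberately use
*uncorrected* per-tissue `p < alpha` conjoined over all tissues: the
conjunction is itself the multiplicity control, and the rule mirrors how
such calls are made in practice.

### Hypergeometric enrichment and its universe

Published interactomes are consumed as edge lists. For one interactome,
the universe is the set of proteins that occur in its edges *and* belong
to at least one complex; each complex contributes its within-complex
pairs over that universe (`n` possible, `k` present as edges). With `N`
and `K` the totals over all observed complexes, enrichment is
`P(X >= k)`, `X ~ Hypergeom(N, K, n)` — i.e. the reference rate is the
within-database edge density. The database-wide universe is the main
unstated degree of freedom in this kind of analysis; restricting it to
within-complex pairs makes degenerate cases explicit (a complex holding
every observed pair has `p = 1` by construction) and is the
interpretation under which "enriched against the average rate" is
well-defined. The generic tail `hypergeometric_upper_tail()` also
underlies the set-overlap test in the expression module.

"Predicted" for technique-specific selection means at least one
within-complex edge, not the hypergeometric call: selection asks whether
a study *saw* the complex at all. The default rule keeps complexes
predicted by at least two-thirds of a technique's interactomes and at
most one interactome of each other technique. Its chance model permutes,
within each interactome, which complexes carry the predicted flag —
preserving each interactome's detection count, the only margin the
observed count conditions on — and reports the add-one bootstrap
p-value.

### CF-specific subsets

A complex enters the subset at threshold `t` if its enrichment p-value
is below `t` in *every* chosen CF interactome (an any-k-of-n mode
exists but conjunction is the default, matching the threshold-1 reading
"at least one interaction in each study"). At `t = 1` the criterion is
exactly the predicted flag. Subsets nest along the conventional ladder
1, 1e-2, 1e-6, 1e-10. Random control subsets are drawn uniformly
without replacement over *unique gold pairs*, not complexes, so the
control matches pair count, the quantity that drives label volume.

### Predictor

The classifier is Gaussian Naive Bayes with per-class feature means and
variances (variance floor 1e-9 guards exact separability) over three
features per pair: Pearson correlation, min-max Euclidean distance, and
co-apex distance (absolute difference of maximum-intensity fractions),
averaged over the datasets where both profiles are computable. TP = pair
co-member of a gold complex; FP = both proteins in the gold database but
never co-complexed; everything else is unlabeled. Labelled pairs are
scored strictly out-of-fold (stratified 10-fold, seeded); unlabeled
pairs are scored by the model trained on all labelled pairs, count
toward interactome size, and never enter precision. Ranking ties break
by canonical pair order so results are deterministic. Precision is
cumulative down the ranked list; `interactome_at_precision()` returns
the deepest rank whose cumulative precision still meets the target —
the thresholded-set alternative would differ only by monotonizing the
curve first.

## The synthetic-data generator

The generator emulates the statistical structure the analyses consume,
with planted ground truth:

* **Chromatograms**: one or two Gaussian peaks (secondary peak with
  probability 0.3 at 30-80% amplitude) over 50 fractions, peak SD 2
  fractions, height 10 on the ratio scale; additive Gaussian noise
  truncated at zero (SILAC ratios are nonnegative), default SD 1 — a
  tenth of the peak height; 20% of cells missing at random. Each
  protein additionally carries a shared broad elution envelope
  (Gaussian, SD a third of the gradient) with per-protein amplitude
  uniform on [0, 0.3 x peak height]. The envelope reproduces two
  features of real CF data that matter for calibration: random pairs
  are mildly positively correlated on average while the *majority* of
  random pairs still anti-correlate (~60-65% with R < 0).
* **Complexes**: disjoint member sets of size 2-10 drawn from the
  protein pool; by default 60 complexes among 500 proteins, 3 replicate
  datasets. A configurable share co-elutes (members share a
  dataset-specific peak center, jitter at most a quarter peak width); a
  share is *disrupted* — members are spaced evenly across the gradient
  with random order, so no within-complex pair co-elutes and the
  complex sits in the depleted tail; the remainder are *neutral*, with
  independent background centers, indistinguishable from the null.
  The even-spacing design was chosen over windowed "anti-phase"
  variants because members confined to shared windows correlate with
  each other, which can make a nominally disrupted complex look
  enriched.
* **Interactomes**: per technique (6 CF, 3 AP-MS, 3 Y2H by default),
  within-complex pairs of technique-detectable complexes (CF mask =
  co-eluting status; AP-MS and Y2H masks Bernoulli(0.5)) become edges
  with probability 0.8, plus noise edges over random protein pairs
  (3 x n_proteins attempts at rate 0.5) so the edge list covers most of
  the proteome, as published interactomes do — this keeps unsupported
  complexes inside the enrichment universe, where they belong. CF
  interactomes emit quantified rosters (90% of the proteome), Y2H
  interactomes bait lists.
* **Expression**: lognormal per tissue around protein-specific base
  levels; housekeeping proteins (members of co-eluting complexes) get
  across-tissue CV 0.2, others 1.5; 7 tissues.

What the generator does **not** emulate: correlated missingness,
peak-shape heterogeneity and tailing, shared contaminant signatures,
protein-abundance-dependent detection, and overlapping complex
membership. Tests passing on this generator therefore certify the
statistical machinery (calibration, recovery, ordering effects), not
performance on any particular real dataset.

## Numerical and design choices

* Isoform tags: a single trailing `-<digits>` group is stripped only
  when the stem matches a UniProt-style accession; other identifiers
  pass through. Protein groups resolve to their first accession.
* Missing encoding: empty cells, `NA`, `NaN` on read; empty on write.
* Oracle comparisons in tests use absolute tolerance 1e-12; the
  alternative sorted-data Gini formula suffers catastrophic
  cancellation near G = 0, which is why comparisons are absolute.
* Permutation and bootstrap p-values use the add-one rule throughout.
* Fold assignment is stratified per class; the fold count drops to the
  minority-class size when needed.
* `run_all()` writes every stage output plus a manifest of MD5
  checksums; all seeds live in the config, and a rerun with the same
  config is byte-identical.

## Problem sizes used by the test suite

Calibration and recovery checks run at sizes chosen to make their Monte
Carlo error small relative to the bands they assert: 200 structure-free
complexes (two pooled datasets, 999 permutations) for permutation
calibration, where the pooled rejection rate over the two one-sided
families is used because a single 200-complex tail has binomial SD
~0.015; 200 complexes of size 10-16 at edge density 0.5 for
hypergeometric calibration, where the generator's default 2-10 sizes
would leave the discrete p-grid too coarse near the 0.05 tail (the
exact test is then conservative, not miscalibrated); 100 complexes
(30 co-eluting / 30 disrupted / 40 neutral) pooled over 20 datasets for
class recovery, matching the pooling depth of a multi-dataset CF study;
50 seeded replicates of a 250-protein study for the gold-subset
comparison; and 50 replicates of 200-vs-200 protein groups for the Gini
separation check.

## Limitations

* The enrichment universe and the bootstrap's resampling unit are
  genuine analysis choices; both are configurable and alternatives
  (all-pairs universe, edge resampling) would shift absolute p-values.
* Depletion detection for very small complexes (2-3 members) needs many
  pooled datasets: a single anti-correlated pair is simply not extreme
  relative to a null in which most random pairs are themselves
  anti-correlated.
* The strict subset thresholds (1e-6, 1e-10) are rarely attainable for
  complexes of <= 10 members (at most 45 within-complex pairs); with
  the default synthetic sizes those subsets are usually empty, whereas
  real databases contain far larger complexes.
* Gini analysis drops missing expression values per protein rather than
  zero-filling: expression matrices, unlike chromatograms, carry no
  "absent means zero" convention here.
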