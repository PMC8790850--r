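---
title: "Host source tracking of gut microbiota: models, nulls and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host source tracking of gut microbiota: models, nulls and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microsource)
```

`microsource` implements an analysis workflow for deciding whether a fish's
gut microbiota identifies it as wild-caught or farm-raised, and for
diagnosing *when* that identification should be distrusted. The workflow has
three scientific layers: community description (diversity, distances,
variance partitioning, core taxa), community assembly (the Sloan neutral
model and phylogenetic null models), and supervised source classification
(a random forest with several validation schemes), tied together by a
linkage test asking whether stochastically assembled communities are the
ones the classifier gets wrong.

This vignette explains the models, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical and design decisions that were genuinely open.

## The community layer

Counts are normalized by rarefaction: each sample is subsampled without
replacement (one multivariate hypergeometric draw, seed-controlled) to a
common depth, 10,000 reads by default; shallower samples are dropped with a
warning. All downstream statistics assume this common depth — the neutral
model in particular, because its detection limit is `1/depth`.

Alpha diversity is the Shannon index on natural logs. Beta diversity is
Bray–Curtis on relative abundances and weighted UniFrac: for every branch
of the rooted OTU tree, the branch length multiplies the absolute
difference of the fractions of each sample's reads descending from it; the
normalized variant (default) divides by the same sum over branch-wise
totals, bounding values in [0, 1]. The implementation accumulates
descendant mass by a single postorder pass and is checked in the test suite
against a naive branch-enumeration oracle on every tree shape up to six
tips.

Group structure on a distance matrix is tested two ways. AMOVA partitions
the squared distances into among- and within-group components and permutes
group labels; the p-value uses the `(count + 1)/(n_perm + 1)` estimator so
it can never be zero. Variance explanation uses sequential (order-dependent)
distance-based partitioning via `vegan::adonis2`. Order matters
scientifically here: in a design where every batch contains animals of one
source, fitting batch first leaves source with zero residual degrees of
freedom. `permanova_r2()` reports such terms as non-estimable rather than
erroring, which is exactly the "no independent contribution" structure of a
batch-nested study. Which ANOVA flavour the original analyses used is not
recoverable from the methods available to us; sequential partitioning is
the standard reading and the choice is recorded in the output.

Core taxa are OTUs detected (count > 0) in strictly more than a prevalence
threshold (default 0.70) of a group's samples; the abundance/prevalence
filter used before classification likewise applies strict `>` thresholds.
`gene_copies_per_ng()` is the small analytic helper for judging absolute
bacterial load: with 650 g/mol per base pair of dsDNA, a 4 Mbp genome
carrying four 16S operons yields about 9.3e5 copies per ng of pure
bacterial DNA (926,483 exactly under CODATA's Avogadro constant), so
measured loads orders of magnitude below that indicate host-dominated DNA.

## The Sloan neutral model

The model predicts an OTU's occurrence frequency across samples from its
mean relative abundance alone, assuming drift and migration but no
selection. If `p` is the metacommunity relative abundance and `Nm` the
product of local community size and migration rate, the local abundance is
Beta(`Nm p`, `Nm (1 - p)`) and the predicted occurrence frequency is the
probability of exceeding the detection limit `d = 1/N`:

    f_hat(p) = 1 - I_d(Nm p, Nm (1 - p))

with `I` the regularized incomplete beta function. `fit_sloan()` estimates
`Nm` by bounded nonlinear least squares on the (p, f) cloud, multi-started
on the log scale from 1e2–1e5 because the SSE surface can be flat for weak
fits. R² is computed against the constant mean-frequency model and may be
negative; it is not clamped. OTUs with zero mean abundance are excluded.

**Envelope.** The 99% prediction envelope per OTU is the 0.5%/99.5%
quantile band of the sampling distribution of observed frequency given the
fitted detection probability. Under the model, detection across `n` samples
is iid Bernoulli(`f_hat`), so that distribution is Binomial(`n`, `f_hat`);
the band is `qbinom` quantiles divided by `n` (default), with the Wilson
score interval available as the `envelope = "wilson"` alternative. Because
binomial quantiles are discrete, a quantile can land marginally past the
mean; bounds are clamped to always contain `f_hat`. OTUs are then
classified within / above / below the band; "above" flags taxa occurring
more often than neutrality predicts (selected for presence), "below" flags
patchy taxa — in these data typically abundant but batch-specific ones.

**A known bias worth stating.** When data are generated by the full
sampling process — latent Beta abundances *then* multinomial read
sampling — reads can detect OTUs whose latent abundance is below `1/N`.
Occurrence frequencies of near-limit OTUs are therefore systematically
higher than the threshold-detection model expects, and the least-squares
`Nm` runs high (about 25% at `N = 10,000`, `S = 200`, `n = 100`,
`Nm = 1000`; the acceptance script recomputes this number). In a controlled
experiment where detections are drawn by the threshold rule itself the same
estimator is unbiased to within 1%, so the bias belongs to the
detection-model approximation, not the optimizer. We keep the classical
formulation — it is the one the field fits — and document the bias rather
than compensating for it.

## Phylogenetic null models

`mntd()` is the abundance-weighted mean nearest-taxon distance; `nti()` is
its negated z-score against a taxa-label null (positive NTI = phylogenetic
clustering), and `beta_nti()` is the between-sample analogue with the
conventional sign (βNTI < −2: homogeneous selection; |βNTI| ≤ 2:
stochastic; > 2: variable selection; ties count as stochastic, an explicit
boundary policy). OTUs are filtered to mean relative abundance > 0.01%
before the null (the threshold is a parameter), patristic distances are
precomputed once per tree, and the null shuffles taxa labels across that
matrix — one shuffle per iteration shared by all samples, 999 iterations by
default, seed-controlled. Internally taxa are put in canonical (sorted)
order first, so results are invariant to the column order of the input
table. When the null has essentially zero variance (e.g. a star tree where
all distances are equal) the z-score is reported as 0 when the observed
value equals the null (no deviation) and NaN otherwise, with a warning.

Two structural facts about this null are easy to trip over and shaped our
test fixtures. First, the z-score of a clade-confined community is bounded
by the null's spread, which is wide when the tight clade is a large share
of the taxa pool — demonstrating clustering cleanly needs a pool much
bigger than the clade and a fairly uniform background. Second, because the
same permutation applies to both samples of a pair, co-occurring taxa
contribute zero to βMNTD under the observed *and* the null matrices;
βNTI's homogeneous-selection signal is therefore carried entirely by taxa
that turn over between samples within the conserved clade, and its
magnitude grows with how many such taxa there are. The
selection-vs-neutral demonstration in the tests and the acceptance script
uses communities drawing ~25 of 40 tight-clade taxa so that turnover is
plentiful; realistic-sized marker sets (5–20 OTUs) produce the right sign
but modest magnitudes.

Since βNTI is pairwise while summaries are often quoted per sample, the
result object carries both the raw pairwise fractions and two per-sample
reductions (per-sample class fractions and majority class).

## The classifier

The learner is a standard random forest (5001 trees, default `mtry`),
consuming relative abundances of OTUs that survive the 20%-prevalence
filter. Splits are stratified by batch so that every batch appears in both
partitions at the requested ratio. Reported quantities: AUC by the rank
(Mann–Whitney) construction, equivalent to trapezoidal ROC integration
with midpoint tie handling; per-class accuracy at the 0.5 probability
threshold (published practice varies between thresholded probabilities
and majority votes, so the convention is labelled in the report); and
out-of-bag permutation
importance (mean decrease in accuracy), the mode recorded in every report.
Top-k selection breaks ties lexicographically by OTU id, recorded. The
10-fold feature curve re-ranks features inside each training fold, so no
selection information leaks into validation. Leave-one-batch-out trains on
the remaining batches with an internal 8:2 split, 20 repeats; bootstrapped
assignment probabilities repeat a 5:5 per-batch split 100 times and average
each sample's predicted probability of its true class over the iterations
where it was held out.

## The linkage test

For every sample, the summed relative abundance of neutral ("within") and
below-prediction OTUs is computed against the neutral fit of the sample's
own source (wild samples against the wild fit, farmed against farmed,
matching per-source fitting). The "upper boundary of the 90% confidence
interval" of the load is not defined precisely in published practice; we
default to the normal construction `mean + 1.645 sd` and report the
empirical 95th percentile alongside, so the choice is auditable. Whether
the neutral and below-prediction loads are pooled or tested separately is
equally ambiguous; `linkage_test()` computes the combined test and both
single-category tests. Samples above the boundary are cross-tabulated
against poorly assigned samples (mean correct probability < 0.5) and
tested with Fisher's exact test (two-sided point-probability method, the
`stats::fisher.test` construction). An empty margin returns p = 1 with a
flag instead of an exception. Mechanistically, the discriminating quantity
in our simulations is the *neutral* load: misassigned samples are those
whose reads are dominated by the source-uninformative neutral background.

## The synthetic-data generator

`simulate_dataset()` produces the study structure end to end: a log-normal
metacommunity (`meanlog = 0`, `sdlog = 2`); per-sample Sloan draws
Beta(`Nm p`, `Nm (1 − p)`) renormalized; source-selected OTUs multiplied by
`selection_strength` in their own source; a per-batch multiplicative
log-normal perturbation (`batch_effect_sd`); multinomial reads at depth
10,000; and a random phylogeny in which each selected set is grafted as its
own clade, with internal branch lengths scaled by 0.1 because a selected
cluster stands for a congeneric group, much shallower than the tree that
spans the community. Selected roles go to deterministic abundance ranks
(alternating between sources), which keeps the generator's random stream
identical to the pure neutral generator when selection and batch effects
are switched off — a property the tests assert exactly.

Two presets define the study conditions:

* **Dominance regime** (`sim_config()`): ten batches (five wild — C, F, N,
  S, W — five farmed — A, B, H, T, X), 20 individuals each, five selected
  OTUs per source at the top abundance ranks, 25-fold boost,
  `batch_effect_sd = 1`, `Nm = 1000`. The selected cluster holds ~90% of
  its source's reads (the dominance observed in wild animals) and batch
  explains more community variance than source, reproducing the nesting
  problem that motivates leave-one-batch-out validation.
* **Moderate regime** (`sim_config_moderate()`): markers at abundance ranks
  21–40 with an 8-fold boost, `Nm = 30`, `batch_effect_sd = 0.3`. The
  neutral background dominates every sample, marker occurrence is patchy,
  classification is good but imperfect (AUC in the 0.9s at a 5:5 split,
  seed-dependent, rising with the training fraction), roughly a tenth of
  samples are poorly
  assigned, and the markers fall below the prediction envelope. This is
  the regime in which the stochastic-load linkage is informative; in the
  dominance regime the classifier saturates (AUC ≈ 1) because simulated
  markers are noiseless compared with real 16S data, and a saturated
  classifier leaves no misassignment to explain.

What the generator does *not* emulate: sequencing error and chimeras,
compositional correlations beyond the renormalization step, taxa shared
between sources with source-specific abundances (markers are boosted
multiplicatively, so their *occurrence* stays neutral — one reason
simulated markers classify as "below", not "above"), uneven batch sizes,
and any longitudinal structure. Passing tests on these simulations
therefore demonstrate internal correctness and directional behaviour, not
that real-data values (R², βNTI fractions, AUC) are reproduced — those
depend on the deposited sequencing data, which this package deliberately
does not require.

## Numerical choices and evaluation sizes

Permutation p-values always use `(count + 1)/(n_perm + 1)`. All stochastic
operations take explicit seeds and are bitwise reproducible; the pipeline
rerun twice with the same seeds writes byte-identical bundles. Fisher's
exact p-values are discrete and conservative, so the test-suite calibration
check applies the randomized probability integral transform under the exact
conditional (hypergeometric) distribution of the p-value given each table's
margins, which is exactly uniform under the null; AMOVA and PERMANOVA
p-values are near-continuous and are KS-tested against the uniform
directly.

The standard evaluation sizes used by the tests and the acceptance script,
chosen as representative desk-scale conditions: neutral recovery at
`S = 200`, `n = 100`, `N = 10,000`, `Nm = 1000` over 20 seeds; NTI
calibration on 25-taxon, 5-sample communities over 100–200 replicates with
99 randomizations; βNTI demonstrations on 200-taxon two-clade trees;
classifier experiments on 200-sample, 300-OTU (or 40-sample, 80-OTU)
datasets with 301–501 trees; the analysis drivers under `analysis/` use
the full defaults (999 randomizations, 5001-tree-scale forests scaled to
501 where the experiment repeats many fits).

## Known limitations

* The neutral fit inherits the threshold-detection approximation; absolute
  `Nm` values on read-sampled data run ~25% high (see above).
* βNTI magnitudes on realistic marker-set sizes are conservative relative
  to what large, turnover-rich real communities produce.
* The classifier experiments share one forest implementation; no
  alternative learners are provided by design.
* AMOVA is implemented for a single grouping factor (the only design the
  workflow needs); nested/hierarchical AMOVA is out of scope.
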