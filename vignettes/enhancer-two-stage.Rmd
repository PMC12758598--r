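---
title: "Two-stage enhancer prediction and boundary localization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage enhancer prediction and boundary localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(enhancerscan)
```

## The problem

Enhancers are distal cis-regulatory elements marked by open chromatin
(DNase-seq) and characteristic histone modifications (H3K27ac, H3K4me1,
H3K4me3, H3K9ac), and functionally testable by STARR-seq. `enhancerscan`
implements a two-stage analysis:

1. **Region classification.** Decide whether a 4000 bp genomic region
   contains an enhancer, using any available combination of binned
   epigenetic signal tracks.
2. **Boundary localization.** Within a positive region, find the enhancer's
   boundaries from the DNA sequence alone, by scoring 200 bp sliding windows
   and merging high-probability windows.

## Stage 1: blending ensemble with a KAN meta-classifier

### Sample construction

Candidate regions are the base-level intersection of STARR-seq and DNase-seq
peak coverage; a candidate that overlaps any ChIP-seq peak by at least one
base is labeled an enhancer. Every sample is standardized to exactly 4000 bp.
The anchoring rule (nowhere specified by convention) is ours: anchor at the
candidate midpoint, expand symmetrically, clip at chromosome ends and shift
back to preserve length — symmetric context is the least biased choice.
Negatives are drawn uniformly from the genome, rejecting any window that
overlaps a positive by one base or more (at most `1000 * n` placement
attempts), at the conventional 1:10 positive:negative ratio. Signals are
averaged in 10 bp bins, so each signal contributes a 400-length feature
block; bases with no track coverage count as 0, the standard signal-track
convention.

All coordinates are 0-based half-open (BED native); "overlap" always means
at least one shared base.

### Layer 1: the base-classifier registry

The original design delegates layer 1 to an external AutoML framework that
auto-generates ~123 models; that zoo is an artifact of the framework, not of
the method. `enhancerscan` replaces it with an explicit, ordered,
user-extensible registry. The default has eight diverse tabular learners:
ridge and lasso logistic regression (glmnet), Gaussian naive Bayes, diagonal
LDA, weighted 5-NN, gradient-boosted trees in two configurations, and a
random forest. Because the hosting environment provides no R tree ensemble
package, the boosted trees and the forest are implemented in the package as
vectorized weighted regression trees (greedy least-squares splits, Newton
leaf values for the binomial deviance, per-tree feature subsampling); they
are exercised against separable and null benchmarks in the test suite. All
entries honor per-sample weights — the positive:negative weight ratio
defaults to 10:1 to counter the 1:10 class imbalance (k-NN honors weights
through weighted voting; an entry that cannot is free to emulate weights by
replication, which is exactly equivalent for likelihood-based learners, as
the test suite verifies for weighted logistic regression).

Each registry entry is fit per signal on that signal's 400-column block of
the 70% "blend-train" split (stratified 7:3, preserving the class ratio
within one sample). Its **hard 0/1 predictions** on the 30% holdout — not
probabilities — become the meta-features, one column per entry, concatenated
across signals in the declared signal order. A configuration flag for
probability meta-features exists as an extension, but hard labels are the
specified behavior.

### Layer 2: the Kolmogorov–Arnold network

The meta-classifier is a from-scratch Kolmogorov–Arnold network: every edge
carries a learnable univariate function

$$\phi(x) = w_{\mathrm{res}}\,\mathrm{silu}(x) + \sum_j c_j B_j(x),$$

with $B_j$ cubic B-spline basis functions on a uniform grid and
$\mathrm{silu}(x) = x\,\sigma(x)$ a fixed smooth residual; a node adds its
incoming edges plus a bias, and the final layer emits two logits. Training
minimizes class-weighted softmax cross-entropy with mini-batch Adam.

Hyperparameters are unstated in the source method, so the package fixes
reference defaults at tabular scale: grid of $G = 5$ intervals, spline
degree $k = 3$ (so $G + k = 8$ coefficients per edge), grid support
$(-1, 3)$ — comfortably covering 0/1 meta-features — with out-of-range
inputs clamped rather than extrapolated (spline extrapolation blows up;
meta-features are bounded anyway), architecture
$[p, \min(2p, 64), 2]$, Adam at $\beta = (0.9, 0.999)$,
$\varepsilon = 10^{-8}$, learning rate $10^{-3}$, 100 epochs, batch 256.
Grid refinement and pruning from the original KAN recipe are deliberately
omitted. Analytic gradients are verified against central finite differences
(relative tolerance $10^{-4}$) and the basis is verified to be a
non-negative partition of unity on its support; both checks run in the
acceptance suite.

The KAN is evaluated by stratified 5-fold cross-validation on the
holdout-derived meta-features (each fold must contain both classes or the
run aborts), reporting mean ± sd accuracy, AUROC and AUPRC, then refit on
all holdout rows for inference. The decision threshold on the meta
probability is 0.5.

## Stage 2: window scoring and dynamic thresholding

A 4000 bp region is segmented into 200 bp windows every 50 bp — 77 windows.
Each window is embedded; the built-in embedder is a normalized k-mer
frequency vector (default $k = 6$, dimension $4^6$; k-mers with non-ACGT
characters are skipped), standing in for the out-of-scope pretrained
transformer embedder. Precomputed external embeddings (one delimited row per
window) plug in through the same interface with strict shape checks.

The scorer is a stacking model: a gradient-boosted level-1 learner produces
**out-of-fold** probabilities under stratified 10-fold cross-validation (a
sample's meta-feature always comes from the fold model that never saw it —
the suite confirms a memorizing 1-NN learner scores at the class prior, not
1.0, on label-free data). The OOF column is concatenated to the original
features; each candidate meta-learner (gradient-boosted trees, ridge
logistic, random forest) is scored on a stratified 20% holdout and the best
is refit on everything. At inference, where out-of-fold is undefined, the
meta-feature is the mean of the ten fold models' predictions — standard
stacking practice.

### The boundary call

Given the 77 window probabilities $p$, the dynamic threshold is
$t = \bar p - 0.3\,\hat\sigma(p)$. Windows with $p_i \ge t$ are retained,
runs of consecutive retained windows are merged, and the run with the
highest mean probability is the enhancer call, spanning from its first
window's start to its last window's end. Numerical conventions the source
leaves open, fixed here once:

- $\hat\sigma$ is the **population** standard deviation (divide by $n$);
- retention uses $\ge$, so the zero-variance profile retains everything;
- ties between runs with equal mean go to the **leftmost**;
- exactly one region is reported per input (multi-enhancer calling is a
  non-goal).

Since $\max(p) \ge \bar p \ge t$, at least one window always survives. The
implementation is checked against an exhaustive oracle (enumerate all
maximal retained runs, take the argmax of means) on 1000 random profiles.

## The synthetic world

The generators state one fixed world; their defaults are not tuned per test.

- **Signal datasets**: positives carry a Gaussian-shaped enrichment bump
  (height 3, sd = bump_width/2 with bump_width 1000 bp, centered) over a
  flat background of 0.5, in every configured signal; negatives are
  background only; Gaussian noise of sd 0.3 on every bin; 1:10 class ratio.
  A smooth unimodal bump is the canonical histone-mark idealization. The
  noise-robustness protocol adds elementwise Gaussian noise with
  $\sigma \in \{0.1, 0.3, 0.5, 0.7, 0.9\}$ on top.
- **Localization regions**: 4000 bp uniform-ACGT sequences with one
  motif-dense enhancer segment (default 600 bp, i.e. 12 window steps) at a
  50 bp-aligned offset. Motif copies are planted **evenly spaced** with small
  jitter, so density is homogeneous inside the segment and proportional to
  overlap at its edges; with uniformly random placement the within-segment
  density fluctuates so strongly that no scorer can resolve boundaries at
  window resolution — homogeneity is part of the stated "clean planted
  enhancer" world, not a tuning knob.
- **Window training sets**: labels follow the ≥ 50%-overlap rule. Positives
  are sampled fully inside enhancer segments; negatives anywhere with
  < 50% overlap, with half of them deliberately drawn from the flanks
  (1–49% overlap). Without flank negatives a scorer only ever sees
  zero-motif negatives, learns motif *presence* rather than *density*, and
  fires on windows barely touching the enhancer; flank negatives pin its
  decision near the label boundary, which is what "well-trained" should
  mean. The effective transition then sits mid-margin (~75% overlap), giving
  boundary errors of at most one step on clean data.

What the generators do **not** emulate: real signal autocorrelation, GC
bias, replicate structure, blacklist artifacts, multi-enhancer regions, or
the pretrained sequence embedder. A green synthetic test therefore
establishes algorithmic correctness and recoverability in a controlled
world, not performance on ENCODE-scale data.

## Noise-sweep design

The qualitative robustness claim — mean AUROC does not increase as noise
grows from $\sigma = 0.1$ to $0.9$ — is tested with a paired design: per
seed, the same base dataset and the same standard-normal noise direction
scaled by $\sigma$ (so corruption grows monotonically within a seed), five
seeds, weak enrichment (height 0.25 over noise 0.2) so the sweep spans a
real decline rather than a saturated flat line. A wobble of 0.02 per
consecutive step is allowed, fixed before measurement: the published noise
table itself is non-monotone at the third decimal, so the claim under test
is the trend, not strict ordering.

## Scaled-down testing

Desk-scale runs use tens of positives, a single signal kind, a reduced
registry (logistic + naive Bayes + boosted stumps), 30–40 KAN epochs and
$k = 4$ embeddings so the whole suite fits a small CPU budget. The package
defaults remain at the stated values (full registry, 100 epochs, $k = 6$).
The headline accuracies of the original study depend on external ENCODE
data, an external model zoo and a pretrained embedder, and are out of scope
by design; nothing in this package asserts them.

## Known limitations

- Region-model persistence is limited to the KAN meta-classifier
  (`save_kan()`/`load_kan()`); base-classifier objects are arbitrary R
  models and are retrained deterministically from the seed where needed
  (e.g. the CLI's `locate` trains its scorer from the synthetic generator,
  since the real benchmark training sets are external).
- Layer-1 bagging ("best_quality" presets) of the original framework is not
  replicated; registry entries are fit once on the blend-train split.
- The k-mer embedder is a deliberate stand-in; with external embeddings the
  locator's accuracy depends entirely on their quality.
- bigWig tracks are not read directly; convert to bedGraph first.
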