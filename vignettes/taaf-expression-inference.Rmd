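---
title: "Adaptive-activation networks for landmark-based expression inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-activation networks for landmark-based expression inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide expression profiling is expensive, but transcript levels are
highly correlated: a well-chosen subset of roughly a thousand *landmark*
genes carries most of the information in the transcriptome.  Landmark-based
inference therefore measures only the landmarks and reconstructs the
remaining *target* genes with a regression model — in the production-scale
setting, a family of feed-forward networks with one to three equally wide
hidden layers, a linear output unit per target gene, and the target set
split into two halves served by two separate networks.

`taafgex` implements that stack around a *transformative adaptive
activation function* (TAAF).  A TAAF wraps any fixed inner activation $f$
(here $\tanh$ or the logistic sigmoid) in four per-neuron trainable
parameters:

$$ g(y) = \alpha \, f(\beta y + \gamma) + \delta . $$

A neuron computes $\alpha f(\beta \sum_i w_i x_i + \gamma) + \delta$;
$\gamma$ is exactly the neuron's bias, so TAAF units carry **no separate
bias term** — keeping one would double-count a parameter.  $\alpha$ and
$\delta$ scale and shift the output range, $\beta$ rescales the input
slope.  At initialization $(\alpha, \beta, \gamma, \delta) = (1, 1, 0, 0)$,
so a TAAF network starts from exactly the same function as its
fixed-activation twin; everything it gains, it gains by adapting.

Two closed-form facts anchor the implementation and its tests:

* $\tanh(u) = 2\,\sigma(2u) - 1$, so the tanh-TAAF $(\tfrac12, \tfrac12,
  0, \tfrac12)$ *is* the logistic sigmoid, and any tanh-TAAF maps to a
  pointwise-equal sigmoid-TAAF via $(\alpha, \beta, \gamma, \delta)
  \mapsto (2\alpha, 2\beta, 2\gamma, \delta - \alpha)$
  (`equivalent_sigmoid_params()`).  Choosing tanh versus sigmoid is a
  choice of initialization, not of function family.
* For odd $f$, $g$ is invariant under $(\alpha, \beta, \gamma) \mapsto
  (-\alpha, -\beta, -\gamma)$; recovered parameters are only identified up
  to this orbit, which is why the single-unit recovery check accepts
  either representative.

The gradients used by backpropagation are the analytic partials
$\partial g/\partial y = \alpha\beta f'$, $\partial g/\partial\alpha = f$,
$\partial g/\partial\beta = \alpha y f'$, $\partial g/\partial\gamma =
\alpha f'$, $\partial g/\partial\delta = 1$; these closed forms are the
contract the test suite verifies against central finite differences.  The
comparison uses the standard gradient-check denominator
$|a - n| / \max(1, |a|, |n|)$: where a saturated tanh drives a true
derivative to $10^{-10}$, a pure relative error would only measure
finite-difference roundoff.

The *adaptivity mask* restricts which of the four parameters train.  The
sixteen subsets (`taaf_variants()`, ordered by size then canonical
parameter order) span the ablation family, and single-parameter masks
recover two classical adaptive activations: $\{\alpha\}$ is the trainable
amplitude, $\{\beta\}$ the slope-varying activation.

## Training protocol

`train_network()` runs mini-batch Nadam — Adam with Nesterov momentum —
with learning rate $5\times10^{-4}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
momentum schedule $\psi(t) = \beta_1(1 - 0.5 \cdot 0.96^{t\eta})$ with
schedule decay $\eta = 0.004$ per update step, and batch size 256.  Sample
order is reshuffled each epoch under the config seed, dropout (rate 0.25 by
default) is applied to hidden activations only, with inverted scaling so
the evaluation path needs no rescaling, and the model reported is the
epoch with the lowest validation MMAE (first occurrence on ties), not the
last.  The protocol's full-scale setting is 600 epochs; the package's own
benchmarks use desk-scale problem sizes (below) where far fewer suffice.

The training loss defaults to mean squared error while *all* reported
metrics are MAE-based; only the metric, not the loss, is pinned by the
protocol, so `loss_kind` exposes the choice.  Epoch-level determinism is
guaranteed for this backend; agreement with other optimizer
implementations is a non-goal.

Two conventions worth stating exactly:

* **Weight initialization** is normalized (Glorot) uniform on
  $\pm\sqrt{6/(\text{fan}_\text{in} + \text{fan}_\text{out})}$; biases and
  TAAF parameters start at their canonical values.
* **Parameter counting** (for capacity matching): a fixed unit owns
  fan-in weights plus one bias; a TAAF unit owns fan-in weights plus four
  TAAF parameters and no bias.  `capacity_matched_width()` returns the
  largest width whose TAAF network stays within the fixed reference's
  budget (the sandwich property); published width tables from other
  counting conventions are deliberately not treated as an oracle, since no
  convention we could reconstruct reproduces them.

## Data handling

Standardization is **global**: one mean and one population standard
deviation for the whole matrix (`global_standardize()`).  Per-gene scaling
would erase the absolute expression differences between genes and give
noise-level genes equal weight in the error metrics; global scaling keeps
highly expressed genes proportionately large, which is the point of the
method.  Population rather than sample SD is a documented exactness choice;
at any realistic matrix size the two are indistinguishable.

Splitting comes in two flavours.  `random_split()` shuffles sorted sample
ids (so splits are functions of the id set, not row order) with
largest-remainder rounding of the fractions, ties to the earlier split.
`group_aware_split()` keeps every series — a GEO-series-like sample group —
wholly inside one split, removing series-level information leakage between
training and evaluation.  Series are assigned greedily, largest first, to
the split with the largest remaining deficit; when no series dominates
(none above ~20% of samples) realized fractions track targets within a few
points, and a deviation beyond 5 points raises a warning rather than
failing.  Series labels come from an explicit metadata column or sidecar
file, never parsed out of sample-id strings.

File formats are plain text: GCT v1.2 (genes in rows) and a samples-in-rows
TSV, with gene roles supplied by a one-id-per-line landmark list.

## The synthetic benchmark

`generator_config()` defines the package's standard study conditions:
2,000 samples, 50 landmarks, 200 targets, 8 latent factors, observation
noise SD 0.3, 20 series with intercept SD 0.2.  Landmarks are a noisy
linear readout of the latent state; each target gene is a scaled and
shifted nonlinear (tanh or sigmoid) readout, with per-gene scales in
$[0.5, 3]$ and offsets in $[-2, 2]$.  That per-gene range mismatch is the
mechanism the benchmark exercises: under global standardization a
fixed-activation network must absorb each gene's range through its output
weights, while a TAAF unit can absorb it directly in $\alpha$ and
$\delta$.

What the generator deliberately does **not** emulate: probe-level noise,
quantile-normalization artifacts, realistic series composition, or the
scale of a real compendium.  Passing benchmarks here show the machinery
behaves as designed under controlled nonlinearity and range mismatch; they
do not certify error levels on real microarray data.

The paired benchmark (`taaf_benchmark()`) trains, per seed, a TAAF network
and a fixed-activation twin — same depth (1 hidden layer), width (32),
inner sigmoid, dropout, weight seed, 60 epochs, a 70/15/15 split — and
compares test MMAE with the paired Wilcoxon test on per-sample MAEs.
Sixty epochs is comfortably past the validation-MMAE plateau at this
problem size.  The TAAF variant with TAAFs in the output layer
(`output_mode = "taaf"`) replaces the linear regression head; its
$\alpha/\delta$ provide the arbitrary output range the linear head
otherwise supplies.

Phenotype fixtures plant a two-class structure: class B shifts a
designated set of target genes on the expression scale.  A scalar
`de_effect_size` shifts all of them equally; a range draws one effect per
gene.  The DGE benchmark uses 30 of 100 genes with effects in
$[0.5, 4]$ — heterogeneous by design, because a single effect size makes
every study size either floor (no method detects anything at $n = 12$) or
ceiling (every method recovers everything at $n = 60$), and neither
regime discriminates methods.  Genes near the detection boundary at each
sample size are what grade the scores, as in real cluster-derived
phenotypes.

## Model comparison statistics

Per-sample MAE over genes is the unit of replication; samples are treated
as (approximately) independent while genes within a sample are not.  MMAE
is its mean; MDAE/MMDAE are the paired differences (negative favors the
first model), with the identity MMDAE$(m_1, m_2)$ = MMAE$(m_1)$ −
MMAE$(m_2)$ and exact antisymmetry.  Uncertainty comes from a percentile
bootstrap over samples (default $B = 1000$; endpoints are inverse-ECDF
order statistics of the resampled means), and each pair is additionally
tested with the paired $t$ and Wilcoxon signed-rank tests on per-sample
MAEs.  Conventions chosen where the protocol is silent: percentile rather
than BCa intervals; zero differences dropped from the signed-rank test,
exact distribution up to 25 non-zero differences, tie/continuity-corrected
normal approximation beyond; an all-zero difference vector yields $p = 1$
with a warning and a constant non-zero difference yields $t$-test $p = 0$
with a warning (the guard mirrors `stats::t.test`'s own constant-data
criterion, since exact float equality is the wrong test after arithmetic).

## Ensembles

`per_gene_expert_selection()` assigns each target gene the model with the
lowest per-gene MAE on one half of the validation data (ties to the
lexicographically smallest model id); `enumerate_and_select()` enumerates
all model subsets up to size four, builds each subset's expert map on the
selection half, and ranks candidates by MMAE on the other half.  On the
selection half the full-pool ensemble is provably no worse than any single
model (per-gene minimality aggregates) and adding models never hurts; on
the evaluation half neither guarantee holds — which is exactly why the
two-stage design exists — so the winner is only claimed to be the best
*enumerated candidate* there.

## Downstream DGE impact

The practical question: if expression is inferred rather than measured,
how much does a differential-expression analysis degrade?
`subsample_experiment()` repeatedly draws balanced two-class subsamples
across study sizes (e.g. 12–600), calls DE on ground truth and on each
inferred matrix for the same samples (Benjamini–Hochberg adjustment,
flag threshold 0.01), and scores each method against the truth flags with
accuracy, $F_{0.5}/F_1/F_2$ and MCC, plus the mean absolute rank
displacement of truth-selected candidates (top-100 and $p < 0.05$
selections, ranks tie-broken by gene id).  Method pairs are compared with
paired Wilcoxon tests per size and metric.

The default DE backend is a vectorized Welch $t$-test; the moderated
empirical-Bayes test from limma — the caller the full-scale analyses
used — is available as `backend = "limma"`, and any function returning
per-gene p-values can be plugged in.  The evaluation design, not the
caller, is what the module contributes.  Artificial two-class phenotypes
for unannotated data come from Ward/Euclidean hierarchical clustering of a
seeded sample subset, cut at the shallowest level where the two largest
clusters both exceed the size threshold (linkage and distance are our
documented choice; only "hierarchical clustering" is pinned).  Degenerate
confusion denominators score 0 with a warning; a zero-variance gene with
equal class means gets $p = 1$, with different means $p = 0$.

## Problem sizes and reproducibility

All shipped checks are desk-scale by design: the paired benchmark runs ten
seeds of the 2,000 × (50 → 200) problem at width 32 for 60 epochs; the
DGE benchmark runs 200 repetitions at sizes 12 and 60 on 100 genes;
bootstrap coverage uses 500 simulations of $n = B = 2000$.  Every random
draw flows through explicit seeds (generation, weight init, shuffling,
dropout, resampling), so every table in the package's output is exactly
reproducible from its configuration; the command-line front end writes
the resolved configuration and a log next to every artifact for the same
reason.

## Known limitations

* Absolute error levels on real compendia are out of reach of the
  synthetic benchmark by construction; only directional, paired claims are
  made.
* The half-network split exists for memory-parallel training at full
  scale; at desk scale it is exercised for correctness (partition,
  composition, ordering), not needed for speed.
* The optimizer is single-threaded R matrix code: correct and adequate at
  benchmark scale, not a GPU training stack.
* The ensemble enumeration is over user-supplied pools; no attempt is made
  to reconstruct any particular published pool composition.
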