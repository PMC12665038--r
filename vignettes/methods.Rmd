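---
title: "Predicting enhancer-enhancer interactions from paired DNA sequence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting enhancer-enhancer interactions from paired DNA sequence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etnet)
```

## The problem

Enhancers regulate transcription not only through contacts with promoters
but also through physical enhancer-enhancer interactions (EEIs) revealed by
chromatin-interaction assays such as ChIA-PET. Each assay loop reports two
genomic anchors; when enhancer annotations fall fully inside both anchors of
a loop, the enhancer pair is an experimentally supported interaction. This
package predicts such interactions from DNA sequence alone: given two
enhancer windows, it returns the probability that they physically interact,
and then asks *why* — which sub-regions carry the signal, whether the two
sides cooperate super-additively, and how single-nucleotide variants shift
the prediction.

## Dataset construction

Positive pairs come from loop/enhancer containment: for every loop, each
enhancer fully contained in the left anchor is paired with each enhancer
fully contained in the right anchor ("full overlap" is deliberately read as
containment, with no partial-overlap threshold). Duplicate unordered pairs
arising from multiple loops are collapsed; we treat `(E1, E2)` and
`(E2, E1)` as the same sample because a physical contact has no
orientation. Every enhancer window is standardized to a fixed width
(2 kb by default) centered on the enhancer midpoint; windows that overhang a
chromosome end are padded with `N` rather than shifted, so the midpoint
stays anchored. Coordinates are 0-based half-open (BED convention)
throughout, enhancers are treated as strandless, and soft-masked lowercase
bases are uppercased.

Three negative-sampling strategies are implemented:

* **random** — left-pool x right-pool combinations, excluding (as unordered
  pairs) anything in the positive set; the default, 1:1 with positives;
* **distance-matched** — the positive midpoint-distance distribution is cut
  into quantile bins (deciles by default) and same-chromosome candidates are
  drawn so per-bin counts are proportional to the positive counts, with
  deficits redistributed to neighbouring bins;
* **fixed-end** — one enhancer of a sampled positive pair is retained and
  the partner re-drawn, alternating sides uniformly at random.

Splits are stratified 8:1:1 train/validation/test by default, with 10-fold
partitioning and a dual-constraint enhancer-level split also available. The
enhancer-level split enforces (i) no enhancer id occurs in both train and
test and (ii) each enhancer occurs at most once inside test; test pairs are
admitted greedily over a seeded random order until the quota is met, and the
same exclusion is applied to every non-test partition. The constraints
define the split; the greedy order is our choice of algorithm.

## The classifier

Each side of a pair is one-hot encoded (`A`,`C`,`G`,`T` columns; `N` rows
all-zero), scanned by a single layer of 128 length-9 convolution kernels
(length-preserving, zero padded), rectified, and max-pooled by a factor of 4
so a 2000 bp window becomes 500 position vectors. The "9 x 9" kernel of the
published description is realized as a 1-D convolution of length 9 over the
4-channel input: a two-dimensional 9 x 9 kernel is dimensionally impossible
on an L x 4 input at the stated channel count. A single-layer MLP then maps
each pooled position vector into the token space.

Tokens from the two branches are concatenated along the position axis and
processed by a Transformer encoder: multi-head self-attention (8 heads;
total key/query dimension 1000, total value dimension 1024), a learned
relative-position bias added to the attention logits, a position-wise
feed-forward network, residual connections and layer normalization. Because
the published description names a relative positional encoding without
specifying its form, we use the additive learned-bias variant, indexed by
token offset. The number of encoder layers and the MLP width are not
publicly specified; the defaults here are one layer and 512 hidden units,
both configurable.

Two prediction heads close the model: head one mean-pools the left-branch
tokens, head two the right-branch tokens; each applies a small MLP, the two
logits are averaged, and a sigmoid yields the interaction probability. The
fusion of the two branches is not specified in the published description;
concatenation before the encoder (so attention mixes the sides) plus
side-specific pooled heads is our design, isolated in one place so
alternatives are drop-in. The convolution weights are shared between the
branches (siamese) by default and can be untied. Note an internal
inconsistency we chose not to resolve: the description of each pooled
position "representing 128 bp of genomic context" conflicts with the stated
2000 -> 500 reduction (4 bp per position); the 2000 -> 500 arithmetic is
treated as authoritative and 128 read as the channel count.

There is no deep-learning framework dependency: forward and backward passes
are written directly (R reference implementation plus a compiled
RcppArmadillo engine, cross-checked against each other and against finite
differences in the test suite). Training minimizes binary cross-entropy with
Adam (default learning rate 1e-5, 50 epochs, batch size 100), retains the
best-validation-AUC checkpoint, and optionally applies early stopping
(patience in epochs) and decoupled weight decay on weight matrices. The loss
function and checkpoint-selection criterion are unstated in the published
protocol; binary cross-entropy and validation AUC are our choices. All
randomness (initialization, batch order, dropout) derives from explicit
seeds, so runs are exactly reproducible.

### Transfer with a frozen encoder

Cross-context adaptation updates the convolution, the input MLP and the
prediction heads while every Transformer-encoder parameter stays bitwise
frozen (default: Adam, learning rate 1e-4, 30 epochs, early-stopping
patience 5). The intuition: convolution re-learns context-specific motif
detectors while the frozen encoder retains generic token-interaction
structure.

## Evaluation

`eei_metrics()` implements Accuracy, Precision, Recall, F1 (threshold 0.5,
the conventional default), AUC as the trapezoidal integral of the ROC curve
with tied scores contributing half credit (identical to the normalized
Mann-Whitney statistic), and AUPR as the step-wise integral of precision
over recall. `delong_paired()` compares two models scored on the same test
set: per-positive and per-negative U-statistic components with the 1/2 tie
kernel, 2 x 2 covariance matrices, the variance of the AUC difference, and
a two-sided normal p-value. The paired (correlated) form is used because
model comparisons share the test set. Both the metrics and the DeLong
variance are verified against brute-force enumeration oracles in the tests,
and the test suite checks the type-I error rate of the test by simulation.

## Interpretability

**Dinucleotide shuffling** is the reference/perturbation primitive: the
Eulerian-path construction (random last-edge trees with a connectivity
check) preserves the dinucleotide count multiset exactly — not
approximately — keeps the first and last base of each ACGT run fixed, and
holds `N` positions in place.

**Attribution** contrasts the input with dinucleotide-shuffled references:
for each reference, the contribution is `(input - reference)` times the
gradient of the output logit averaged over several points along the
reference-to-input path (8 by default), averaged over references (10 by
default). The path average matters in practice: a single-point gradient is
visibly noisier and localizes planted motifs in far fewer pairs. This keeps
the reference semantics of reference-based attribution while using only
quantities the model exposes exactly; the estimator sits behind one
function and can be swapped. Per-position importance is the contribution at
the observed base. A constant model attributes exactly zero everywhere,
which the tests assert.

**Greedy region search** splits both 2 kb windows into non-overlapping
regions (100 bp by default, a scale chosen to cover a few motif widths),
then iterates: every remaining region (both sides pooled) is shuffled
`n_shuffles` times *on top of the current perturbed sequence*, the region
whose perturbation best satisfies the objective is permanently fixed (its
first shuffled replicate is retained as the realized perturbation) and
removed from the pool. Deltas are `baseline - mean(replicates)`, the
baseline re-scored each iteration. Ties break to the leftmost region, left
side before right. On additive scorers the greedy order equals the
exhaustive optimum, which the tests verify against enumeration.

**Super-additivity.** For one focal region per side (top-1 greedy region by
default, whole-enhancer mode available), three drops are measured against
the unperturbed baseline: left-only, right-only, and joint (replicates
paired so that additive scorers cancel exactly). The synergy statistic is
`S = delta_joint - (delta_left + delta_right)`, classified super-additive
when `S > tau` with `tau = 0` (no tolerance is published; zero with
averaged replicates is the strictest choice). A scorer whose prediction
collapses only under joint perturbation — both regions must be hit — is the
canonical super-additive case: individual drops are zero, the joint drop is
the full gate height, so `S > 0`. Surveys over many pairs report the
super-additive fraction and the Pearson correlation between `S` and
pairwise sequence similarity, measured as cosine similarity of 4-mer count
vectors (the similarity metric behind the published correlation is
unspecified; 4-mer cosine is a standard alignment-free choice).

**Motifs.** High-importance windows (sliding window of the mean database
motif width; strict top-5%-quantile threshold, so flat tracks yield
nothing) are converted to position weight matrices from the positive
attribution mass, matched against a JASPAR/MEME database by maximum cosine
similarity over all full-overlap offsets (forward orientation by default,
reverse complement optional), retained at similarity >= 0.8, and written in
MEME minimal format with `nsites` carrying occurrence counts.

**Variant effects.** For each SNP, anchor1 is the 150 bp immediately
upstream of the locus plus the SNP base, standardized to the model window
with its genomic context; every partner enhancer is anchor2. The per-partner
effect is `p_alt - p_ref` and the per-SNP summary is the mean absolute
effect in percentage points (the published summary does not state whether
it averages signed or absolute changes; the absolute mean is reported and
labelled as such).

## The synthetic fixture

Because the real inputs (ChIA-PET loops, FANTOM5 enhancers, dbSUPER
annotations) require large downloads and full-scale training needs GPU
budgets, the package ships a generator whose ground truth exercises every
module. It emulates: a small genome (2 x 200 kb), 120 enhancers of
300-600 bp (the upper end near the 95th-percentile enhancer length of
541 bp), a planted complementary motif pair (widths 10 and 9), loops formed
with probability 0.9 between pairs whose sides carry the two motifs of the
pair and 0.05 otherwise, super-enhancer regions spanning adjacent enhancer
runs, and motif-breaking versus background variants.

Design choices worth recording, because they determine what the desk-scale
experiments can show:

* **Every same-chromosome enhancer pair inside the distance band is tested
  against the loop rule.** If only a subset were tested, never-tested pairs
  would enter the negative pool with motif content indistinguishable from
  positives, and interaction labels would no longer be recoverable from
  sequence — the defining property of the fixture.
* **Main-chromosome enhancers carry exactly one motif of the pair.** With
  independent motif assignment, randomly recombined negative pairs
  frequently carry a complete motif pair and the achievable AUC collapses;
  with exclusive assignment the Bayes ceiling under the 0.9/0.05 rule is
  about 0.93, which desk-scale training can approach.
* **A small background chromosome carries motif-free enhancers**, so
  cross-chromosome negative combinations are genuinely signal-free and the
  super-enhancer/variant paths see both signal and background.

What the fixture does *not* emulate: real enhancer sequence composition
(its background is uniform i.i.d.), distance-dependent contact decay,
cell-type-specific chromatin state, or motif degeneracy (motifs are planted
as exact consensus strings). Passing the fixture experiments therefore
demonstrates that the machinery is correct and that the architecture can
learn cross-side motif logic from sequence — not that real-data performance
figures are reproduced.

## Desk-scale experimental protocol

The tests and the acceptance script run a reduced configuration chosen to
fit a single CPU: 200 bp windows, 16 kernels, pool factor 8 (25 tokens per
side), 32-dimensional tokens, 2 heads, one encoder layer. Training uses
1,500 balanced pairs, Adam at learning rate 3e-3, dropout 0.1, decoupled
weight decay 2e-3, 150 epochs, best-validation checkpoint, with three
random-initialization probes of 20 epochs each and the best-probing
candidate trained in full (at this network size some initializations fall
into the constant-predictor basin and never escape; probing restarts are
the standard remedy). Weight decay is
essential at this scale: without it the network memorizes the small
training set (perfect training AUC, chance-level held-out AUC) instead of
learning the planted motif rule. The overfitting sanity check (200 pairs,
no dropout, no decay, 200 epochs) demonstrates capacity; the held-out
evaluation demonstrates generalization to within a few points of the
fixture's Bayes ceiling.

## Known limitations

* The desk-scale protocol validates mechanism, not real-data performance;
  full-scale runs require the published data sources and GPU budgets.
* Exact layer counts and widths of the original supplementary material are
  not public; where unspecified, defaults are documented above and
  configurable.
* The attribution estimator is a gradient-based realization of
  reference-based attribution, not a layer-rule backpropagation; for this
  bespoke architecture the latter has no published specification.
* Attention-weight downstream analyses (hub statistics) are out of scope;
  the attention matrices themselves are exposed via `attention_maps()`.
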