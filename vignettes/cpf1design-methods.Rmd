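---
title: "Predicting Cpf1 guide activity and specificity with small convolutional networks"
author: "cpf1design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting Cpf1 guide activity and specificity with small convolutional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpf1design)
```

## The problem

CRISPR-Cpf1 (Cas12a) cleaves DNA at sites composed of a thymidine-rich
TTTN protospacer-adjacent motif (PAM) followed by a 23-nt protospacer.
Guides vary enormously in cleavage efficiency, and near-matching loci
elsewhere in a genome can be cut too. A usable guide-design tool therefore
needs two predictors — one for on-target activity at perfectly matched
sites, one for off-target activity at mismatched sites — plus a pipeline
that turns both into a ranked guide library for a gene of interest.
`cpf1design` implements all three stages, with convolutional network
classifiers operating directly on one-hot encodings of the 27-nt target.

## Sequence encodings

A matched target is encoded by sliding a k-nucleotide window along the
sequence and marking the observed k-mer in a binary category-by-position
matrix. Position 1 (5'-most PAM base) is the leftmost column. For the
27-nt target the order-2 scheme gives the 16 x 26 matrix used by the
default on-target model; order-1 and order-3 give 4 x 27 and 64 x 25.
Column sums are exactly 1 by construction, and the encoding is injective
for fixed k. Category rows are ordered lexicographically (AA, AC, AG,
...); the ordering is a convention, not information — `permuteRows()`
exists precisely to verify that a trained model does not depend on it.

A guide/site pair is encoded by the 12 x 27 mismatch scheme: each of the
12 ordered substitutions (guide base g against site base t, g != t) owns a
row, each of the 27 positions a column. Matched positions give all-zero
columns, so the matrix total equals the Hamming distance of the pair —
the encoding carries the number, position and type of every mismatch and
nothing else. Degenerate bases are rejected rather than spread
fractionally across rows; windows containing N never reach the encoder
because the candidate scan skips them.

## The two classifiers

Both models are a single convolution + sum-pooling + dense stage:

* on-target: 16 x 26 input, 50 filters of 5 x 5 (valid, no padding)
  giving 12 x 22 feature maps, 2 x 2 sum pooling to 6 x 11, flatten 3300,
  dense 650, two-class softmax;
* off-target: 12 x 27 input, 35 filters of 7 x 7 giving 6 x 21 maps,
  2 x 2 sum pooling to 3 x 10 (the trailing odd column is dropped —
  pooling truncates, which is what makes the flatten size 35 x 3 x 10 =
  1050), flatten 1050, dense 300, softmax.

All shapes are derived from the `NetSpec` at run time and asserted at
build time, never hard-coded. Training is mini-batch gradient descent
with momentum on the two-class cross-entropy: base learning rate 0.005,
momentum 0.9, batch size 40. These optimizer settings are deliberate
defaults of the method, not tuned per dataset. The epoch count is the one
genuinely free training parameter; the package default is 100, and the
test and acceptance runs use 15 epochs, which on the synthetic data below
is well past the point where held-out AUC plateaus.

Design choices worth recording:

* **Output head.** The model is used exclusively as a binary classifier
  (AUC, F1), so the head is a 2-unit softmax trained with cross-entropy
  and the reported "activity score" is the positive-class probability.
  The output layer is zero-initialized, which has the convenient
  consequence that an untrained classifier scores every input exactly
  0.5 — a useful sanity anchor in tests.
* **Initialization.** Convolution filters are small seeded uniform draws;
  the first dense layer uses a fan-in/fan-out scaled uniform. All
  randomness (init, batch shuffling) flows from explicit integer seeds,
  and training is bit-reproducible given data order, seed and epochs.
* **Compiled core.** The batch forward/backward pass is implemented twice:
  a pure-R reference path (readable, the executable specification) and an
  RcppArmadillo core used by default. A test asserts both produce
  identical predictions and loss curves; this is also why the per-epoch
  shuffles are drawn up front rather than inside the loop.
* **Order-1 variant.** A 5 x 5 kernel cannot slide inside a 4-row input,
  so the order-1 spec uses a 4 x 1 convolution with 1 x 2 pooling,
  exposed through `buildOnTargetNet(order = 1)`.

## Evaluation harness

`labelByCutoffs()` sorts records by indel frequency (the percentage of
reads carrying insertions/deletions — the activity readout) and labels
the top and bottom fractions, dropping the middle; with 1251 records and
20%/20% this gives the canonical 250 + 250 = 500 training records and 751
held-out middle records (`splitExtremes()`). Floor rounding reproduces
that arithmetic exactly. Ties keep input order so labelling is stable.

`rocAuc()` computes AUC as the Mann-Whitney rank statistic with the
half-credit tie convention, which the suite verifies against an
exhaustive pairwise oracle to 1e-12. `externalCV()` implements k-fold
external cross-validation: every record is scored exactly once by a model
that never saw it. Folds are a seeded *stratified* random partition —
the description "randomly divided" leaves stratification open, and
stratifying is the choice that keeps both classes in every fold at small
n, without which fold AUCs are undefined. `cutoffGrid()` re-labels the
data over a grid of top/bottom cutoffs (default 9 x 5 = 45 combinations,
top 5-45%, bottom 60-80%) and cross-validates each labelling; infeasible
combinations (fractions summing past 1) are reported as NA with a reason
rather than silently dropped.

## Permutation importance and receptive-field projection

To ask *where* in the input a trained model looks, each of the flatten
neurons is permuted across samples (all other neurons fixed) and the mean
decrease in a performance criterion is recorded. Two criteria are
provided because the classical phrase "average decrease in node impurity
after permuting each predictor" mixes two notions: the default permutes
the classifier's own flatten activations and measures AUC decrease; the
alternative fits a seeded random-forest surrogate on the flatten
activations and reports Gini impurity decrease. Neither is claimed
canonical; both produce the same report shape. Permuting one flatten
column shifts the dense pre-activations by a rank-one update, which is
what makes scoring all 3300 neurons cheap.

Top-ranked neurons are projected back onto the input through
`flattenReceptiveField()`: with 2 x 2 pooling and a 5 x 5 kernel every
flatten neuron sees exactly a 6 x 6 input rectangle, and the projection
heatmap is the sum of indicator masks of the top-N fields (default
N = 50). The projection is purely structural — it depends on the
architecture, never on weights — and the suite verifies by exhaustive
perturbation that activations are invariant to anything outside the
computed field. When reading heatmaps in sequence coordinates, note that
an order-2 column j covers sequence positions j and j+1;
`positionColumns()` performs that mapping (seed positions 5-10 touch
columns 4-10).

## Guide library design

The pipeline mirrors standard Cpf1 screen design: scan both strands for
TTTN-N23 candidates (`findCandidateSites()`; overlapping sites all
reported, N-containing windows skipped, minus-strand sequences stored
PAM-first); remove candidates with extreme GC or a polyT run
(`applyFilters()`); score the survivors with the on-target model and keep
the top fraction (`rankAndRetain()`, default 10%, ceiling with a floor of
one); enumerate genomic near-matches of each retained guide
(`enumerateOffTargets()`); score each hit with the off-target model and
count predicted high-activity off-target sites (`specificityScore()`,
normalized score 1/(1 + n_high)); and rank lexicographically on (fewest
high-activity off-targets, highest activity, leftmost coordinate)
(`designLibrary()`).

Parameter conventions, chosen once and fixed:

* GC content is computed over the 23-nt protospacer only — the PAM is a
  fixed TTTN, so including it would merely shift every value — and the
  removal bounds are strict inequalities (< 30%, > 70%).
* "polyT" is a run of four or more consecutive T within the protospacer
  (a Pol III terminator signal); the run length is configurable because
  the notion has no universal definition. Only the protospacer is
  inspected, not flanking context.
* Off-target mismatches are counted over the protospacer with the PAM
  required to match TTTN exactly (position 4 free), the convention of
  fixed-PAM off-target scanners.
* Coordinates are reported on the forward strand; BED export is 0-based
  half-open with score = round(1000 x activity).

## Synthetic data with planted truth

No experimental dataset ships with the package, so every claim the test
suite makes is grounded in generators whose ground truth is known by
construction:

* `simulateOnTarget()` draws random TTTN + 23-nt targets with latent
  activity `plogis(b0 - bT * nT(5:10) + bGC * (GC - 0.5))` and indel
  frequency `100 * activity + N(0, sigma)` clipped to [0, 100]. Defaults
  b0 = 0, bT = 0.8, bGC = 1.0, sigma = 5. The thymine penalty is placed
  in the PAM-proximal seed region (positions 5-10) because that is the
  region whose composition governs Cpf1 activity; it gives the importance
  analysis a known answer.
* `simulateMismatch()` pairs a random guide with a copy carrying 1-6
  substitutions at protospacer positions 5-27 and multiplies a base
  activity by a per-mismatch region penalty: 0.1 in the seed (5-10), 0.5
  in the trunk (11-22), 0.9 in the promiscuous region (23-27) — the
  ordering seed < trunk < promiscuous is the defining property. The base
  activity is Uniform(0.5, 1): wide enough to be a nuisance variable the
  classifier cannot explain, narrow enough that a single seed mismatch
  (at most 0.1 x 100 = 10%) can never outscore a single promiscuous
  mismatch (at least 0.9 x 50 = 45%) in the noiseless limit, which is
  what makes the region-ordering tests strict.
* `simulateGenome()` plants guide copies with exact mismatch counts on
  random strands in uniform background, returning a truth table; at these
  scales a random 23-mer background match within a few mismatches is
  vanishingly improbable, so planted-count assertions are exact.

What these generators deliberately do not emulate: the PAM-discovery
design of real guide libraries, lentiviral readout noise, sequence
composition bias of real genomes, or bulges (indel-type mismatches).
Passing recovery tests therefore demonstrates that the machinery learns
the signal it is pointed at — not that the models reach any particular
accuracy on experimental data.

## Problem sizes and numerical conventions

The recovery runs use 2000 simulated records (so 800 labelled extremes)
with 5-fold CV for the on-target model, 2000 mismatch records with an
80/20 split for the off-target model, ten independent 1000-record
simulations for the importance concentration check (success = mean
heatmap mass on seed-region columns exceeds the overall mean; a one-sided
binomial test against chance), and a 50 kb genome with planted duplicates
for the pipeline check. These sizes are the package's reference
conditions: large enough that recovery is stable across seeds, small
enough to run routinely.

Numerical conventions: AUC ties get half credit; F1 calls scores at or
above the threshold positive and returns 0 when TP = 0; Spearman
correlation uses average ranks and is reported NA for constant vectors;
sum pooling truncates trailing odd rows/columns; retention uses ceiling
with a floor of one so tiny inputs still yield a candidate; all
file-format output is plain TSV/BED/FASTA.

## Known limitations

* The classifiers are deliberately small and CPU-trainable; there is no
  GPU path, no explicit regularization (the epoch budget is the only
  capacity control), and no two-stage architecture.
* Off-target enumeration is an exhaustive desk-scale scan (exact by
  construction, verified against a naive re-scan); genome-scale scanning
  would need an indexed search and is out of scope.
* Only substitution mismatches are modelled; bulges and PAM variants
  (e.g. TTTV-preferring enzymes) are not.
* Scores are class probabilities under the extreme-labelling scheme, not
  calibrated indel frequencies; the middle of the activity range is by
  design absent from training.
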