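---
title: "Inferring the affinity-fitness response of germinal-center B cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the affinity-fitness response of germinal-center B cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcfitness)
```

## The problem

Germinal centers (GCs) are the micro-evolutionary arenas in which B cells
mutate their receptor (BCR) and compete on binding affinity to an antigen.
B cells with higher affinity divide faster on average, but the *shape* of the
map from affinity to division rate — the affinity-fitness response function —
cannot be measured in vitro, because a cell's fitness is an emergent property
of the whole competing population. `gcfitness` implements a simulation-based
inference stack that recovers this function from collections of phylogenetic
trees, one tree per sequenced germinal center.

Affinity is expressed on a log10 scale relative to the naive antibody's
dissociation constant, \(x = -\log_{10}(K_D / K_D^N)\) with \(K_D^N = 40\)
nM, so the naive sequence has affinity 0 and larger \(x\) means stronger
binding. The response function is a four-parameter sigmoid

\[
\lambda(x) \;=\; \frac{y_c}{1 + e^{-x_c (x - x_h)}} + y_h ,
\]

with steepness `xscale` (\(x_c\)), midpoint `xshift` (\(x_h\)), scale
`yscale` (\(y_c\), births/day) and lower asymptote `yshift` (\(y_h\)). The
upper asymptote \(y_c + y_h\) is a hypothesized fitness ceiling; the lower
asymptote is the residual fitness of cells with effectively non-binding
receptors.

## The forward model

`run_gc_simulation()` is a cell-based birth-death-mutation process:

* Each living cell carries a nucleotide sequence; its affinity is the sum of
  per-substitution effects from an additive, DMS-style map (no epistasis);
  its intrinsic birth rate is \(\lambda(x)\); its death rate is a constant
  (default 0.2/day) or a much larger "purging" rate (10/day) if the sequence
  contains an in-frame stop codon; its mutation rate is a 5-mer
  context-dependent somatic hypermutation (SHM) model summed over sites and
  scaled by a global multiplier.
* A carrying capacity \(N_0\) is enforced by the logistic factor
  \(m = (\sum_i \mu_i / \sum_i \lambda_i)^{N/N_0}\), applied multiplicatively
  to all birth rates (the default "birth" method). At \(N = N_0\) the process
  is exactly critical, \(\sum_i m\lambda_i = \sum_i \mu_i\); below capacity
  growth is supercritical, above it \(m\) collapses. Two alternatives are
  implemented: dividing death rates by \(m\) ("death"), and a "hard" cap that
  kills one uniformly random cell whenever a birth overshoots \(N_0\).
* Waiting times: every cell/event-type pair has an exponential waiting time
  whose rate is the corresponding response value; the minimal time fires. We
  implement the distributionally exact shortcut — one exponential with the
  summed rate, then a rate-proportional choice of the firing pair — in
  compiled code with Fenwick-tree selection, using R's RNG so runs are
  reproducible under `set.seed()`. The alternative, deterministic reading of
  "waiting time from the reciprocal of the rate" would make all cells fire in
  lockstep and is rejected.
* The simulation starts from a single naive cell that undergoes an
  instantaneous binary expansion to the initial population (non-powers of two
  truncate the last level, filling in creation order), runs to a fixed
  sampling time, and samples cells uniformly without replacement. Runs that
  go extinct or end with fewer than 10 living cells are discarded and
  retried.

Degenerate branches are excluded by construction: the functional death rate
must be positive (otherwise \(m = 0\) stops all births), and `yscale` must be
positive. The intrinsic sums in \(m\) always use unmodulated \(\lambda_i\).

## Synthetic study fixtures

The real inputs of this kind of study — a deep mutational scan of the naive
antibody and a published 5-mer SHM model — are replaced by first-class
synthetic generators:

* `synthetic_dms_map()` draws each single-nucleotide-variant effect from a
  two-component mixture: deleterious with probability 0.75 (exponential,
  scale 1.8 affinity units) and beneficial otherwise (exponential, scale
  0.7). Random mutants therefore have negative mean affinity while selection
  can still find beneficial trajectories reaching affinities of +2 to +5.
* `synthetic_shm_model()` draws log-normal 5-mer mutabilities with a 5%
  hotspot subset boosted 8-fold, flat-Dirichlet substitution triples, and a
  mean per-site rate of 4e-4 per day. That rate was calibrated once so that
  central data-mimic simulations (20 days, multiplier 0.5) accumulate on the
  order of 1% nucleotide divergence, matching the low-SHM regime of
  extracted-GC sequencing data; selection amplifies accumulation, which is
  why the neutral expectation alone would undershoot. The two terminal
  positions on each side have no full 5-mer context and get zero mutability.

What these fixtures do *not* emulate: epistasis in the sequence-affinity map,
amino-acid-level structure in the DMS, strand asymmetries and motif structure
of real SHM, expression effects, and clonal competition between families.
Passing tests therefore demonstrate that the inference machinery recovers the
response function *under the model*, not that the model captures every
feature of real germinal centers.

## From simulation to data-like trees

Real pipelines infer trees from sampled sequences (one leaf per unique
sequence, naive outgroup, maximum-likelihood branch lengths in
substitutions/site). `true_tree_fallback()` produces the analogous object
from the simulation truth without any external program: it prunes to sampled
cells, collapses duplicate sequences to one representative tip, removes
unobservable unifurcations (mutation events), collapses the zero-length
initial-expansion edges and re-binarizes the resulting root polytomy into a
deterministic caterpillar, converts branch lengths from days to expected
substitutions per site using the parent sequence's SHM rate, and annotates
every node with the affinity of its (known) sequence. An optional
IQ-TREE-style wrapper (`infer_tree_external()`) runs the same pipeline
through an external maximum-likelihood program when one is installed; all
package tests and analyses use the fallback.

A subtlety worth recording: internal node times are the *event* times (when
a cell divided), not cell creation times. Using creation times would give
the two products of every division identical times and affinities, creating
exact encoding ties throughout; with event times, ties have probability
zero, which is exactly the regime the encoding's tiebreaker design assumes.

## Tree encoding

`encode_tree()` implements the compact bijective ladderized vector (CBLV)
encoding augmented with affinities. Ladderization orders the children of
every node by node time (descending — longer branches to the left), then by
the time of the immediate ancestral node, then by affinity; a remaining
exact tie raises an error rather than silently producing an ambiguous
encoding. The tree is first scaled to mean unit leaf depth. An inorder
traversal writes each leaf's distance to the most recently visited internal
node into row 1 and each internal node's root distance into row 2, with the
corresponding affinities in rows 3-4; each row pair advances its own column
counter and the matrix is zero-padded to width 200.

Standardization (`fit_standardizer()`) maps three variable groups — branch
lengths (rows 1-2), affinities (rows 3-4), and each non-sigmoid conditioning
scalar — to mean 0 / variance 1 over the training set. Two design choices
here were genuinely open: padding zeros are excluded from the statistics
(otherwise the pad width would dominate them) and are re-inserted *after*
standardization so padding stays exactly zero; and the scaler is persisted
and reapplied unchanged at prediction time.

## The inference network

The network is built from scratch in R (matrix algebra via BLAS): three 1-D
convolutions (25, 25, 40 filters, kernel 4, no padding), max-pooling (size
2, stride 2) after the second, global average pooling, then dense layers
48/32/16/8 down to the head, ELU activations throughout, and a linear
output followed by a clip to a box wider than the sampling box
(`xscale` [0.001, 3.5], `xshift` [-1.5, 5], `yscale` [0.1, 65], `yshift`
[0, 10]). The three non-sigmoid scalars (carrying capacity, initial
population, death rate) are standardized and concatenated onto the first
dense layer's input, which makes that layer 43x48 + 48 = 2112 parameters
(a variant without the concatenation would have 41x48 = 1968; the layer
counts quoted elsewhere for this architecture — 2525 for the second
convolution, 4040 for the third, 1568 for the 48-to-32 dense layer — are
unaffected by where the scalars enter). The sigmoid head has 4 outputs;
a per-bin head predicting the response value in 11 uniform affinity bins
over [-2.5, 3] (0.5-unit resolution) is available as a cross-check.

Training minimizes the **curve difference loss**: the area between the true
and predicted response curves divided by the area under the true curve, on
the affinity domain [-2.5, 3] (trapezoid rule, 0.1 grid). Parameter-space
error would be the wrong objective because parameter changes can compensate
each other while leaving the curve essentially unchanged. Gradients flow
analytically through the sigmoid curve into the network; the clip passes
gradients unchanged inside the box and for updates that move an out-of-box
output back toward it (a plain zero gradient outside the box can permanently
kill an output unit). The output bias starts at the sampling-box center so
initial predictions are inside the clip box. The optimizer is Adam
(learning rate 0.01, batch 32, 35 epochs) with an exponential moving
average of the weights (momentum 0.99) used at prediction time; 20% of the
sample is held out for testing and 10% of the remainder for validation.

Three numerical choices keep this optimizer stable on a small sample:
weights are initialized variance-preserving (uniform with variance equal to
the reciprocal fan-in — fan-average scaling amplifies activations roughly
4x per convolution here and saturates the downstream ELUs); per-batch
gradients are clipped to global norm 1 (the per-sample loss scale varies by
two orders of magnitude with the area under the true curve, and occasional
huge batches otherwise throw the dense stack into saturation); and the
final weights are those of the best-validation epoch within the 35-epoch
run — the 35-epoch budget corresponds to the point at which validation
performance starts to degrade at full scale, and at desk-scale sample sizes
that point arrives earlier, after which the network slowly degenerates
toward a constant (bias-only) predictor.

## Two-step inference and the medoid curve

Non-sigmoid parameters are not predicted by the network; they are supplied
to it. `scan_nonsigmoid()` therefore runs conditional inference over a grid
of carrying capacity (500, 750, 1000, 2000) x initial population (8, 32,
128) x death rate (0.05, 0.1, 0.2, 0.4); for each of the 48 combinations a
data-mimic sample (`make_data_mimic()`, 120 GCs sharing one parameter set,
60-95 sampled cells each) is generated from the medoid of the per-GC
predictions, and `select_central_mimic()` picks the combination whose
summary statistics most closely match the target sample.

Summary statistics (`compute_summary_stats()`) are this package's own
design choice and cover the axes the model controls: per-GC leaf counts, per-sequence mutation counts,
per-cell affinities, sequence abundance multiplicities, pooled branch
lengths, mean tree depths, and the per-GC basal lineage count (lineages
branching at the root, a direct readout of how many founder lineages the
sample represents and hence of the initial population). The matching metric
is the mean over components of the 1-D earth-mover (Wasserstein-1) distance
between empirical distributions, each scaled by the pooled standard
deviation so that components with very different ranges are commensurable.
When candidate mimics are compared during selection, the same RNG seed can
be set before each candidate's simulation (`crn_seed`): with common random
numbers the mimic sampling noise largely cancels out of the comparison,
which matters at desk scale where between-candidate margins are a few
hundredths while a 40-GC mimic's distance fluctuates by about as much.

Two caveats the closed-loop experiments expose honestly: after 20 days of
selective sweeps, samples carry little memory of the founder population, so
nearby non-sigmoid combinations (capacity differing by 1.5-2x, initial
population by 4x) are statistically indistinguishable at desk scale; and a
large-capacity/small-founder combination can partially compensate for the
truth, which is why the packaged closed-loop checks use a widely spaced
sub-grid of the full scan.

`medoid_curve()` picks the central prediction: pairwise curve distances are
the curve-difference loss symmetrized by normalizing the area between two
curves by the mean of their two areas (the raw loss is asymmetric in which
curve is "true"; the symmetrized form reduces to it when areas agree and
makes the medoid of flat curves at heights 1, 2, 10 the middle one, which
the asymmetric variants do not). The medoid minimizes the sum of squared
distances to all other curves, ties broken by lowest index; pointwise 68%
and 95% quantile bands accompany it.

## Desk-scale study sizes

All empirical checks in the test suite and the acceptance script run on one
CPU with synthetic fixtures, at sizes chosen as the package's desk-scale
study conditions: 60-nt sequences; a training sample of about 5,000 trees
(full-scale studies of this kind train on tens of thousands of trees with
300+ nt sequences); evaluation samples of about
100 GCs; closed-loop combination selection over a 2 x 2 x 2 subgrid of the
full scan with 40 GCs per candidate mimic under common random numbers. The
desk-scale encoding width is 64 rather than the full-scale default of 200:
these trees have at most ~40 nodes, and with width 200 the global average
pool mostly averages padding, which dilutes the input signal and worsens
the attenuation of the predictions toward the prior center. At this scale single-GC curve losses are comparable
to what full-scale training reaches on diverse-parameter samples
(about 0.7), and the meaningful recovery
property is relative: the medoid of the per-GC predictions should be closer
to the truth than the typical single-GC prediction, and the closed loop
should select the true non-sigmoid combination. The latter is only
partially achieved: carrying capacity remains weakly identified, because a
larger capacity paired with the (attenuated) sigmoid inferred under that
conditioning reproduces the target's summary statistics nearly as well as
the true capacity does — exactly the kind of compensation one expects when
the effective capacity a cell experiences is not directly observable, and
which full-scale data richness is needed to break.

## Known limitations

* The sigmoid family cannot represent non-monotone or asymmetric responses;
  the per-bin head is still trained on sigmoid simulations.
* Dark-zone/light-zone compartments, clonal bursts, biased sampling,
  multi-clonal and multi-GC competition, and affinity-dependent SHM rates
  are out of scope.
* The additive affinity map is an extrapolation outside the range where
  additivity is typically validated (about -1 to 2).
* At desk scale, trees carry few mutations; per-GC predictions are strongly
  attenuated toward the prior center, so absolute single-GC accuracy is
  poor — only ensemble-level quantities (medoid curve, summary-statistic
  matching) are informative.
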