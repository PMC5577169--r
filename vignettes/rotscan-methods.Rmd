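---
title: "Modelling mental-rotation scanpaths with a block-structured discriminative HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mental-rotation scanpaths with a block-structured discriminative HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotscan)
```

## The problem

In a two-figure mental-rotation task, an observer compares two Shepard-Metzler
block figures and decides whether they are identical or mirrored. The task can
be performed with either of two instructed strategies: keep the left figure
fixed and mentally rotate the right one (LFRR), or the reverse (RFLR).
`rotscan` asks two questions of the recorded eye movements:

1. **Classification** -- can the strategy of a single trial be read off its
   scanpath?
2. **Segmentation** -- can the scanpath be decomposed into interpretable
   cognitive processing states (encoding-and-searching, comparison,
   searching-on-one-side), and how do the two strategies differ in those
   states?

Both are answered with one model: a hidden Markov model whose hidden states
are partitioned into two class-specific blocks, trained generatively and then
refined discriminatively.

## From fixations to observations

Each trial is a sequence of fixations. Four areas of interest (AOIs)
discretize gaze position: the upper and lower arm of the left figure (L1, L2)
and of the right figure (R1, R2); the numbering 1 = L1, 2 = L2, 3 = R1,
4 = R2 is fixed throughout. Every fixation contributes an observation vector
$X_t$ with four components:

* $\log$ fixation duration (ms), modelled as Gaussian per state;
* $\log$ outgoing saccade length (px), Gaussian per state, where saccade
  length is the Euclidean distance between consecutive retained fixation
  coordinates;
* the AOI category (4-way categorical);
* the outgoing saccade direction (SD), a 4-way categorical relation between
  source and target AOI: SD-1 within the same AOI, SD-2 to the other AOI of
  the same figure, SD-3 to the corresponding AOI of the other figure
  (L1-R1, L2-R2), SD-4 to the transformed AOI of the other figure
  (L1-R2, L2-R1).

The last fixation of a trial has no outgoing saccade; its saccade-length and
saccade-direction likelihood factors are omitted, never imputed. Fixations
landing outside every AOI are dropped by default (`outside = "drop"`); a
nearest-region snap within a pixel threshold is available as a configurable
alternative for noisier calibrations. Region containment is edge-inclusive
for rectangles, and layouts must be strictly disjoint, so assignment is
unambiguous.

The "saccade between the current and the next fixation" can be measured in
several ways when only fixation centroids are available; `rotscan` uses
centroid-to-centroid distance, the only definition computable without raw
gaze samples.

## The model

Let $n_1$ and $n_2$ hidden states form the LFRR and RFLR blocks of one joint
HMM with parameters $\lambda = (\pi, A, \theta)$:

$$P(X_{1..T} \mid \lambda) = \sum_{\varphi} \pi_{s_1} P(X_1 \mid s_1)
  \prod_{t=2}^{T} A_{s_{t-1}, s_t} \, P(X_t \mid s_t),$$

where the sum runs over state paths $\varphi$. Two structural constraints
encode the two-strategy design:

* $A$ is block-diagonal: a path never crosses between class blocks, so each
  path "is" a class;
* $\pi$ spans both blocks and sums to one, so the mass a block receives under
  $\pi$ is the class prior. (The published initial probabilities sum to 99%
  over the six states; `default_params()` renormalizes them to exactly 1.)

Emission components are conditionally independent given the state -- the
naive factorization matching the separate per-state marginals that the model
is meant to recover. Classification is Bayes inversion,

$$P(C \mid X, \lambda) = \frac{\sum_{\varphi \in \text{block } C} \cdots}
 {\sum_{\varphi} \cdots},$$

computed from the per-block terminal forward masses; exact ties (possible
only for exactly symmetric blocks) classify as LFRR, and Viterbi ties break
toward the lowest state index. Both rules are deterministic and documented
rather than random.

## Training

**Generative stage.** With labelled training data, block membership is
observed: Baum-Welch responsibilities for a labelled sequence are confined to
its class block, which is equivalent to per-class EM with a shared
initial-distribution normalization (so $\pi$ keeps encoding the class prior).
The maximized objective is the labelled joint log-likelihood
$\sum_n \log P(X_n, C_n \mid \lambda)$, which is non-decreasing across
iterations; the test suite asserts this monotonicity. Initialization is a
seeded perturbation of global moment estimates -- no clustering -- with
multiple restarts (10 by default): each restart is screened with a short EM
run, and the best is run to convergence. A state that receives essentially no
responsibility is re-seeded from the global moments with a warning.

**Discriminative stage.** The refinement maximizes the conditional
log-likelihood $\sum_n \log P(C_n \mid X_n, \lambda)$. The update rule is
gradient ascent in an unconstrained reparameterization -- softmax logits for
$\pi$, transition rows and the categorical emissions, log scale for the
Gaussian sigmas -- so every iterate is a valid parameter set. The gradient
has the classic discriminative-HMM form: expected sufficient statistics under
the labelled block minus their posterior-weighted expectation under the full
model, both obtained from the same forward-backward pass that EM uses. Steps
that would decrease the objective are rejected with learning-rate halving, so
the conditional likelihood is non-decreasing across accepted steps; the
analytic gradient is verified against central finite differences in the test
suite. Fixing the objective and its guarantees, rather than a specific
published update formula, is a deliberate contract: several "discriminative
EM" variants exist, and any monotone ascent on this objective satisfies the
role the refinement plays here.

Forward, backward and Viterbi recursions run in log space (no underflow for
sequences far longer than occur in practice) and are implemented in C++
(`src/hmm.cpp`), with emission log-densities computed vectorized in R, the
same division of labour used by established HMM packages. All categorical
probabilities are floored at $10^{-12}$ to keep log-space finite.

## Baselines and evaluation

The comparison classifiers operate on five per-trial aggregates: number of
fixations, mean and SD of fixation duration (ms), mean and SD of saccade
length (px), computed on the untransformed scales (SDs define to 0 when there
are too few events). Logistic regression is unpenalized `stats::glm`;
the SVM is `e1071::svm` with an RBF kernel and cost 1 -- the period-typical
defaults, exposed as arguments because the comparison design does not pin
them down. Both standardize features internally, which makes their
predictions invariant to affine rescaling of any input feature (asserted in
the tests). Whether features should be standardized at all is not specified
in the comparison design; standardization is the safer default for the SVM
and harmless for logistic regression.

Evaluation utilities: stratified seeded k-fold partitions (fold offsets
rotate across strata so totals stay balanced); repeated cross-validation with
derived per-repeat seeds; confusion matrices with row-wise, column-wise and
total accuracies reported to 0.1%; Wilcoxon rank-sum (exact for small
tie-free samples, normal approximation with tie correction otherwise);
classical one-way ANOVA; and the OLS angle-effect slope in ms/degree. These
all delegate to the corresponding base-R routines -- they are standard
statistics, not contributions.

**Choosing the number of hidden states.** The accuracy curve over the
candidate grid $\{2\text{-}2, \dots, 5\text{-}5\}$ typically rises and then
levels off. "Levels off" is operationalized explicitly: the smallest
candidate (fewest total states, then most balanced) whose cross-validated
mean accuracy is within a margin -- one accuracy point by default -- of the
grid maximum. The margin makes the rule monotone: enlarging it can only
select a smaller model. A complementary majority-vote selection compares two
candidates on per-participant accuracies with a paired Wilcoxon signed-rank
test and keeps the simpler model unless the evidence against it is
significant at 0.05.

Whether repeated-CV accuracies should enter a classifier comparison pooled by
fold or by repeat is left configurable (`oneway_anova` takes whatever
grouping the caller supplies); the package takes no position.

## The synthetic-data generator

Real recordings for this design are not redistributable, so the generator is
a first-class module: it emits labelled corpora whose per-state statistics
default to the published model estimates -- initial probabilities
(9%, 5%, 35% / 15%, 4%, 31%, renormalized), per-state duration and
saccade-length medians, AOI-occupancy and saccade-direction rows, and the
four published leave-probabilities of the `e` and `s` states. Transition mass
not pinned down by those four values follows a documented equal-split
convention, with the comparison-state rows uniform over their block;
everything is overridable in `generator_config()`.

Choices the published estimates do not determine:

* **Log-scale spread.** The dispersion notation for durations and lengths
  does not identify the log-scale sigma; printed values are treated as
  back-transformed medians with a configurable log-sigma defaulting to 0.5 --
  a typical within-state spread for fixation durations (roughly +/-65% at one
  sigma).
* **Sequence lengths.** Negative-binomial with mean 20 and dispersion 5,
  truncated at 1, reflecting that small angular disparities produce trials
  with only one or two fixations.
* **Corpus layout.** 840 sequences per class (15 subjects x 2 sessions x 56
  trials), subject ids round-robin, stratified 80/20 split: 1344 training,
  336 test sequences.
* **Zero cells.** Published zero entries in the SD rows are floored at
  $10^{-3}$ before renormalization; exact zeros would make recovery of the
  floored entries trivial.
* **Reaction times.** $RT = \text{intercept} + \text{slope} \cdot
  \text{angle} + \varepsilon$, truncated at the 8000 ms response deadline,
  with the published LFRR slope as default.

**Two AOI regimes.** The saccade-direction code determines the target AOI
given the source, so a geometrically self-consistent scanpath fixes the whole
AOI chain once the SD stream is drawn (`aoi_mode = "chained"`). That chain,
however, carries strong AOI serial dependence that the model's conditionally
independent AOI emission does not describe; fitting such data, the maximum
likelihood solution dedicates states to figure persistence instead of the
intended processing states -- a correctly implemented estimator *cannot*
recover the generating parameters from chained data, a mismatch we measured
directly. The default regime (`aoi_mode = "independent"`) therefore draws
every fixation's AOI from its state's occupancy row, exactly matching the
model's emission assumptions, which is the appropriate regime for validating
estimators. Chained mode remains the right regime -- and is required -- when
emitting raw coordinate tables, where the property under test is that
re-extracting the table reproduces the generated AOI and SD streams exactly.

What the generator does **not** emulate: real AOI serial dependence beyond
the chained construction, between-subject heterogeneity (all sequences share
one parameter set), angle-dependent sequence lengths or difficulty, response
errors, calibration drift, blinks, and raw-sample-level noise. Passing
recovery tests therefore demonstrates correctness of the estimator under the
model's own assumptions, not robustness to the ways real eye-tracking data
violate them.

## Numerical behaviour of the estimator

Under the default log-sigma, the comparison and searching-on-one-side states
have nearly identical duration medians (170 vs 179 ms, about 0.1 sigma on the
log scale), so their separation rests almost entirely on the
saccade-direction rows. The labelled likelihood surface consequently has a
near-flat ridge along which responsibility for ambiguous events shifts
between those two states: tightly converged fits from different starts reach
indistinguishable log-likelihoods while their categorical rows and initial
probabilities scatter by a few percentage points. Three consequences are
reflected in the package defaults and tests:

* EM convergence uses a tight relative tolerance ($10^{-8}$) and a generous
  iteration cap, because loose stopping rules leave fits partway along the
  ridge;
* recovery tests in the unit suite use tolerances with head-room above the
  measured ridge scatter (0.10 for categorical entries, 0.06 for initial
  probabilities at 500 sequences per class), so they guard against estimator
  regressions rather than tripping on sampling noise;
* the acceptance check of the three headline quantities (SD-1 of the
  encoding state, SD-3 of the comparison state, the initial probability of
  the searching state) uses the four-point tolerance appropriate for one
  seeded replicate at 1000 sequences per class.

States of a fitted model are identified only up to permutation within their
block; all comparisons first align states with `match_states()`, which
minimizes the summed $L_1$ distance between saccade-direction rows (with a
small duration-mean term to break near-ties).

## Problem sizes used by the test suite

The suite exercises every stage on corpora of 100-1000 sequences per class:
full-scale (840/class) corpora for design arithmetic and the baseline
comparison, 1000/class for the headline recovery check, 500/class for
estimator-consistency properties, and 100-120/class with reduced restart and
iteration settings for the cross-validated ordering and state-selection
experiments -- sizes chosen so each experiment still shows the behaviour it
is about while the whole suite stays conveniently runnable.

## Known limitations

* The discriminative refinement optimizes the conditional likelihood only;
  run to extremes it will trade generative fidelity for separation, as any
  conditional-likelihood method does. The default settings refine rather
  than re-train.
* With both baselines near chance on synthetic corpora generated from the
  published per-state parameters, the SVM-versus-logistic ranking is
  effectively a coin flip; the published large gap between them evidently
  reflects real-data structure that those per-state parameters alone do not
  encode.
* Per-subject heterogeneity is not modelled; per-participant fits are
  supported by passing each participant's sequences separately (as
  `majority_vote_selection()` expects), not by hierarchical pooling.
* The pipeline assumes fixations have already been detected; velocity- or
  dispersion-based event detection from raw gaze samples is out of scope.
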