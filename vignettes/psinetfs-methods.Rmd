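---
title: "Phase-synchronization networks and multi-objective feature selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-synchronization networks and multi-objective feature selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`psinetfs` implements a complete workflow for discriminating two groups of
subjects from multichannel electrophysiological recordings through the
topology of their functional brain networks:

1. **Preprocessing** — epoch segmentation and zero-phase FIR decomposition
   into the five canonical bands (δ 1–4, θ 4–8, α 8–12, β 12–30,
   γ 30–60 Hz).
2. **Connectivity** — instantaneous phases via the discrete analytic
   signal; the phase synchronization index (PSI) between every channel
   pair; binarization at a threshold τ.
3. **Graph features** — fourteen topological summaries per binary network,
   in a fixed order (DG, NB, CC, SPL, EB, GE, LE, TT, AC, SW, MD, MZ, HC,
   GIC).
4. **Feature selection** — a wrapper search over feature subsets by
   multi-objective particle swarm optimization with Gaussian differential
   mutation (MOPSO-GDM), scored by the cross-validated error of three
   classifier families plus a Fisher-style distance measure, against
   NSGA-II, plain MOPSO and MOPSO-M baselines.
5. **Benchmarks and synthetic data** — the ZDT suite with analytic Pareto
   fronts for optimizer validation, and generators for coupled multichannel
   signals and planted-feature tables so that every stage is testable
   without clinical data.

# Signal model and connectivity

## Analytic signal and PSI

For a real channel $x(t)$, the discrete analytic signal is built in the
frequency domain (positive frequencies doubled, negative zeroed), giving
the instantaneous amplitude $A(t)$ and phase $\varphi(t) = \mathrm{atan2}
(\tilde x, x) \in (-\pi, \pi]$, where $\tilde x$ is the Hilbert transform.
The phase synchronization index of two channels with 1:1 locking is

$$\mathrm{PSI} = \left| \left\langle e^{i(\varphi_x(t) - \varphi_y(t))}
\right\rangle_t \right| \in [0, 1],$$

1 for perfect phase locking and 0 for no coupling. PSI is invariant to
positive amplitude scaling; it does **not** discard zero-lag coupling, so a
phase-lag index (PLI) variant, $|\langle \mathrm{sign}\,
\sin\Delta\varphi\rangle|$, which is insensitive to volume conduction, is
available behind `method = "pli"`. The package takes no position on which
variant suits a given montage; PSI is the default because it is the
measure the rest of the workflow is calibrated on.

Phases are extracted only after band-pass filtering (broadband phases are
not physically meaningful) and over the whole epoch, with no sub-windowing.
A constant channel is a documented degenerate case: amplitude 0, phase 0.

## Thresholding

The network realizes an edge where PSI strictly exceeds τ (default 0.3);
the diagonal is zero and self-loops are excluded. Edge count is therefore
monotone non-increasing in τ. Group-level matrices for visualization are
means of per-epoch PSI matrices; per-epoch networks feed feature
extraction, which is what yields one statistical sample per epoch.

## FIR design and its edge effects

Filters are Hamming windowed-sinc band-passes with
`taps = max(3 fs / f_low rounded to odd, 257)`, applied forward–backward
(zero phase) over an odd-reflection pad of one filter length. Output length
equals input length and filtering is linear to numerical precision. One
consequence worth knowing: any padding scheme leaves a small edge
transient. A 10 Hz sinusoid pushed through the δ filter retains ~2% of its
power in the outermost filter-length of samples even though the frequency
response at 10 Hz is below $10^{-10}$; the steady-state interior is clean.
Ten-second epochs are long relative to the filter, so the transient has a
negligible effect on epoch-level PSI.

# The fourteen graph features

Node- and edge-level metrics are reduced to a single scalar by the
unweighted arithmetic mean, because each feature is used as one classifier
input. Where textbook variants exist, the package fixes: *raw* (not
normalized) betweenness with fractional counting of tied shortest paths;
characteristic path length over *reachable ordered pairs*; efficiencies
with the $1/\infty = 0$ convention, so disconnected graphs produce finite
features. Small-worldness and the motif z-score are normalized against a
degree-preserving (Maslov–Sneppen) rewired ensemble — default 100
surrogates, 10 rewiring attempts per edge, seeded, shared between the two
metrics within one `feature_vector()` call. Modularity is the Q of the
deterministic greedy agglomerative partition. The hierarchy coefficient is
the least-squares exponent of $C(k) \sim k^{-\beta}$ over nodes with degree
≥ 2 and positive clustering. Graph index complexity normalizes the
adjacency spectral radius between the path-graph and complete-graph
extremes, $\mathrm{GIC} = 4c(1-c)$; $c$ is clamped to $[0,1]$ so graphs
sparser than a path return 0.

Every degenerate case (edgeless graph, zero degree variance, zero ensemble
variance, fewer than two qualifying degrees) returns 0 with a warning
rather than NaN, keeping feature tables classifier-ready. These choices are
deliberate stand-ins where a metric admits several conventions; each is
isolated in its own function so a different convention can be swapped in.

# Objectives and the wrapper search

A candidate subset is a binary mask over the (band, feature) columns,
band-major (δ block first, γ last; 14 bits for a single band, 70 for all
five). Its objective vector, all minimized, is:

* $F_1, F_2, F_3$ — stratified 10-fold CV error of an RBF-kernel SVM
  ($C = 1$, $\gamma = 1/(D \cdot \mathrm{var})$), Gaussian naive Bayes, and
  linear discriminant analysis. One seeded fold assignment is shared by all
  three so errors are comparable; features are z-scored by training-fold
  statistics only. Leave-one-out is available for re-validation.
* $F_4$ — a Fisher-style separability measure:
  $D_b$ = mean distance of each sample to its *nearest* other-class sample,
  $D_w$ = mean distance to its *farthest* same-class sample,
  $F_4 = 1/(1 + e^{-(D_w - D_b)})$, Euclidean on the masked columns.
  (The surrounding prose in the source literature swaps "nearest" and
  "farthest" relative to its own equations; the equations as printed are
  implemented.) The pipeline min–max normalizes the whole table once before
  optimization; `distance_objective()` itself works on the columns as
  given, which keeps it verifiable against hand computations.

An empty mask receives the penalty vector $(1,1,1,1)$. Objective vectors
are memoized by mask, and the evaluator counts total and distinct-mask
evaluations — the search revisits masks heavily once it converges, and the
distinct count is itself a diversity diagnostic.

The naive Bayes and discriminant engines are closed-form implementations
vectorized for the inner loop (the wrapper search performs thousands of CV
fits); their predictions are cross-checked against `e1071::naiveBayes` and
`MASS::lda` in the test suite. The SVM is `e1071::svm`.

# MOPSO-GDM and baselines

Particles are real vectors in $[0,1]^D$ decoded by strict thresholding at
0.5. The velocity update uses inertia $w = 0.7$ and learning factors
$c_1 = c_2 = 2$; velocities are clamped to $\pm 0.5$ per dimension,
positions to $[0,1]$, velocities start at 0 and positions uniform. Leaders
are drawn from a bounded external archive (capacity 100, crowding-distance
maintenance) by binary tournament on crowding. With four objectives many
position pairs are incomparable, so a particle's personal best is replaced
on domination and with probability 0.5 on incomparability.

With probability 0.1 per particle per iteration, Gaussian differential
mutation perturbs the position:

$$\Delta L = p_1 f_1 (L^\* - L) + p_2 f_2 (L_{rand} - L), \qquad
p_1 = p_2 = 0.5,\; f_1, f_2 \sim \mathcal N(0, 1)$$

with $L^\*$ the personal best and $L_{rand}$ a random peer; $f_1, f_2$ are
drawn once per mutated particle (they are scalar coefficients, not
per-dimension noise). The defining update rule, read literally, *replaces*
the position with $\Delta L$; because the construction is described as a
perturbation around the current position, the default adds $\Delta L$ to
$L(t)$, and the literal form is available via `gdm_literal = TRUE`. The
perturbation has mean 0 and variance
$p_1^2 (L^\*-L)^2 + p_2^2 (L_{rand}-L)^2$, so it grows with the particle's
disagreement with its own best and with the swarm — large where the swarm
is undecided, small at consensus.

Plain MOPSO is the same engine with the mutation disabled; the mutation
gate's uniform draw is consumed either way, so `mutation_rate = 0`
reproduces plain MOPSO bit-for-bit under a shared seed (a tested
invariant). MOPSO-M replaces GDM with polynomial mutation (η = 20, same
rate). NSGA-II uses binary tournament on rank and crowding, SBX crossover
(η = 15, $p_c$ = 0.9) and the same polynomial mutation.

# Validation protocols and problem sizes

The package's own empirical checks, run by the test suite and
`scripts/acceptance.R`, use the following desk-scale protocols. Sizes were
fixed once, from the study design where it states them (30 particles, 50
iterations, 20 trials; 10 or 50 decision variables; 360 × 70 tables;
τ = 0.3) and from what a workstation evaluates in minutes where it does
not.

* **Graph-metric oracles** — 200 random graphs on ≤ 6 nodes compared to
  brute-force enumeration (BFS distances, explicit shortest-path
  enumeration, direct triple counting) at $10^{-9}$, plus closed forms for
  complete graphs, paths, stars and cycles.
* **ZDT campaign** — ZDT1–ZDT4 and ZDT6 (ZDT5 is Boolean-coded and
  excluded); 30 particles, 50 iterations, 20 trials; IGD against a
  1000-point analytic front; "front attained" means median IGD < 0.1. At
  this evaluation budget the MOPSO family attains ZDT1/ZDT2/ZDT3/ZDT6 at
  D = 10. Two caveats the package reports honestly rather than hides:
  NSGA-II does not converge on ZDT1/ZDT2 within 1,500 evaluations at
  population 30 (an independent reference implementation reproduces this),
  and no generic optimizer solves ZDT4's 9-variable Rastrigin g-function in
  1,500 evaluations, so the ZDT4 "front attained" flag is not reachable at
  this budget; the meaningful and reproducible comparison there is
  *relative*: MOPSO-GDM's median IGD on ZDT4 does not exceed plain
  MOPSO's.
* **Planted-feature recovery** — one 360 × 70 table with 5 informative
  columns at standardized effect size 2; MOPSO-GDM with 30 particles and
  30 iterations (the shorter run keeps the five-seed protocol inside a
  desk-scale budget; at effect size 2 the recovery outcome is already
  stable at this depth), 5 seeds, median reported: planted features in
  the minimum-mean-error solution, and that solution's mean CV error.
* **End-to-end determinism** — the full pipeline twice at a reduced scale
  (8 channels, 256 Hz, 4-s epochs, 6 epochs per group, two bands,
  null-ensemble size 20), byte-identical output files required.

# The synthetic-data generator

The generator emulates the *design* of a two-group resting-state EEG study
— 16 channels at 1024 Hz, 10-s epochs, 180 epochs per group (12 from each
of 15 subjects) — not its physiology. Per band, each channel mixes a
shared band-limited driver (weight = coupling) with private band-limited
noise (weight = 1 − coupling) plus a broadband floor (`noise_sd = 0.5`);
the drivers go through the same FIR filters as preprocessing, so tunable
coupling maps directly onto PSI without simulating neural dynamics. The
default preset couples group A ("AD-like") more weakly than group B
(δ/θ: 0.45 vs 0.50; α/β/γ: 0.35 vs 0.55), mirroring the qualitative
finding that synchronization loss is strongest in the higher bands. Each
(group, epoch) pair draws from a counter-derived sub-stream, so enlarging
the epoch count never reshuffles earlier epochs.

What the generator does **not** model: 1/f spectra, artifacts, eye blinks,
volume conduction, subject-level random effects. Tests passing on this
surrogate demonstrate that the machinery — filtering, phase extraction,
network construction, feature extraction, search — behaves as specified;
they say nothing about clinical discriminability, whose headline numbers
come from private data and are out of scope here.

A note on baselines worth knowing when interpreting PSI tables: for
independent band-limited noise the PSI is not near 0 — with bandwidth $B$
and duration $T$ there are roughly $BT$ independent phase patches, so the
no-coupling PSI concentrates around $\sqrt{\pi/(4BT)}$ — about 0.12 for
the α band over 10 s, with a Rayleigh 95th percentile
$\sqrt{3/(BT)} \approx 0.25$. Narrow bands therefore
have a higher PSI floor than wide ones, which is why low-coupling α-band
values in the 0.1–0.2 range must not be read as weak true coupling.

# Numerical and degenerate-input choices

* Strict inequalities for both binarization (PSI > τ) and decoding
  (position > 0.5), so boundary values map to "no edge" / "not selected".
* Ties in personal-best comparisons resolve by a fair coin; ties in
  archive trimming resolve by crowding order.
* Zero-variance feature columns standardize with scale 1 and screen to
  p = 1 with a warning.
* A class with one sample contributes 0 to $D_w$.
* All validation errors name the offending field.

# Cross-validation granularity

Folds are stratified at the *epoch* level, matching a design that treats
each epoch as a sample (which is what yields 180 samples per group from 15
subjects). Epochs of one subject can then appear in both training and test
folds, which inflates absolute accuracy estimates on real data; the
original design is ambiguous on this point, and this package follows the
epoch-level reading while keeping subject identifiers in the manifest so a
subject-stratified split can be built by the user.

# Known limitations

* The per-metric conventions (betweenness normalization, null-model
  choice, motif set limited to triangles) are fixed stand-ins; a different
  supplement-faithful convention would change feature values but not the
  pipeline contract.
* PSI's zero-lag sensitivity means common-reference or volume-conduction
  artifacts can inflate connectivity; the PLI mode and common average
  reference are mitigations, not solutions.
* The SVM objective dominates the wrapper search's runtime; feature tables
  much larger than 10^3 samples need either fewer folds or a cheaper
  surrogate objective.
* NSGA-II at swarm-sized populations is a weak baseline on continuous
  benchmarks; this is a property of the evaluation budget, not an error.
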