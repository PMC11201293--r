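---
title: "Static and dynamic resting-state features for case-control classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic resting-state features: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`flexstates` implements a complete resting-state fMRI radiomics workflow for
two-group (case-control) classification: temporal preprocessing, five static
per-parcel metrics, two families of dynamic features (multilayer-network node
flexibility and Gaussian-HMM state dynamics), three feature-selection
strategies run inside cross-validation folds, and four-kernel SVM evaluation
with label-permutation testing. Because patient scans are generally not
shareable, the package ships a synthetic cohort generator that reproduces the
statistical structure the analysis assumes, so every stage is testable end to
end and parameter recovery can be demonstrated on known ground truth.

The canonical configuration mirrors a typical clinical resting-state
acquisition: 240 volumes at TR = 2 s (230 analyzed after dropping 10 for
signal equilibrium), 90 atlas parcels, a 0.01–0.1 Hz analysis band, six
recurring brain states, and a 110-patient / 106-control cohort. At that scale
the assembled feature table has 1,267 columns: 5 metrics × 90 parcels = 450
static features and 9 × 90 + 6 + 1 = 817 dynamic features.

## Temporal preprocessing

Only the temporal steps that follow spatial preprocessing are in scope:
volume dropping, per-signal linear detrending, and band-pass filtering.
Slice timing, realignment, spatial normalization, smoothing and nuisance
regression act on raw scanner data and belong to upstream toolboxes.

The band-pass filter is an ideal FFT-domain projection: bins whose folded
frequency lies in [0.01, 0.1] Hz (edges inclusive) are retained, everything
else — including DC — is zeroed. An ideal filter was chosen over a
Butterworth design because it is exactly testable: it preserves pass-band
power to machine precision (a Parseval identity) and is idempotent. Note
that the *sequential* chain detrend → filter is not a projection: re-running
the chain on its own output refits a small trend whose in-band component is
nonzero (a few percent in relative L2). The tests assert the true invariants
(filter idempotence, chain stability) rather than exact composite
idempotence.

`falff()` needs the full spectrum in its denominator, so fALFF is computed
on the detrended but *unfiltered* series; ReHo, degree centrality and both
dynamic analyses use the filtered series.

## Static features

**fALFF.** The fraction of total spectral amplitude that falls in a target
band: slow-5 (0.01–0.027 Hz) for f1ALFF and slow-4 (0.027–0.073 Hz) for
f2ALFF, with half-open band membership so the two bands never double-count a
bin. Amplitudes (not powers) are summed, following the convention of the
standard resting-state toolboxes. A Hann taper is applied before the FFT:
under a rectangular window the amplitude sum is dominated by spectral
leakage for components that fall between bins (an off-bin sinusoid loses a
third of its nominal band fraction to 1/k sidelobes), while the taper bounds
leakage and leaves the flat white-noise expectation — the band-bin fraction
— unchanged. Constant (zero-variance) series return 0 with a degeneracy
flag.

**ReHo.** Kendall's coefficient of concordance W between a voxel's time
course and its spatial neighborhood (27 voxels by default; 7 and 19
available), computed from per-voxel temporal ranks:
W = 12 Σ_t (R_t − R̄)² / (K²(n³ − n)) with K in-mask series and n time
points. Mask-edge voxels use the available neighbors with K adjusted; no tie
correction is applied. ReHo is rank-based and therefore invariant under any
strictly monotone transform applied to each series. ReHo is a voxel-level
quantity by construction: in node mode (parcel series only) it is disabled
and requesting it is an error.

**Degree centrality.** Pearson correlation of each in-mask signal with every
other; edges are correlations strictly above 0.25 (a common toolbox default
— the threshold is exposed), negative correlations never count. BDC counts
edges, WDC sums their weights. Zero-variance signals get no edges and are
flagged. Degree centrality can be computed either at voxel level before
parcel averaging (the default, matching toolbox convention) or directly on
node signals.

Voxel maps are averaged within atlas parcels (arithmetic mean, deterministic
label order; an empty parcel is an error). No z-standardization is applied
to feature maps before averaging — scaling differences are handled by the
classifier's training-fold standardizer.

## Dynamic features I: multilayer network flexibility

Sliding-window Pearson networks (rectangular window of 40 time points,
overlap 0.975, hence step 1 and L = 191 layers at T = 230) with negative
correlations truncated to zero and zero diagonals form an ordinal multilayer
network. Multilayer modularity

Q = (1/2μ) Σ_{ijsr} [(A_ijs − γ k_is k_js / 2m_s) δ_sr + δ_ij ω 1(|s−r|=1)] δ(g_is, g_jr)

uses the Newman–Girvan null model within each layer (resolution γ) and
uniform coupling ω between a node and itself in adjacent layers. The
negative-truncation step is required by this null model, which assumes
non-negative weights; a layer with zero total weight contributes no null
term and is flagged.

The optimizer is an iterated Louvain scheme on node-layer tuples: seeded
random sweeps of single-node moves until no move has positive gain, then
Louvain moves on the (sparse) community-level aggregate, repeated until
neither phase improves Q; the best of three seeded restarts is kept. Q is
non-decreasing across phases by construction, and on small instances
(4–5 nodes, 2–3 layers) the optimizer attains the exhaustively enumerated
optimum in ≥95% of seeded runs — the test suite checks this against a
restricted-growth-string enumeration of all joint partitions.

Node flexibility is the fraction of adjacent layer pairs at which a node's
community label changes: NF(i) = #{l : g_{i,l+1} ≠ g_{i,l}}/(L−1). It is
invariant under community relabeling, 0 when coupling dominates (large ω)
and 1 for a node that switches every layer. The feature block evaluates NF
on the 3 × 3 grid γ ∈ {0.9, 1, 1.1} × ω ∈ {0.5, 0.75, 1}; cell (i, j) is
labelled `NF_g{i}_o{j}` — the grid-cell reading is the only interpretation
of the "NF i→j" feature naming consistent with nine blocks of 90 features.
Each cell runs on its own derived seed, so the 810-value block is
deterministic given the subject seed.

## Dynamic features II: Gaussian-HMM state dynamics

A single group-level hidden Markov model with K = 6 states and a
multivariate Gaussian observation model is fitted to all subjects' series
jointly — per-node z-scored within subject, then concatenated with sequence
boundaries respected (no transition across subjects). A group-level fit is
essential: per-subject models would make occupancies incomparable across
subjects. Diagonal covariances are the default at 90 nodes for
identifiability at desk scale (full covariance would add ~4,000 free
parameters per state); near-singular variances are ridge-regularized and
flagged.

Baum–Welch EM runs from k-means initializations (best of the configured
restarts by final log-likelihood), stops at a relative log-likelihood change
below 1e-6 or 300 iterations, and asserts monotone log-likelihood. Decoding
is hard Viterbi: fractional occupancy FO_k is the fraction of time points
assigned to state k (so Σ_k FO_k = 1 exactly), and the switching rate SR is
the fraction of consecutive pairs at which the state changes, with a T − 1
denominator — the per-step reading is the one consistent with group means
near 0.06–0.08. Soft-posterior occupancies are available behind a flag. The
HMM block contributes FO1..FO6 and SR: 7 features.

One property of the pipeline convention deserves emphasis: the HMM is fit to
the band-passed series, and the 0.01 Hz high-pass removes the sub-band
content of long state dwells, pulling mid-dwell frames toward the global
center and inflating the *absolute* decoded switching rate (roughly twofold
on synthetic cohorts) while preserving the patient-versus-control direction
and the occupancy contrasts. Absolute switching-rate recovery is therefore
assessed on the raw generated series — where decoded group means land within
±0.015 of the planted 0.08 and 0.06 — and the filtered-series SR enters the
feature table as a relative, not calibrated, quantity.

## Feature assembly

Blocks are bound in a fixed order (f1ALFF, f2ALFF, ReHo, BDC, WDC by
parcel; NF by grid cell and parcel; FO1..FO6; SR), giving 1,267 uniquely
named columns at the canonical scale. A subject missing from any block is an
error — no imputation by design. Tables round-trip through TSV with a JSON
provenance sidecar (seeds, configuration, a column-layout checksum).

## Feature selection

All three strategies run *inside* each training fold; held-out subjects
never inform selection.

- **Spearman screening** ranks features by |ρ| against the binary label and
  keeps the top 1% — `ceil(0.01 P)`, minimum 1, ties broken by column
  order; 13 of 1,267. Constant features get ρ = 0.
- **LASSO** is an L1-penalized logistic regression over a 100-point lambda
  path (the common toolbox convention for the path length) with the penalty
  chosen by inner 5-fold cross-validated deviance; features with nonzero
  coefficients are kept. If the chosen penalty keeps nothing, the largest
  lambda with at least one nonzero coefficient is used and the result
  flagged.
- **t + LASSO** first retains features with a two-sided pooled-variance
  Student t-test p < 0.05 — deliberately uncorrected for multiplicity, as
  is conventional for this screening step — then runs LASSO on the
  survivors. A Welch variant sits behind a flag.

## Classification and inference

Per outer fold of a seeded, stratified 5-fold split: standardize on the
training subjects, select features, fit one SVM per kernel (linear,
polynomial degree 3, RBF, sigmoid; cost 1; kernel scale 1/P on standardized
features — conventional defaults, all exposed in the API; no hyperparameter
grid search is performed), then score the held-out fold.
AUC comes from continuous decision values via the rank (Mann–Whitney)
formulation with ties counting one half; accuracy, sensitivity and
specificity use the zero-threshold class assignment with the patient class
positive. Fold means are reported, one row per strategy × kernel.

The permutation test permutes labels over the whole cohort and re-runs the
*entire* pipeline — fold split, in-fold selection, fit, scoring — per
permutation (the only variant immune to selection bias), with
p = (1 + #{perm AUC ≥ observed})/(n_perm + 1). The canonical configuration
uses 5,000 permutations; the desk preset uses 200, whose smallest attainable
p (1/201 ≈ 0.005) is sufficient for a 0.05-level decision.

## The synthetic cohort generator

The generator defines the study conditions downstream stages are tested
under. Per subject it samples a hidden state path from a Markov chain whose
transition matrix is constructed in closed form to have a prescribed
stationary occupancy profile π and expected switching rate s: off-diagonal
mass proportional to π, uniformly scaled — A_ij = α π_j (j ≠ i),
A_ii = 1 − α(1 − π_i), which leaves π stationary for any α and gives
switch rate α(1 − Σπ²), so α = s/(1 − Σπ²). Infeasible (s, π) combinations
raise an explicit parameterization error. Group conditions: patients switch
at 0.08 per step, controls at 0.06; patient occupancies shift state 1 up by
0.06 and states 3 and 6 down by 0.03 each from the uniform profile. An
optional logit-scale subject-level rate jitter (default off) can widen the
between-subject SR spread; with it off, between-subject variance comes from
chain stochasticity alone (SD ≈ 0.018 at T = 230), which is narrower than
typical empirical spreads — a deliberate simplification.

Emissions are state-specific ±1 spatial patterns plus noise split evenly (in
variance) between white and 0.01–0.1 Hz band-limited components, so the
series carry realistic low-frequency content. Patients' planted static
deficits scale the signal of affected parcels (factor 0.6, first fifth of
parcels by default) and add independent noise — reducing amplitude-based and
coherence-based metrics together, which mimics the *direction* of reported
regional effects without claiming their magnitudes. Voxel volumes place each
parcel as a contiguous run of ≥27 voxels on the smallest cube that can host
all parcels (14³ for 90 parcels — a 12³ lattice cannot hold 90 regions of 27
voxels and raises a sizing error naming the minimum), with independent voxel
noise; parcel-mean extraction of noise-free volumes reproduces the node
series exactly.

What the generator does **not** emulate: scanner physics, head motion,
physiological noise, spatial autocorrelation beyond parcel membership,
hemodynamic convolution, and structural (VBM) differences. Passing tests
therefore demonstrate that the pipeline's mathematics is correct and that it
recovers planted effects under its own model assumptions — not that the
classifier's absolute performance transfers to real cohorts.

## Numerical choices and degenerate inputs

- Band edges: inclusive for the band-pass filter; half-open (low ≤ f < high)
  for the fALFF bands so slow-5 and slow-4 partition the spectrum.
- Flat series: fALFF 0 with a degeneracy flag; zero-variance signals get
  correlation 0 (no DC edges) and a flag; a zero-weight window layer skips
  its null-model term and is flagged.
- EM: covariance floor 1e-6 of the mean variance (flagged when active);
  log-domain forward-backward; per-subject sequence boundaries.
- Louvain: move threshold 1e-12 on gains; communities relabelled to
  first-appearance order for determinism; restarts use consecutive derived
  seeds.
- Spearman ties: stable order; top-fraction count `ceil`, minimum 1.
- Degenerate CV folds (one class) are an error; an empty selection skips
  that kernel-fold with a flag rather than failing the run.

## Problem sizes used in the tests

The test suite runs the structural checks at the canonical 90-parcel scale
(a small four-subject voxel cohort for the 1,267-column assembly), the
recovery checks at reduced scale chosen for one-CPU reruns — switching-rate
recovery with 200 subjects per group at 10 nodes, HMM parameter recovery
with 40 subjects at 10 nodes and T = 500, optimizer-vs-enumeration checks on
4–5 node instances — and the end-to-end desk preset at 20/20 subjects,
20 parcels, 200 permutations. These sizes are the package's own desk-scale
choices; the `paper` preset pins the full cohort.

## Known limitations

- Node-mode runs omit ReHo (undefined without voxel neighborhoods), so the
  static block has 4 metrics per parcel instead of 5.
- The multilayer optimizer is a greedy heuristic; global optimality is only
  guaranteed on the small instances where enumeration is feasible.
- Diagonal-covariance HMM states cannot represent state-specific functional
  connectivity, only state-specific mean activation patterns.
- The permutation test re-fits the full pipeline and dominates run time at
  large n_perm; a selection-frozen fast mode is deliberately not the
  default because it is anti-conservative.
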