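---
title: "Methods: sleep-state phase-coupling networks from neonatal EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep-state phase-coupling networks from neonatal EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

neonet implements a complete analysis chain for asking how a clinical
grouping (here: in-utero drug exposure vs. healthy controls) reorganizes the
frequency-specific cortical phase-coupling networks of the sleeping neonate,
and whether that reorganization carries behavioral information. The chain
runs from multichannel scalp EEG through source reconstruction, debiased
phase-lag-index connectivity, network-level permutation statistics, outcome
correlation, and cytoarchitectonic profiling. Because clinical EEG of this
kind cannot be redistributed, the package ships a synthetic-cohort generator
that emulates the statistical structure of such a study; every stage is
exercised and tested end to end on generated data.

This vignette documents the model and the numerical choices. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Study design being modelled

Two groups of neonates (defaults 46 exposed, 61 controls) are each recorded
in two vigilance states — active sleep (AS) and quiet sleep (QS) — giving a
2 × 2 mixed design: group is a between-subject factor, sleep state a
within-subject factor. Connectivity is estimated per subject, state, and
frequency band in four bands: low delta (0.4–1.5 Hz), high delta (1.5–4 Hz),
theta (4–8 Hz), and alpha (8–13 Hz). The scientifically central contrast is
the sleep-by-group *interaction*: does the AS − QS connectivity difference
itself differ between groups?

## Preprocessing

`bandpass_zero_phase()` realizes each band as a high-pass/low-pass pair of
minimum-order Butterworth filters meeting a 20 dB stop-band attenuation
target with transition bands at 25% of each cut-off (the order is chosen by
`signal::buttord`). Filters are applied forward and backward, which cancels
the phase response exactly — essential, since phase is the measured quantity
downstream — and doubles the attenuation in dB. We interpret the 20 dB
specification as the single-pass design target; the applied two-pass
response therefore attains ≥ 40 dB.

Two numerical points deserve note:

* **Second-order sections.** At the normalized cut-offs this analysis needs
  (0.4 Hz at a 100 Hz rate is 0.008 of Nyquist), high-order Butterworth
  filters in transfer-function form are catastrophically ill-conditioned; a
  direct `(b, a)` realization of the 0.4 Hz high-pass amplified white noise
  to ~1e170. All filters are therefore designed and applied as cascaded
  biquads (bilinear transform of the analog prototype poles), which stay
  well-conditioned at any order.
* **Edge padding.** Zero-phase filtering is preceded by odd-reflection
  padding at both ends, so a DC-constant segment passes a low-pass
  unchanged and start-up transients never reach the analysis windows.

`resample_to()` downsamples (only) by zero-phase anti-alias filtering at
0.45 of the target rate followed by cubic-spline evaluation on the target
grid, which handles rational ratios such as 250 → 100 Hz. Content is
expected well below the new Nyquist (the prefilter is 0.4–45 Hz and analysis
stops at 13 Hz), where the spline error is negligible. `average_reference()`
subtracts the instantaneous channel mean.

`select_epochs()` accumulates the per-state analysis signal as `n_windows`
(default 6) equally spaced windows of `window_length` (default 30 s),
i.e. 3 min per state. "Equidistant" is interpreted *within the annotated
time of that state*: annotated segments are conceptually concatenated and
window onsets spaced evenly from the first to the last possible onset, so
exactly 180 s of annotated signal yields back-to-back windows and windows
never include unannotated samples. Subjects with less annotated signal than
the windows require raise a typed exclusion condition rather than an error,
mirroring cohort-attrition practice. Artifact handling is by annotation
only; no automatic artifact detector is included.

## Source model

`make_inverse()` computes the Tikhonov-regularized minimum-norm kernel
`K = G'(G G' + λC)⁻¹` for a lead field `G` and sensor noise covariance `C`
(identity by default — the synthetic cohorts have no empty-room recordings),
with `λ` defaulting to 1/9 of the mean sensor signal power under
unit-variance sources, the usual SNR = 3 convention. Source estimates are
noise-normalized in the dSPM sense: each source is divided by its standard
deviation under the noise model, `sqrt(diag(K C K'))`, so that pure noise
input yields unit-variance estimates. Source orientations are fixed
(surface-orthogonal).

`collapse_parcels()` averages member sources into parcel signals with
per-source weights. The weights come from `compute_fidelity_weights()`: in
each of `n_iter` (default 100) randomizations, every parcel is driven by an
independent band-limited signal shared by its member sources, the sensor
data are inverted, and a source's weight is its mean correlation between
truth and reconstruction, clamped to [0, 1]. This correlation-based
definition is our operationalization of "weighted by the ability to
represent cortical activity"; the exact formula used with real infant head
models lives in specialist source-modelling pipelines and is not reproduced
here. Note one boundary case: in a diagonal (identity) model a source with a
tiny but nonzero gain still reconstructs perfectly in the absence of noise,
because nothing leaks into its sensor; low weights arise from *leakage* in
mixing models, which is the situation the weights exist for.

MRI segmentation, BEM surface construction and realistic conductor models
are out of scope: lead fields are inputs, and the packaged geometry
(`generate_head_model()`) is a deliberately simple quasi-static dipole model
on concentric spheres with parcels labelled frontal/central/temporal/
occipital by position.

## Connectivity

`debiased_wpli()` implements the debiased squared weighted phase-lag index.
With per-sample cross terms `Im_k` (imaginary part of the analytic
cross-spectrum), the estimate is

```
( (Σ Im)² − Σ Im² ) / ( (Σ |Im|)² − Σ Im² ).
```

It is insensitive to zero-lag (volume-conducted) coupling — `y = x` gives
exactly 0 — has expectation 0 for independent signals, and equals 1 for a
constant non-zero (mod π) lag. Slightly negative estimates are possible and
are *retained*, preserving unbiasedness at the null; downstream t statistics
are well-defined either way. Cross-spectral terms come from the analytic
(Hilbert) signal of the band-filtered data, one term per sample, pooled over
the six analysis windows, with 1 s trimmed from each window edge against
filter/Hilbert transients. The debiasing removes the small-sample bias of
the squared estimator under independent terms; band-limited analytic samples
are serially correlated, so a small residual positive bias remains at short
epochs (≈ +0.04 for the 1.5–4 Hz band at 20 s, vanishing as epochs grow) —
one reason the analysis accumulates 3 min per state.

`fidelity_mask()` reproduces the simulation-based edge screening: for every
parcel pair, `n_iter` (default 500) iterations drive that pair with
perfectly synchronous quarter-cycle-lagged signals (design wPLI of 1) and
all other parcels with independent band-limited noise of equal variance;
the noiseless sensor projection is inverted and collapsed, and the full
parcel-pair wPLI matrix computed. The pair's mean reconstructed wPLI is its
fidelity; all non-driven pair values across all iterations form a *single
global* surrogate pool, and an edge survives if its fidelity exceeds the
99th percentile of that pool. Masked edges are set to `NA` — absent from
all downstream statistics, never treated as zero. Masks are computed per
band (they depend on the model and simulation band, so they coincide when
those do). The published 525-edge exclusion count belongs to the authors'
MRI-based head model and is not reproducible from a toy geometry; on the
identity model the mask excludes nothing, and duplicated lead-field columns
exclude exactly the unresolvable edge — both regression-tested.

## Network statistics

`edge_statistics()` computes per-edge contrasts: paired t on AS − QS across
subjects (sleep main effect, pooling both groups), unpaired pooled-variance
t on the per-subject mean over both states (group main effect — "across both
sleep states" operationalized as the subject mean), and unpaired t between
groups on the per-subject AS − QS difference, which is algebraically the
2 × 2 mixed-design interaction.

`nbs_extent_test()` is the network-based statistic: edges with |t| above a
primary threshold (default 2.5) form connected components in the parcel
graph, and each component's extent (edge count; an intensity variant — the
sum of |t| — is available) is referred to the permutation distribution of
the *maximum* component statistic. Group labels are permuted for the group
and interaction contrasts; sleep labels are flipped within subject for the
sleep contrast. When the permutation group is small enough the null is
enumerated exhaustively; otherwise `n_perm` (default 5000) random
permutations are drawn and the observed labelling is included in the null,
so p ≥ 1/(n_perm + 1). Effect size is Cohen's d = mean |t| over the
component divided by √df.

One design choice deviates from the obvious reading of "report AS > QS and
AS < QS networks separately, each against its own one-sided null". Positive
and negative components *are* reported separately, but by default each is
calibrated against the permutation null of the maximum component statistic
over **both** directions. Calibrating each direction against its own null
puts two families side by side, and the probability that *some* reported
component is called significant approaches twice the nominal level; on 200
null cohorts we measured family-wise rates of 0.065–0.095 at a nominal 0.05.
With the joint null the measured rate is 0.015–0.04. The per-direction
variant remains available via `direction_family = "separate"`.

## Outcomes

`pca_composites()` builds composite neurological scores C1/C2 as projections
on the first two principal axes of the standardized item table, with each
axis's sign fixed so its largest-magnitude loading is positive. Note that
after standardization, equal-sized item blocks with equal within-block
correlation produce degenerate eigenvalues and unidentifiable axes — a
property of PCA, not of the implementation.

`delta_connectivity()` / `cohort_deltas()` summarize a network's sleep
dynamics per subject as the mean over network edges of AS − QS.
`correlate_outcomes()` computes two-tailed Spearman correlations between
those deltas and each clinical score, with exact p-values for n ≤ 10
(no ties) and the t approximation otherwise, average ranks for ties, and
pairwise deletion of missing scores. Benjamini–Hochberg adjustment is
applied within declared families; the default grouping is per network by
assessment type — the two neurological composites form one family and the
four 2-year neurocognitive scores another, matching how such results are
customarily corrected.

## Cytoarchitectonic profiling

`project_atlas()` attaches six per-layer neuronal densities (neurons/mm³)
to every source via its parcel's region (parcel-name match first, coarse
lobar label as fallback). A network's profile is the per-layer density
sample of all sources in parcels touching at least one network edge;
profiles depend only on *incident parcels*, which motivates the surrogate
design. `ks_two_sample()` computes the two-sample Kolmogorov–Smirnov D from
ECDFs evaluated at the pooled jump points (tie-safe; checked against
`stats::ks.test` on continuous data, where the two agree exactly — the base
function serves as cross-check, not implementation, because the surrogate
loop needs a vectorized tie-robust variant). `surrogate_network_test()`
refers each layer's observed D (network vs. whole cortex, network included)
to D-values of `n_surrogates` (default 1000) random parcel sets of the same
cardinality, with the +1 correction, and `cyto_adjust_family()` applies BH
across the declared network × layer family (e.g. 5 × 6 = 30 tests).
Sampling surrogates at the node level (same number of distinct parcels,
uniform without replacement) rather than edge level is deliberate: the
profile is a function of the parcel set only. Sources are sampled
unweighted; parcel-area weighting is not modelled. Sensitivity requires the
network to be a small fraction of the cortex — if it approaches the whole
cortex the null degenerates (a warning is raised) — which the test fixtures
respect by using networks of ~5 of 20 parcels.

## The synthetic cohort generator

`study_config()` + `generate_cohort()` produce a full study: toy head
model, per-subject two-state recordings, outcome tables, and a
cytoarchitectonic atlas. The generator's defaults are the modelled study
conditions: 46 + 61 subjects, 19 sensors, 58 parcels, 100 Hz, 6 × 30 s
windows per state, the four bands above.

* **Signals.** Each parcel receives independent band-limited Gaussian
  signals in every band, with 1/√f amplitude scaling; all signals are
  constructed in the frequency domain (complex Gaussian coefficients on the
  in-band bins), so they are exactly band-limited, transient-free, and their
  analytic form is available in closed form.
* **Planted coupling.** A coupled pair mixes a shared analytic driver with
  independent noise, `√c · a(t) + √(1−c) · e(t)`, the second member rotated
  by a constant phase lag (default π/2). This gives analytic control of the
  endpoints: c = 1 with quarter-cycle lag yields debiased wPLI of exactly 1,
  c = 0 yields independence. The default interaction layout couples a
  disjoint edge set in AS for group A and in QS for group B, so the AS − QS
  difference has opposite sign in the two groups. Per-subject coupling is
  jittered (sd 0.15) around the configured strength. Planted edge sets are
  kept disjoint (a matching) by default because a shared driver inside a
  connected planted component would couple *all* its parcel pairs, blurring
  the edge-level ground truth.
* **Sensors.** Parcel signals are copied to member sources, projected
  through the lead field, and white sensor noise is added at 10 dB SNR (a
  conventional figure; simulation SNR is not otherwise pinned down).
* **Outcomes.** Scores are linked to the per-subject true coupling
  difference by a Gaussian copula with the Pearson parameter
  `2 sin(π ρ/6)`, which targets a Spearman correlation of exactly ρ
  (default 0.4) within the exposed group: fine motor positively, the C2
  composite negatively. Remaining scores are independent noise on the
  conventional mean-100/SD-15 scale; two exposed subjects lose their 2-year
  scores to mirror per-assessment availability.
* **Atlas.** One region per parcel, layer-specific baseline densities with
  log-normal between-region spread (sd 0.15 on the log scale), and an
  optional layer-III shift (in between-region SD units) confined to the
  planted network's parcels.
* **Determinism.** All randomness derives from the config seed through
  fixed child streams; regenerating a study with the same config is
  bit-identical, and the run manifest records the config hash.

`generate_edge_cohort()` is the matrix-level companion used for calibration
and power work: it skips signals entirely and draws connectivity values
directly — i.i.d. Gaussian edges (baseline 0.05, sd 0.1, the scale of
3-minute debiased wPLI estimates) plus a planted interaction expressed as a
Cohen's d on the AS − QS difference, an optional between-subject network
effect (sd 0.15) carrying the outcome linkage, and the same copula outcomes.
With no planted structure it produces the i.i.d. null cohorts used to
measure the family-wise error rate of the network test.

Two readings of "a planted effect of d ≈ 0.5" exist when a between-subject
network effect is present: as the *expected* contrast (the realized
per-cohort effect then varies around d with sd ≈ 0.2 at these sample sizes,
and component detection becomes nearly all-or-nothing across cohorts), or as
the *fixed* planted contrast (subject heterogeneity switched off). The
recovery regression test uses the fixed reading; the heterogeneous reading
is exercised wherever outcome linkage matters.

What the generator does **not** emulate: real EEG artifacts, amplitude
dynamics that differentiate AS from QS (trace alternant discontinuity —
only coupling is state-modulated, not the amplitude regime), realistic BEM
geometry, volume-conduction patterns of a true infant head, or
heavy-tailed clinical score distributions. Passing tests therefore certify
the *statistical machinery* — estimator endpoints and bias, error control,
power at planted effects, bookkeeping — not performance on clinical
recordings.

## Problem sizes and test scaling

The tests and the acceptance script run the full machinery at desk scale:
cohorts of 10–107 subjects with 6–20 parcels; 200 null cohorts with 500
permutations each for the family-wise error measurement; 20 cohorts at the
full 46 + 61 design for effect recovery; 100-seed Monte-Carlo means for
estimator bias and outcome-linkage checks; fidelity masks at 5–60
iterations per edge on 6–8 parcel models (the 500-iteration default is the
study-scale setting). These sizes were chosen so the whole suite completes
in a few minutes while every statistical claim retains a meaningful
Monte-Carlo resolution; all of them are ordinary function arguments, so
study-scale runs need no code changes.

## Known limitations

* The fidelity-weight and fidelity-mask simulations contain no sensor
  noise (matching the description of the original screening procedure); a
  noisy variant would tighten the mask.
* The source space is a toy sphere; region labels are positional, not
  anatomical.
* `run_study()` computes per-band masks from band-limited simulations, so
  masks differ across bands only through the simulation band.
* The sleep main effect pools both groups by default; a per-group variant
  is a one-line filter on the edge table.
* Epoch selection assumes annotations are trustworthy; no artifact
  detection is attempted.
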