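---
title: "Methods: EIT indices and cohort prediction around spontaneous breathing trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EIT indices and cohort prediction around spontaneous breathing trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eitsbt)
```

## The measurement model

An EIT system reconstructs a movie of relative intrathoracic impedance:
`frame(t, x, y)` on a 32 × 32 grid at a fixed sampling rate (20 Hz by
default here). Air entering a lung region raises its impedance, so each
ventilated pixel oscillates with the breath, superimposed on an
end-expiratory baseline (EELI), a cardiac oscillation near 60–120 min⁻¹,
and noise. All indices in this package are computed from that movie alone;
no electrode-level reconstruction is attempted, and impedance stays in
arbitrary units (AU) — only ratios and baseline-referenced changes are
reported, which is why every session of a patient must be referenced to
the same t0 baseline.

The session protocol is encoded as three labels: `t0` (baseline on
pressure support), `t1` (end of a T-piece trial), `t2` (after return to
pressure support), linked by `(subject_id, session_label)` with `t0`
mandatory.

## Signal processing

**Cardiac filter.** A low-pass with cutoff 50 min⁻¹ separates the
respiratory band (≈ 10–35 min⁻¹) from cardiac oscillations. We use a
4th-order Butterworth applied forward and backward, giving zero phase
(breath landmark times are preserved — verified to < 1 sample on pure
tones) and a squared magnitude response: ≈ 0.9 % residual amplitude at
90 min⁻¹, ≥ 99.9 % preserved at 20 min⁻¹. The forward–backward pass is
implemented as a matrix operation over all pixel columns with
odd-reflection padding and steady-state initial conditions, so a constant
signal passes through exactly unchanged and filtering is linear in an
additive offset — properties the offset-invariance of the indices relies
on. Filtering is applied per pixel by default (so tidal images and
regional delays also use cardiac-free traces); `pixelwise = FALSE`
switches to filtering the global curve only, since vendor tools do not
document which convention they use.

**Breath segmentation.** End-expiration points are local minima of the
global impedance curve, end-inspiration the unique maximum between
consecutive minima. Noise-born extrema are pruned with a
minimum-prominence rule: alternating extrema whose swing is below 10 % of
the median peak-to-trough swing are merged (iteratively, smallest first).
Partial breaths at the edges are discarded. The analysis subset is the
longest run of consecutive artifact-free breaths — amplitude within
[0.5, ∞) and duration within [0.5, 2] times the respective medians —
tie-broken toward the earliest run; at least 10 selected breaths are
required, otherwise the session is rejected. The respiratory rate is
60 over the mean selected breath duration.

## The index set

**TIV** (tidal impedance variation): mean over selected breaths of the
masked global curve at end-inspiration minus at the breath-opening
end-expiration; expressed as % of the baseline session's TIV (t0 ≡ 100 %).

**ΔEELI**: the session EELI is the mean of the masked global curve at the
selected end-expiration minima. Because AU offsets are not comparable
across sessions, the change from baseline is normalized by the *baseline
TIV*: ΔEELI = −65 % means the end-expiratory level fell by 0.65 baseline
tidal swings. The raw AU value is also emitted.

**Lung mask**: a pixel belongs to the functional lung when its maximum DI
across the study's tidal images (all available sessions, so the mask
covers the maximum ventilated extent) is ≥ 20 % of the overall maximum —
the common functional-EIT convention; the boundary is inclusive.

**IR / IR_adapt**: (ΣROI1 + ΣROI2)/(ΣROI3 + ΣROI4) of the tidal image
over four horizontal bands, ventral to dorsal. Static bands span 25 % of
grid rows each; the adapted variant splits the rows actually containing
mask pixels into four contiguous bands of equal height, with remainder
rows assigned to the dorsal-most bands (a stable, documented rule — e.g. a
10-row extent gives heights 2, 2, 3, 3). A zero dorsal sum makes the
ratio undefined and raises an error.

**GI**: `Σ_lung |DI_xy − median(DI_lung)| / Σ_lung DI_xy`, all sums and
the median over mask pixels only. The raw value is ~0–1; clinical
literature prints it ×100, so `gi_reported = 100 · gi` is the primary
output. GI is invariant under positive rescaling of the tidal image and
zero exactly when ventilation is uniform on the mask.

**spRVD**: for each selected breath and mask pixel, the delay from the
global inspiration onset (the detected end-expiration minimum) until the
pixel's impedance rise first reaches 40/60/80 % of that pixel's breath
amplitude, normalized by the global inspiration duration and clamped to
[0, 100] %. Pixels that never reach threshold score 100 and are counted
as warnings. Per breath, pixel values are summarized by the across-pixel
SD (the heterogeneity reading) and the mean; both are emitted, with the
SD as the primary output. An identifiability caveat governs
interpretation: a spatially *uniform* delay is a pure phase shift of
every pixel, so the global curve — the only timing reference available —
shifts with it, and the absolute delay is unobservable; only the spatial
*spread* of delays is. Accordingly the phantom's analytic ground-truth
delay map (`expected_rvd_map = 100 · τ_xy / T_insp`, threshold-independent
since a phase shift postpones every crossing equally) is the recovery
target for map-level checks, while pipeline-level checks assert the
observable properties: SD ≈ 0 for uniform delays and monotone growth with
the delay spread. For mixed delay fields the detected global onset and
end-inspiration also sit inside the delay spread, so pipeline spRVD
values are comparable within a patient and session protocol but not as
absolute delays — the same caution that applies to the clinical use of
the index under spontaneous breathing.

**RSBI_EIT**: respiratory rate over normalized TIV, `RR/(TIV %/100)`.
With TIV as the tidal-volume surrogate this is the direct analog of the
bedside rapid shallow breathing index (RR/VT) and *rises* under rapid
shallow breathing (it equals RR at baseline). Descriptions of this index
as "the ratio between TIV and RR" circulate with the operands reversed;
the implemented direction is the one under which the index increases when
TIV falls and RR rises, matching how its values behave in practice.

## Cohort prediction

Deterioration is a tidal-volume drop of at least 20 ml at t2 vs t0
(inclusive boundary; the 20 ml guard absorbs measurement error). The ROC
module sweeps candidate cutoffs (midpoints between sorted distinct scores
plus ±∞) under the rule *score > cutoff ⇒ positive* — high baseline GI
predicts deterioration; no automatic direction flipping. The AUC is the
Mann–Whitney statistic normalized by `n_pos · n_neg` with ties counted ½,
which equals exhaustive pair counting (tested) and the trapezoidal area
of the sweep. `operating_point()` returns exact confusion fractions at
any cutoff. Summary tables report median and IQR with linear-interpolation
quantiles (R type 7); a log-GI column (the customary transformation for
skewed GI values) is available on export. Omnibus testing across the
three time points (Friedman/Nemenyi) is deliberately out of scope: the
tables emitted per session are the input any statistics package needs for
those standard tests.

## The synthetic thorax phantom

Each pixel follows
`frame(t) = eeli(t) + A_xy · w(t − τ_xy) + cardiac(t) + noise`, with `w` a
periodic raised-cosine breath waveform rising 0 → 1 over the inspiratory
fraction of the period and returning to 0 over expiration; smooth extrema
keep peak detection well-posed. Defaults and rationale:

- `respiratory_rate` 23.5 min⁻¹, the typical baseline rate on pressure
  support in this patient group; T-piece sessions are simulated near
  26 min⁻¹.
- `inspiration_fraction` 0.5: the waveform is then a single spectral line
  at the respiratory rate, safely inside the filter passband, so index
  recovery is limited by sampling alone. Physiologic I:E ratios (~0.4)
  are available but add harmonics — the 2nd harmonic of a 26 min⁻¹
  breath lies at 52 min⁻¹, where the 50 min⁻¹ filter shaves the tidal
  swing by ~0.7 %; a verification phantom should not fold that rolloff
  into every recovery check.
- `sampling_rate` 20 Hz, typical for clinical belt systems.
- `cardiac_rate` 90 min⁻¹ with amplitude 5 % of the mean lung amplitude
  when enabled — above the 50 min⁻¹ cutoff by design.
- `duration` must cover ≥ 12 full breaths so ≥ 10 complete cycles remain
  selectable; cohort phantoms use 13.5 breath periods (~32–40 s), which
  keeps a 31-patient, 3-session cohort analyzable in about a minute on
  one core.
- `eeli_trajectory` is piecewise-constant per breath (AU per lung pixel),
  so EELI recovery has an exact target; delays are pure phase shifts, so
  expiration shifts with inspiration.
- Ground truth (`expected_tiv`, `expected_gi`, `expected_rvd_map`,
  `expected_eeli_offsets`, `expected_ir`) is computed analytically from
  the parameters, never from the generated movie.

**What the phantom does not emulate:** anatomy beyond two ellipses,
reconstruction artifacts and the spatial blur of real EIT, posture and
electrode-contact drift, irregular breath-to-breath variability, coughs
and swallows, or genuinely nonstationary EELI drift. Passing recovery
tests therefore demonstrates correctness of the *computations* under the
stated signal model, not robustness to every artifact a bedside recording
can contain.

## The virtual cohort

Each virtual patient carries a latent deterioration label
(Bernoulli, expected fraction 13/31), a baseline GI score from a
group-conditional normal, a tidal-volume pair, and three phantom
specifications. Score distributions follow the subgroup medians reported
for this population — GI 46 (deteriorating) vs 41 (stable) — with a
common SD of 5.77 chosen so the binormal theoretical AUC,
`Φ((μ₊ − μ₋)/√(σ₊² + σ₋²))`, equals 0.73; the value is stored with the
cohort and the empirical AUC converges to it (within ±0.02 at n = 2000).
The published group means (59.3 ± 46.1 vs 81.5 ± 62.5 across sessions)
imply heavy right tails that a noise-free two-ellipse phantom cannot
realize: under the 20 %-of-max mask rule a two-level map that keeps every
support pixel in the mask has an analytic GI ceiling near 0.67, so the
generator works on the realizable part of the scale and the median-based
parameterization was preferred.

Amplitude maps realize the drawn score exactly: a half/half two-level
field over the lung support (alternating assignment, so IR stays ≈ 1)
whose low level `c` is solved numerically such that the analytic GI
equals the target (clamped to ≤ 0.58 on the raw scale so `c ≥ 0.25`,
safely above the mask threshold; the latent score itself is never
clamped). T-piece sessions scale the map to 72 % TIV (with the sum
renormalized so the TIV ratio is exact), shift EELI by −0.65 baseline
TIV, add 2.5 min⁻¹ to the rate, and inflate GI by 1.37; t2 returns to
99 %, −0.01, +0.5 and 0.96. Tidal volumes encode the label exactly:
deteriorating patients drop ≥ 20 ml (mean 57), stable patients never do.
Cohort phantoms use zero inspiratory-delay fields by default: a delayed
pixel's DI sampled at the global landmarks shrinks by
`cos(2π · delay/period)`, which would silently bias the designed GI
(regional-delay recovery has dedicated phantoms instead); a delay spread
can be enabled where that bias is acceptable.

## Numerical choices and degenerate inputs

- Filter coefficients from `signal::butter`; cutoffs at or above Nyquist
  are rejected with both rates named.
- Quantiles: linear interpolation (type 7) everywhere; medians over even
  counts average the middle pair (this matters for GI on small masks).
- Tie-breaks: breath-run selection prefers the earliest run; extremum
  pruning removes the smallest swing first; among same-type neighbouring
  extrema the more extreme survives.
- Degenerate inputs error loudly rather than return NA: empty masks,
  all-zero tidal images, non-positive tidal swings, dorsal DI sums of
  zero, single-class ROC labels, cohorts with fewer than two patients in
  either outcome group.
- Reproducibility: all randomness flows from integer seeds
  (phantom `seed`, cohort `seed`, CLI `--seed`); a fixed seed makes
  simulate → analyze → roc byte-identical, and every output table carries
  the config hash and seed.

## Problem sizes used in verification

Verification runs use phantom recordings of 12–19 breaths at 20 Hz
(≈ 650–1200 frames × 1024 pixels), GI and AUC oracle checks on ~100–170
random small instances, a score-only cohort of n = 2000 for Monte-Carlo
AUC convergence, and full-pipeline cohorts of n = 31 (the study scale,
three seeds) — sizes chosen so the whole suite runs in about two minutes
on one core while still exercising every stage end to end.

## Known limitations

- Absolute volumes are out of reach by design: no AU → ml calibration is
  attempted, so TIV/ΔEELI are relative to t0 and patients are only
  comparable after that referencing.
- spRVD absolute levels depend on the detected global inspiration window
  (see the identifiability caveat above); cross-patient comparison of
  absolute spRVD is discouraged, spread comparisons within a patient are
  the intended use.
- The ROC stage provides no confidence intervals (DeLong or bootstrap) —
  at n = 31 the empirical AUC scatters with an SE near 0.09, which the
  Monte-Carlo checks make visible but nothing in the package shrinks.
- The text frame container is verbose (built for exactness and
  inspectability, not storage efficiency); long recordings belong in a
  binary store with this container as the interchange format.
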