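---
title: "Models and methods behind ephysflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ephysflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephysflow)
```

ephysflow analyses paired-region extracellular recordings: sorted spike
units plus local field potentials (LFPs) from two simultaneously recorded
cortical areas (in the motivating application, the prelimbic and
infralimbic subdivisions of rodent medial prefrontal cortex, "PL" and
"IL"). This vignette explains each model the package implements, the
defaults and why they were chosen, what the synthetic-data generator does
and does not emulate, and the numerical decisions a maintainer should know
about. Nothing here states an empirical result that the package's tests do
not themselves compute.

## Spike-unit classification

Sorted units are classified from two measurements:

* **Trough-to-peak waveform width.** The time from the most negative sample
  of the mean waveform to the following positive peak. Widths under 0.5 ms
  mark putative interneurons; wider waveforms mark putative pyramidal
  neurons. A width of exactly 0.5 ms is classed pyramidal: "narrow" is the
  marked category, so the tie goes to the unmarked one.
* **Mean firing rate.** Spike count divided by session duration. Units
  below 0.5 Hz are excluded outright, before the width rule is applied, so
  a narrow but nearly silent unit is `excluded_low_rate`, not an
  interneuron.

Both thresholds are exposed (`width_threshold_ms`, `min_rate`) rather than
hard-coded.

## Evoked-response classification and the modulation index

Spikes are binned in 0.1-s bins over a window from 2 s before to 2 s after
each stimulus onset (40 bins, 20 per side). Bins are half-open `[lo, hi)`,
so a spike exactly at onset belongs to the first post-onset bin. For each
trial the baseline is the mean rate across the 20 pre-onset bins; each
post-onset bin's per-trial rate is compared against the per-trial baseline
with a paired two-sided t-test. A unit is *excitatory* if any significant
bin lies above baseline and *inhibitory* if below; if both directions reach
significance, the earliest significant bin decides (physiologically, the
first response), and the result carries a `mixed_directions` flag plus a
warning so the case is auditable.

Two conventions matter:

* `alpha` defaults to 0.05 per bin, two-sided, with **no correction across
  the 20 post-onset bins**. The resulting family-wise false-positive rate
  is therefore a *measured* property of the procedure — the test suite
  estimates it by Monte-Carlo on null sessions and asserts it is stable
  across independent replications — rather than an assumed one.
* Bins whose paired differences have zero variance are non-significant by
  convention, so deterministic flat tensors come out neutral instead of
  producing 0/0.

The modulation index `|f_after − f_before| / (f_after + f_before)` uses the
mean rates over the full 2-s windows. It is bounded in [0, 1], symmetric,
and invariant to common rescaling of both rates; both invariances are
property-tested. When both rates are zero the index is undefined and
returned as `NA` with a warning.

Z-scored PSTHs standardise the trial-averaged PSTH against the mean and
standard deviation of its own pre-onset bins; units whose baseline bins
have zero spread are reported unscorable (all-`NaN`) rather than silently
dropped. Display-style re-binning (e.g. 50-ms bins for heat maps) is
available through `bin_width` but 0.1 s is the analysis default.

## LFP preprocessing and multitaper spectra

Raw traces are brought to 1250 Hz with a zero-phase anti-alias low-pass
before decimation (the input rate must be an integer multiple of the
target), band-passed 1–100 Hz, and notch-filtered 48–52 Hz against mains.
All filters are forward–backward (zero-phase) Butterworth — 4th order for
the pass bands, 2nd order for the notch — so stimulus alignment is never
shifted. The band-pass is realised as a high-pass/low-pass cascade, which
is numerically safer than one narrow-relative-band transfer function, and
the signal mean is removed before filtering so a DC offset cannot excite
edge transients; as a consequence the whole spectral pipeline is invariant
to constant voltage offsets (property-tested).

For spectra, records are cut into consecutive non-overlapping 10-s
segments (trailing remainder dropped) after a 1–46 Hz band-pass. Each
segment is tapered with the first 5 discrete prolate spheroidal (Slepian)
sequences at time–bandwidth product NW = 3; direct spectral estimates are
averaged over tapers, then over segments. The frequency grid is the
segment's natural resolution — 0.1 Hz for 10-s segments at 1250 Hz —
restricted to [1, 46] Hz inclusive (451 points). The *relative* PSD is each
frequency's fraction of total power on that grid and sums to 1 by
construction.

No R package in the package's dependency set provides Slepian tapers, so
they are computed in-package from the classic symmetric tridiagonal
operator whose eigenvectors are the DPSS, using Sturm-sequence bisection
for the top eigenvalues and inverse iteration with tridiagonal solves for
the eigenvectors — O(n) per taper, under a second for n = 12 500, cached
per configuration. The tests validate the result against a dense
eigendecomposition of the same operator at small n, and `k > 2·NW` is
rejected because higher-order tapers lose their band concentration.

Canonical bands are delta 1–4, theta 4–8, alpha 8–13, beta 13–30 and gamma
30–46 Hz. Since the printed band edges touch, a convention is required: a
shared boundary belongs to the *upper* band (13 Hz is beta), and the top
band keeps its upper edge. Relative band power is the sum of relative PSD
in the band (so the five bands add to exactly 1); absolute band power is
reported both integrated (rectangle rule) and averaged, since either
summary may be wanted downstream.

## Point-by-point group comparison with FDR control

Group contrasts of relative PSD (and of gPDC, below) are made per
frequency point with an unpaired two-sided pooled-variance t-test — the
groups are independent animals — and corrected across the grid with the
Benjamini–Hochberg step-up procedure, the default reading of "an FDR
procedure". Maximal runs of adjacent significant frequencies are reported
as intervals, which is the natural readout ("a significant 17–42 Hz
interval") for spectra. The BH step is implemented in-package because it is
shared infrastructure for both pipelines, and it is verified in tests
against an independent brute-force step-up oracle and against
`stats::p.adjust(method = "BH")`. Degenerate frequencies where both groups
are constant and equal yield p = 1 rather than an error.

## MVAR fitting and generalized partial directed coherence

The two-region LFPs are modelled as a vector autoregression
x(t) = Σ_{r=1..p} A_r x(t−r) + u(t) with white Gaussian residuals. The fit
is conditional least squares per channel (no intercept; channels demeaned
first). Candidate orders 1..max_order are scored with AIC and BIC on a
common effective sample — conditioning on the first max_order values so
criteria are comparable — then the model is refit at the selected order on
all data. When AIC and BIC disagree, the default is BIC (the more
conservative order); `criterion = "aic"` and `"min_of_both"` (the smaller
of the two selections) are flags, and both criteria are always reported in
the diagnostics. Unstable fits are returned with a warning flag rather than
silently used. `stats::ar.ols` serves as an independent cross-check in the
test suite, never as the implementation.

Generalized partial directed coherence is computed from the spectral
coefficient matrix Ā(f) = I − Σ_r A_r e^{−i2πfr/fs} (the "I-minus-sum"
convention of the PDC literature; it is the convention under which zero
coupling gives exactly zero and full linear predictability gives one) as

|C_{i←j}(f)| = (|Ā_ij(f)|/σ_i) / sqrt( Σ_k |Ā_kj(f)|²/σ_k² ),

with σ_k the residual standard deviation of channel k, taken from the
diagonal of the residual covariance (the off-diagonal covariance does not
enter the formula). The 1/σ_i weighting in the numerator is essential: it
is what makes the squared values down each source column sum to exactly 1,
which is the structural reason the measure is bounded in [0, 1]. Some
printed statements of the formula omit this factor, but without it the
bound fails (the supremum becomes σ_i), so the package implements the
weighted form whose normalization identity it can and does verify to
machine precision. Diagonal (uncoupled) models give *exactly* zero
off-diagonal gPDC — an analytic zero, asserted as such.

Mirroring the spectral pipeline, `segment_gpdc()` fits one MVAR model per
10-s segment and averages the gPDC spectra across segments; a
whole-record single fit is available via `seg_len = NULL`. The default
frequency grid matches the PSD grid (1–46 Hz, 0.1 Hz steps) so the two
reports align, and directional band summaries default to 20–46 Hz
(beta + gamma), the band in which directed PL/IL coupling is typically
summarised.

## The synthetic-data generator

The generator exists so that every analysis stage has a parameter-recovery
test with known ground truth; its defaults are the study conditions the
pipeline targets, not tuning knobs:

* **Stimulus protocol**: 20 stimulus events per session with a minimum
  inter-stimulus interval of 60 s (configurable — desk-scale tests use
  denser events), placed uniformly at random subject to the gap, leaving
  2.5 s of margin at both session ends so every trial window fits.
  Sessions default to 1320 s, enough for the full protocol.
* **Spike trains** are inhomogeneous Poisson processes sampled by thinning,
  which is exact for piecewise-constant rates. A unit is described by a
  baseline rate and a multiplicative gain inside a response window after
  each stimulus — gain > 1 excitatory, < 1 inhibitory, = 1 neutral. The
  default response window is (0, 0.5) s: response latency/duration are not
  constrained by the motivating study, so this is a free parameter chosen
  as a typical evoked-excursion length, stated here once and not
  revisited. Default units are one of each class at 5–8 Hz baseline,
  ordinary for deep-layer cortical units.
* **Waveforms** are stereotyped trough-then-peak shapes whose
  trough-to-peak separation equals the requested width (two default
  classes straddle 0.5 ms: 0.3 ms and 0.8 ms), with 0.2 %-amplitude seeded
  jitter — visible in overlays but too small to displace the measured
  extrema by more than one sample.
* **LFPs** are realised from a stable bivariate VAR model (default: VAR(2)
  with one-way coupling IL → PL) with independent Gaussian residuals, after
  a discarded burn-in of 1000·order samples. Stability is checked via the
  companion-matrix spectral radius before any simulation, and the
  generator's stationary covariance is verified in tests against the
  discrete-Lyapunov solution. Known band-limited structure is injected
  with `inject_oscillation()`, which adds a pure sinusoid.

What the generator does **not** emulate: spike-sorting noise and unit
contamination, non-Poisson firing statistics (bursting, refractoriness),
1/f-shaped LFP backgrounds, nonstationarity across a session, artifacts,
or any behavioural covariate beyond an optional scalar. Tests passing on
synthetic sessions therefore demonstrate that the *estimators recover
known ground truth under the stated model*, not that real recordings
satisfy that model.

## Numerical choices and degenerate inputs

* Seeds: every generator takes an explicit seed and restores the caller's
  RNG state; a session seed reproduces the session byte-for-byte, and
  study-level seeds derive per-session seeds within 32-bit range.
* Problem sizes in the test suite are chosen for desk-scale verification:
  direction-recovery runs use 12 500 samples (10 s at 1250 Hz) per fit,
  coefficient recovery 50 000, covariance convergence 100 000; Monte-Carlo
  loops use 100–1000 replicates depending on the property.
* Division-by-zero paths are all explicit: zero-variance t-test bins are
  non-significant, zero-baseline Z-scores are `NaN` with a warning,
  zero-rate modulation indices are `NA` with a warning, and `gpdc()`
  refuses σ ≤ 0.
* Serialization keeps timestamps as 6-decimal text (microsecond precision
  at second scale) and signals as little-endian float32 with a JSON
  sidecar; float32 round-trips are exact to single precision, which is far
  below the noise floor of any analysis here.

## Known limitations

The MVAR machinery supports k channels, but the shipped pipeline exercises
the bivariate case; no time-varying (adaptive) MVAR, spectral Granger
causality, DTF or coherence variants are provided. There is no artifact
rejection beyond filtering, no spike sorting (the pipeline consumes sorted
units), and no behavioural modelling: correlations against behavioural
recovery measures accept any user-supplied vector, whose definition is the
user's responsibility.

## A worked desk-scale example

```{r example, eval = FALSE}
s <- simulate_session(sim_config(seed = 2, session_duration = 60,
                                 n_trials = 8, min_event_gap = 6))
classify_units(s)
tt <- build_trial_tensor(s$units$spike_times[[1]], s$events)
glance(classify_response(tt))
band_power(lfp_psd(s$lfps$PL))
directional_band_gpdc(segment_gpdc(s$lfps), band = c(20, 46))
```
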