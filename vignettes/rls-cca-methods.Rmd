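---
title: "Adaptive background cancellation for SSVEP decoding: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive background cancellation for SSVEP decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlscca)
```

## The signal model

A steady-state visual evoked potential (SSVEP) is a periodic occipital
response phase-locked to a flickering stimulus: for stimulation frequency
$f$ the noise-free response is well approximated by a harmonic sum

$$s(t) = \sum_{h=1}^{N_h} a_h \sin(2\pi h f t + h\phi), \qquad
a_1 > a_2 > \dots$$

with energy decaying across harmonics. What an occipital electrode actually
records is this response plus spontaneous background EEG — broadband
activity with an approximately $1/f$ power spectrum and a narrowband alpha
rhythm near 10 Hz — mixed in by volume conduction, plus sensor noise.
Because alpha sits inside the 8–15 Hz stimulation band, the background is
not removable by frequency-selective filtering alone; that is the problem
this package addresses.

The decoding chain is:

1. **Preprocessing** — zero-phase band-pass, optional decimation,
   optional whole-head common average reference (CAR).
2. **Region split** — the occipital channels form the primary block; the
   sample-wise mean of the non-occipital channels forms a single reference
   channel $u(n)$. Volume conduction spreads the same background sources to
   both regions, so $u(n)$ observes the contaminant but (essentially) not
   the SSVEP.
3. **RLS cancellation** — per occipital channel $d(n)$, a recursive least
   squares filter predicts the background component from the last $L$
   reference samples and subtracts it; the residual $e(n)$ is the cleaned
   channel.
4. **CCA classification** — the cleaned occipital block is scored against
   sin/cos harmonic templates at each candidate frequency; the largest
   canonical correlation wins.

The key assumption is *instantaneous, stationary mixing within an epoch*:
the background reaching an occipital electrode is a (short-FIR-filtered)
copy of what the non-occipital mean sees. The method needs no training
data: templates are analytic and the filter adapts within the epoch being
decoded, which is why block cross-validation here is purely an evaluation
protocol (nothing is ever fitted on the training blocks — one test
asserts this structurally by tampering with the training blocks and
checking the held-out predictions are unchanged).

## The RLS recursion and its parameters

With forgetting factor $\lambda$, weight vector $w$, inverse-correlation
matrix $P$, reference window
$u(n) = [u(n), u(n-1), \dots, u(n-L+1)]^\top$ (zero-padded before sample
$L$):

$$y(n) = w^\top(n-1)\,u(n), \quad e(n) = d(n) - y(n)$$
$$k(n) = \frac{P(n-1)u(n)}{\lambda + u^\top(n) P(n-1) u(n)}, \quad
w(n) = w(n-1) + k(n)e(n)$$
$$P(n) = \lambda^{-1}\left[P(n-1) - k(n)u^\top(n)P(n-1)\right]$$

initialised at $w(0)=0$, $P(0)=\delta^{-1} I$. The identity
$d(n) = y(n) + e(n)$ holds by construction at every sample, and with
$\lambda = 1$ the recursion reproduces the ridge-regularised batch
normal-equations solution $(U^\top U + \delta I)^{-1}U^\top d$ exactly —
the package's primary correctness oracle.

Defaults and rationale:

* **`n_taps` (L) = 8.** Volume conduction is effectively instantaneous at
  EEG timescales, so $L=1$ already captures the dominant mixing; a few
  extra taps absorb the small phase/spectral differences that band-limited
  propagation and reference averaging introduce. Large $L$ mostly adds
  estimation noise.
* **`forgetting` (λ) = 0.999.** Epochs are short (≤ 8 s) and near
  stationary; a long memory trades tracking speed (unneeded) for variance
  reduction. λ = 1 is exact least squares and is what the equivalence
  tests use.
* **`init_scale` (δ) = 0.01**, i.e. $P(0) = 100I$: weak regularisation
  that washes out within tens of samples. The recursion updates $P(n)$,
  so δ is stated as the inverse scale of $P(0)$.
* Two numerical safeguards: $P$ is re-symmetrised every step (the update
  is algebraically symmetric but drifts in finite precision), and a
  divergence guard reinitialises the state with a warning if any weight
  exceeds $10^6$ in magnitude. Neither changes any test value beyond
  tolerance.

One reading had to be fixed by design: the filter is run **once per
occipital channel against the single non-occipital mean**, before any
per-frequency scoring. Cancellation is therefore frequency-agnostic, and
the per-frequency "integration" happens entirely in the classifier's ρ
vector. An alternative reading — one filter per candidate frequency —
has no defined per-frequency reference and would let the filter's
behaviour depend on the hypothesis being tested.

## The CCA classifier

For epoch block $X$ ($p$ channels × $n$ samples) and template $Y_f$
($2N_h$ × $n$), the score is
$\rho_f = \max_{w_x, w_y} \mathrm{corr}(w_x^\top X, w_y^\top Y_f)$. The
solver centers each row, takes the SVD of each centered data matrix to get
an orthonormal basis of its row space, and returns the largest singular
value of the cross-product of the two bases. This is algebraically the
largest singular value of
$C_{xx}^{-1/2} C_{xy} C_{yy}^{-1/2}$ but avoids forming covariances, so a
self-comparison returns $\rho = 1$ to machine precision. The `ridge`
parameter (default $10^{-8}$) acts as a relative rank tolerance:
row-space directions with singular value below $\sqrt{\mathrm{ridge}}$ of
the largest are discarded, which is what keeps the whitening stable with
few samples or near-collinear channels; fully constant input is a hard
error rather than a silent zero.

* **`n_harmonics` = 3**, matching the visible harmonic structure of
  occipital responses (fundamental through third harmonic). Harmonics at
  or above Nyquist are an error, never silently dropped — dropping rows
  for some frequencies and not others would make the ρ values
  incomparable across candidates.
* **Ties** resolve to the lowest frequency index, with a message. Exact
  ties essentially occur only in degenerate synthetic cases: with the
  6-frequency set {8, 10, 12, 13, 14, 15} Hz and $N_h = 3$, the 8 Hz and
  12 Hz templates share a 24 Hz row, so a *pure template* fed back as data
  ties at ρ = 1 for both. Real (or realistically simulated) epochs never
  sit exactly in a template's row space.

## Preprocessing choices

* **Band-pass**: 4th-order Butterworth applied forward–backward
  (`signal::filtfilt`), so the phase response is zero and SSVEP phase
  locking is preserved. Channel means are removed first; DC is outside any
  pass-band and would only inject edge transients. Edge-affected samples
  (`max(3·order, fs/low)` per side) are counted in an attribute rather
  than dropped — epochs are short and callers should decide.
* **Default band 4–45 Hz.** A 4–30 Hz band is the minimal published
  choice for 8–15 Hz stimuli, but it truncates third harmonics above
  30 Hz (e.g. 39 Hz for a 13 Hz target) while the template set expects
  them; `band_preset_narrow()` provides the stricter band for
  reproducing that configuration.
* **Decimation** low-passes at 0.8× the new Nyquist before subsampling;
  plain subsampling would alias broadband background onto the
  stimulation band.
* **CAR scope**: the non-occipital *mean* is the adaptive reference — that
  is the role CAR plays in this pipeline. A whole-head CAR mode
  (`car_scope = "all"`) additionally re-references every channel before
  the split. It is off by default: subtracting the non-occipital mean
  from the occipital channels before cancellation would pre-empt (and
  fix the gain of) exactly the subtraction the RLS filter is there to
  learn.

## Evaluation harness

* **Folds are blocks.** `block_kfold()` never shuffles epochs across
  blocks; with $K$ = number of blocks it is leave-one-block-out.
* **ITR** (bits/min) $= \left[\log_2 M + P\log_2 P +
  (1-P)\log_2\frac{1-P}{M-1}\right] \times 60/T$, entropy limits at
  $P \in \{0, 1\}$. Below chance ($P < 1/M$) the value is clamped to 0
  with a warning: the formula turns positive again as $P \to 0$, but a
  below-chance speller conveys no usable selection rate under this
  reporting convention. **$T$ has no default tied to any published
  table** — reported ITRs depend on a gaze/selection time their sources
  rarely print — so `selection_s` must be chosen by the user (the
  examples use the 2 s decode window).
* **Narrowband SNR** at $f_0$: periodogram power in the bin nearest $f_0$
  over the mean power of bins within ±1 Hz (the $f_0$ bin excluded), in
  dB, capped at ±100 dB. This is the standard SSVEP band-ratio
  definition; before/after-RLS comparisons use it paired per epoch.

## What the synthetic generator emulates — and what it does not

`simulate_trials()` produces tensors in the canonical
(electrode, time, target, block) layout, default (32, 1024, 6, 12): 9
occipital + 23 non-occipital channels, 8 s at 128 Hz, targets at
{8, 10, 12, 13, 14, 15} Hz (chosen, as in real protocols, so that no
frequency is a multiple of another), quarter-cycle phase spacing.

* occipital channel = `ssvep_amp`·harmonic waveform +
  `crosstalk_gain`·shared background + sensor noise;
* non-occipital channel = shared background + independent background +
  sensor noise.

The background is $1/f$-shaped noise (log–log spectral slope ≈ −1) plus
one alpha component (8–12 Hz filtered noise) common to all channels —
the classic confound that overlaps the stimulation band. Defaults:
background 10 µV RMS, SSVEP 3 µV, sensor noise 1 µV, unit crosstalk. The
0.3 signal-to-background ratio places the pure-CCA decoder in a degraded
but clearly above-chance regime on short windows, so the cancellation
benefit is measurable rather than saturated; amplitudes are on the scale
of real scalp EEG. Each (target, block) epoch draws from its own
counter-derived RNG substream, so single epochs are reproducible in
isolation.

Deliberately **not** modelled: realistic leadfield geometry (crosstalk is
a single shared waveform with a scalar gain, not a per-channel mixing
matrix), propagation delays, eye-blink/EMG artifacts, non-sinusoidal
SSVEP waveshape, inter-subject variability. Passing tests on this
generator therefore demonstrate the algorithmic properties of the chain —
exact recursions, correct scoring, the benefit of cancellation when a
shared additive background exists — not expected accuracy on any
particular recorded dataset, where channel-specific mixing and artifacts
make the problem harder for the filter and easier for nothing.

## Problem sizes used by the tests

The suites run at sizes chosen to exercise every property at comfortable
statistical power while staying quick on one CPU: RLS/batch equivalence at
$n = 500$, $L \le 8$; the CCA oracle on 200 random instances; the
contaminated-regime comparison on 102 epochs of 2 s at the 0.3 ratio and
unit crosstalk; the chance floor on 300 signal-free epochs (accuracy must
fall within ±3 binomial SE of 1/6); decode windows of 2 s, which is also
the regime where the two decoders separate — at the full 8 s window both
saturate near perfect accuracy on this generator.

## Known limitations

* The MAT-file layer covers uncompressed little-endian level-5 files with
  numeric and character arrays (zlib-compressed elements are inflated when
  possible); cell arrays, structs and v7.3 files should go through the
  HDF5 dialect instead.
* One shared reference channel is used for all occipital channels; a
  per-channel multichannel (MIMO) canceller is out of scope.
* The canceller cannot distinguish background from signal if the SSVEP
  itself leaks into the non-occipital mean at non-negligible amplitude;
  with strong leakage it would subtract signal. The generator's
  non-occipital channels are SSVEP-free by construction, matching the
  assumption.
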