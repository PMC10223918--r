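# rlscca

SSVEP decoding for brain–computer interfaces by **recursive least squares
(RLS) adaptive noise cancellation** followed by **canonical correlation
analysis (CCA)** frequency classification.

## The problem

A steady-state visual evoked potential (SSVEP) speller flashes several
targets at distinct frequencies; gazing at one entrains occipital EEG at
that frequency and its harmonics. The standard decoder scores each
candidate frequency *f* by the largest canonical correlation ρ_f between
the multichannel occipital recording X and a harmonic template

    Y_f = [ sin(2π f t); cos(2π f t); …; sin(2π N_h f t); cos(2π N_h f t) ]

and selects argmax_f ρ_f. Volume conduction, however, mixes spontaneous
background EEG (1/f activity, the ~10 Hz alpha rhythm) into the occipital
channels, and because that background overlaps the stimulation band it
degrades ρ at exactly the frequencies being tested.

This package enhances the occipital channels before classification. The
mean of the non-occipital channels u(n) serves as a reference recording of
the background; for each occipital channel d(n), an RLS adaptive filter
estimates the background component y(n) = wᵀu(n) that is predictable from
the reference and the residual

    e(n) = d(n) − y(n)

is the cleaned SSVEP channel passed to CCA. The recursion (forgetting
factor λ, inverse-correlation matrix P(n), gain k(n)):

    k(n) = P(n−1)u(n) / (λ + uᵀ(n)P(n−1)u(n))
    w(n) = w(n−1) + k(n) e(n)
    P(n) = λ⁻¹ [ P(n−1) − k(n)uᵀ(n)P(n−1) ]

with w(0) = 0, P(0) = δ⁻¹I. With λ = 1 the recursion is exactly
growing-window least squares — a property the test suite checks against
the batch normal equations.

The package ships the full chain: 4-D trial-tensor IO (MAT/HDF5),
preprocessing (zero-phase band-pass, decimation, common average
reference), the RLS canceller, the CCA classifier, a block-wise K-fold
evaluation harness (accuracy, information transfer rate, narrowband SNR),
a synthetic SSVEP generator with known ground truth, and a small CLI
(`inst/cli/rlscca-tool.R`).

## Worked example

Simulate a 32-channel, 6-target recording (9 occipital + 23 non-occipital
channels; SSVEP at 0.3× the background RMS with unit volume-conduction
crosstalk) and decode it with leave-one-block-out folds on 2 s windows:

```r
library(rlscca)

sim    <- simulate_trials(sim_scenario(n_blocks = 6, epoch_s = 2, seed = 2026))
report <- run_pipeline(sim$tensor,
                       pipeline_config(window_length_s = 2, selection_s = 2))
report
#> <ssvep_eval> 36 epochs over 6 folds
#>   accuracy: 0.7778   ITR: 39.14 bits/min (T = 2 s)
#>   mean SNR at true frequency: 4.40 dB before, 6.28 dB after RLS

baseline <- run_pipeline(sim$tensor,
                         pipeline_config(rls_enabled = FALSE,
                                         window_length_s = 2, selection_s = 2))
baseline$accuracy
#> [1] 0.4444444
```

The report reads: of 36 held-out epochs, 77.8% were assigned their true
stimulation frequency, worth 39.1 bits/min at one selection every 2 s, and
adaptive cancellation raised the narrowband SNR at the true frequency by
about 1.9 dB on average. The pure-CCA baseline on the same data reaches
only 44.4% — the ordering the method is designed to produce when the
background is strong. `tidy(report)` returns the per-epoch tibble
(predictions, SNRs, the per-frequency ρ vector), `glance(report)` the
one-row summary, and `autoplot(report)` the before/after SNR figure.

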