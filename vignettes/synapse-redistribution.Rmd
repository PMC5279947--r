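---
title: "Modelling synapse redistribution and analysing fiber-volley-normalised recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling synapse redistribution and analysing fiber-volley-normalised recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synredist)
```

## The scientific question

The dentate gyrus receives its cortical input through the perforant path,
whose presynaptic terminals form a large but essentially fixed pool. Adult
neurogenesis keeps adding granule cells (GCs) to this circuit. Two
hypotheses describe how a newly integrating GC becomes innervated: the
circuit grows new terminals for it (synaptic *addition*), or the new cell
takes over terminals from neighbouring mature GCs (synaptic
*redistribution*). Redistribution predicts that enhancing neurogenesis
should *weaken* excitatory input onto individual mature GCs while leaving
population measures (the fEPSP) and the total synapse count unchanged.

`synredist` packages the two computational components of that argument: a
deterministic age-structured simulation that quantifies how many mature-cell
synapses the integrating population would appropriate, and the analysis
pipeline for the slice electrophysiology that measures the corresponding
change in synaptic strength.

## The redistribution model

### State and assumptions

The model tracks a single conserved quantity — a static pool of ~19.6
million synapses — and an age-structured ledger of immature cohorts. Its
assumptions:

* **Conservation.** The pool is sized once at day 0
  (`initial_pools()`): mature cells contribute
  `synapses_per_mature_cell × total_cells × mature_fraction` = 1.9e7, and the
  pre-existing immature population (5% of cells with ages spread uniformly
  over the 43-day maturation span) contributes
  `10,000/43 × Σ Y(t) ≈ 6.2e5`. No synapse is created or destroyed
  afterwards; `%im + %mat = 100` at every day is the model's expression of
  redistribution.
* **Deterministic expected values.** Cohort sizes are real-valued expected
  counts; no stochastic birth/death sampling is performed. There is no
  randomness anywhere in this module.
* **No in-window maturation.** The simulated horizon (43 days) does not
  exceed the maturation span, so immature cohorts never convert to mature
  status; the constructor enforces `horizon <= maturation_span`.
* **Integration curve.** `Y(d) = 71.1 ln(14 + d) − 187.7` percent of mature
  strength at `d` days after integration onset, fit to evoked EPSC
  amplitudes of immature GCs at progressive ages. The raw curve is −0.06%
  at `d = 0` and 99.8% at `d = 43`; we clamp to [0, 100] so the narrated
  0→100% bounds hold exactly, which changes no worked example
  (`synaptic_strength(0)` is the only clamped default-range value).
* **Day indexing.** Days are integers; cohorts incorporate on days
  `1..horizon` and a cohort incorporated on day `k` is evaluated at
  `Y(t − k + 1)`, exactly as the convolution
  `S_I(t) = I(t)Y(1) + I(t−1)Y(2) + …` prescribes. We take the printed
  recipe `I(t) = P(t) × survival` at face value and add no extra 14-day
  birth-to-integration shift: the knockout onset day (14) is the sole lag
  in the model, and it is what produces the steep divergence of the
  knockout trajectory at the time immature GCs begin to integrate.

### Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `total_cells` | 200,000 | cells | unilateral GC count |
| `mature_fraction` | 0.95 | — | mature share at day 0 |
| `synapses_per_mature_cell` | 100 | synapses | defines 100% strength |
| `strength_slope/intercept/age_offset` | 71.1 / 187.7 / 14 | %, days | integration curve |
| `maturation_span` | 43 | days | onset to full maturity |
| `prolif_scale/age_offset/exponent` | 4e6 / 42 / −1.5 | cells·day^1.5, days | proliferation decline |
| `survival_wt`, `survival_ko` | 0.20, 0.70 | fraction | newborn survival |
| `ko_onset_day` | 14 | days | first knockout cohort |
| `ko_strength_factor` | 1.35 | — | extra synapses on knockout cells |
| `horizon` | 43 | days | simulated window |

Two numerical choices deserve comment:

* **The mature-pool arithmetic.** The published expression for the mature
  pool multiplies 190,000 — itself already 95% of the total — by 0.95 a
  second time. We compute `S_M = 100 × 190,000 = 1.9e7`, the only reading
  consistent with the stated ~19.6-million total; the package treats the
  duplicated factor as a typographical slip.
* **The proliferation anchor.** The printed curve gives ~9,545 progenitors
  at day 14 and reaches ~8,000 only at day 21, although the narrative says
  it was calibrated to ~8,000 at day 14. The printed formula governs;
  `prolif_age_offset` is exposed so the alternative anchoring can be
  explored by configuration.

The knockout strength multiplier is applied to `Y` *after* clamping and is
itself uncapped: a fully mature knockout cell may hold 135
synapse-equivalents, reflecting the ~35% surplus that blocked synaptic
pruning leaves in place.

The `%im` numerator counts only newly appropriated synapses, following the
printed formula literally, so the trajectory starts at `%im = 0`. Setting
`include_baseline_in_numerator = TRUE` instead counts the pre-existing
immature pool (the trajectory then starts at ~3.2%). The day-36..43
knockout/control ratio is essentially unaffected because the same baseline
enters both conditions.

```{r simulate}
ctrl <- run_simulation(condition = "control")
ko   <- run_simulation(condition = "bax_ko")
predicted_mature_ratio(ko, ctrl)
```

## The evoked-response pipeline

The recordings the pipeline models stimulate the medial perforant path at
increasing intensity (0–100 V) while measuring, simultaneously, the fiber
volley (FV — the extracellular signature of how many axons were recruited),
the fEPSP slope (population synaptic drive) and the whole-cell EPSC of a
clamped GC. The conventions implemented:

1. **Sweep averaging** (`average_by_intensity()`): the 10 stimuli delivered
   at each intensity are averaged into one response; the saturation flag is
   a majority vote, with ties counted saturated (the conservative choice
   for a flag whose purpose is exclusion).
2. **Saturation exclusion** (`exclude_saturated()`): responses that
   saturate axonal recruitment drop out, which is why higher FV bins hold
   fewer observations. The original judgment was the operator's; for data
   without an explicit flag, `flag_saturated()` provides a reproducible
   plateau rule — a response is saturated when its FV and its next-lower
   intensity's FV both lie within 5% of the cell's maximum.
3. **Fiber-volley binning** (`bin_by_fiber_volley()`): responses are
   assigned to half-open bins `[kw, (k+1)w)` anchored at 0 μV (the
   published figures use widths of 100 μV and 75 μV; anchoring is not
   stated there and 0 is the natural choice). Binning by FV removes
   stimulus intensity from the data set and normalises for the number of
   stimulated axons.
4. **Normalised strength** (`response_fv_ratio()`): the per-response
   EPSC/FV ratio (pA/μV), averaged within group. We average per-response
   ratios rather than dividing grand means because the reported sample
   sizes are per response; the two estimators agree in the noiseless limit
   and differ only by a weighting choice.
5. **Unweighted-means ANOVA** (`unweighted_means_test()`): with unequal
   cell sizes across (group × FV-bin) cells, main-effect and interaction
   sums of squares are computed from unweighted cell means with the
   harmonic mean of cell sizes in place of n; the error mean square pools
   the within-cell variances with `N − cells` degrees of freedom (the
   classical unweighted-means error term; the exact degrees of freedom used
   in the original analyses were not stated, so this documented choice
   governs the reported p-values). On a balanced design the procedure
   reduces exactly to the standard two-way ANOVA, which is how it is
   cross-checked in the test-suite against `stats::aov`.

Amplitudes are stored as magnitudes (inward currents positive); SEMs use
the n−1 variance; percent changes are reported rounded to integers and
ratios to two decimals, matching the reporting conventions of the source
measurements.

## The synthetic-data generator

`make_sweeps()` emulates what the pipeline consumes, not the biophysics
that produced it:

* FV recruitment is a saturating hyperbola
  `FV = gain × fv_max × I/(I + fv_half_sat)`; the recordings show
  saturating recruitment without stating a functional form, and a
  hyperbola is the simplest shape with the right asymptote.
* Each slice draws a recruitment gain (CV 0.2), mimicking slice-to-slice
  variability in electrode placement and tissue health.
* fEPSP slope and EPSC are linear in the *same sweep's* FV with
  multiplicative noise `(1 + cv·z)` truncated at −0.9 to keep magnitudes
  positive; group effects enter only through the EPSC gain (and event
  rate), mirroring the experimental finding that FVs and fEPSPs did not
  differ between groups.
* A response is flagged saturated when its FV exceeds 85% of `fv_max`,
  producing the characteristic dropout at high intensity.
* Defaults: 15 slices per group (the size of the recorded control group),
  intensities 10–100 V, `fv_max` 400 μV (the largest reported FV bin),
  half-saturation 30 V, noise CV 0.15, lognormal event amplitudes with
  median ~15 pA at 0.5 Hz. Gains for named experiments come from the
  measured group means (`epsc_gain_presets()`), e.g. 2.44 pA/μV for
  control mature cells.

What passing tests on these data do show: the pipeline is unbiased for the
generating gain, respects its invariants (partition, scale equivariance,
saturation invariance), and detects a measured-scale group effect with high
power. What they cannot show: robustness to features real recordings have
and the generator does not — correlated noise within a slice, rundown over
a session, FV measurement error correlated with the response, non-linear
EPSC-FV relations near saturation, or operator-dependent saturation calls.

```{r pipeline}
cfg  <- preset_config("control", seed = 1)
resp <- exclude_saturated(average_by_intensity(make_sweeps(cfg), 10))
response_fv_ratio(resp)$summary
```

## Numerical and testing choices

* All arithmetic is plain double precision; the simulation is exactly
  reproducible with no seed, the generators are byte-identical given a seed
  and leave the session RNG untouched.
* Degenerate inputs are rejected (negative ages, zero durations,
  non-positive first-pulse amplitudes, all-saturated tables warn and
  return empty) rather than silently propagated.
* Zero-FV rows cannot be ratio-normalised and are dropped with a warning.
* Bins absent from any group are dropped before the unweighted-means test:
  the non-overlapping tails of recruitment curves carry no between-group
  information at matched FV.
* The test-suite checks the simulation against independent brute-force
  oracles (a per-cell expansion of the cohort ledger on a miniature
  parameter set; `stats::aov` on balanced designs and an
  independently coded harmonic-mean-n oracle on unbalanced ones) and the
  generator against its moment contracts. Statistical checks run at desk
  scale: recovery tests use 15 slices per group (~130 responses) and the
  power check 200 seeded replicates of the two-group design, sizes chosen
  to mirror the recorded experiments while keeping the default suite quick.

## Known limitations

* The model is a deterministic expected-value calculation: it propagates no
  uncertainty from the underlying anatomy (cell counts, survival rates) to
  the predicted ratio.
* Proliferation is identical in both conditions by construction; any effect
  of the manipulation on proliferation is out of scope.
* The pipeline consumes already-detected events and already-measured sweep
  summaries; raw-trace processing (filtering, event detection, FV peak
  picking) is deliberately not implemented.
* The unweighted-means procedure assumes homogeneous within-cell variance;
  with strong heteroscedasticity across FV bins its error term is only an
  approximation.
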