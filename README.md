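# dfkurtosis

Task-based **diffusion functional MRI** analysis in R: fast mean-diffusivity
(MD) / mean-kurtosis (MK) mapping per stimulation condition and diffusion
time, diffusion-time-dependence model comparison, and ROI-level
rest-vs-stimulus statistics — together with a seeded synthetic-study
generator so the whole chain is testable without any acquisition.

## The problem

During a block paradigm (alternating 28 s rest / 28 s forepaw-stimulation
intervals), diffusion-weighted volumes are acquired at five diffusion times
Δ ∈ {9.5, 15, 20, 25, 30} ms and labeled by condition. Activity-dependent
changes in cell morphology and membrane permeability shift MD and MK; how
MK varies **with Δ** carries information about inter-compartmental water
exchange. The package answers two questions per region of interest:

1. **Amplitude** — the percent change of MD/MK (and of the BOLD signal)
   during stimulation relative to rest, with mixed-effects significance
   testing and FDR control;
2. **Time dependence** — which of five candidate models best describes
   MD(Δ) and MK(Δ), compared by corrected AIC (AICc):
   * 1D structural disorder: `v(Δ) = c∞ + 2A·Δ^(−1/2)`
   * 2D–3D structural disorder: `v(Δ) = c∞ + A·ln(Δ/t_c)/Δ`
   * two-compartment exchange (Kärger) kurtosis decay:
     `MK(Δ) = K0·(2t_ex/Δ)·[1 − (t_ex/Δ)(1 − e^(−Δ/t_ex))]`,
   the last giving a direct estimate of the exchange time `t_ex`.

MD/MK maps come from the fast two-shell estimator: an exact closed-form
inversion of the cumulant signal model
`ln S(b) = ln S0 − b·D + (1/6)·b²·D²·K` along each of 9 gradient
directions (2 shells, b = 1 and 2 ms/µm²), averaged with a direction set
whose 2nd- and 4th-order moments are isotropic to machine precision (so
the direction average equals the true tensor mean; see
`verify_direction_set()`).

## Worked example

Fit the exchange model to a noiseless 5-point MK(Δ) curve and recover its
parameters:

```r
library(dfkurtosis)
grid  <- c(9.5, 15, 20, 25, 30)
curve <- timedep_curve(grid,
           eval_model("karger_mk", c(K0 = 0.86, t_ex = 53.8), grid),
           metric = "MK")
fit_timedep(curve, "karger_mk")$params
#>    K0  t_ex
#>  0.86 53.80
```

Run the full synthetic study (10 rats, 48 runs, 5 diffusion times; ~10 s
to estimate all 480 parametric maps):

```r
study <- make_study(default_study_config(), seed = 20260928)
est   <- estimate_study(study)
roi   <- study_roi_table(study, est)
change_report(roi[roi$laterality == "contra", ])
```

```
Rest vs. stimulus amplitude changes (max |%| across diffusion times)
  s1fl     MD    -1.19% (Delta = 30 ms)  q = 1.28e-50 ***
  s2       MD    +1.65% (Delta = 9.5 ms) q = 2.39e-67 ***
  tha      MD    +2.28% (Delta = 15 ms)  q = 8.62e-81 ***
  cpu      MD    +1.73% (Delta = 15 ms)  q = 8.07e-59 ***
  hip      MD    +1.65% (Delta = 15 ms)  q = 9.1e-45  ***
  m2       MD    -0.15% (Delta = 25 ms)  q = 0.255
  rsc      MD    -0.20% (Delta = 25 ms)  q = 0.255
  s1fl     MK    -7.05% (Delta = 30 ms)  q = 1.67e-43 ***
  s2       MK    +0.72% (Delta = 9.5 ms) q = 0.668
  tha      MK    +3.51% (Delta = 25 ms)  q = 6.82e-18 ***
  cpu      MK    +2.24% (Delta = 15 ms)  q = 7.22e-08 ***
  hip      MK    +2.12% (Delta = 25 ms)  q = 7.22e-08 ***
  m2       MK    -0.38% (Delta = 15 ms)  q = 0.828
  rsc      MK    -0.54% (Delta = 30 ms)  q = 0.862
```

Each line is one ROI × metric: the signed maximum percent change across
the five diffusion times (with the Δ where it occurs), and the
FDR-corrected q-value of the mixed-effects condition test (condition +
diffusion time fixed; run + subject random). The injected pattern — MD/MK
decrease in the S1FL-like primary somatosensory region, increases in the
S2-like and subcortical-like regions, nulls in the two control regions —
is recovered with the expected signs and significance. Fitting the
exchange model to the study's contralateral S1FL MK(Δ) curves gives
`t_ex` = 64.8 ± 1.9 ms at rest vs. 43.4 ± 1.9 ms during stimulation
(shorter exchange time, i.e. higher apparent membrane permeability, under
stimulation).

The numbered drivers under `analysis/` run the same chain as a narrative
workflow and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # manifest + text fixtures
Rscript analysis/02_estimate.R   # 480 maps -> results/roi_table.tsv
Rscript analysis/03_timedep.R    # model comparison tables
Rscript analysis/04_stats.R      # change report + BOLD arm
```

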