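---
title: "Functional diffusion MRI: fast kurtosis mapping and diffusion-time dependence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional diffusion MRI: fast kurtosis mapping and diffusion-time dependence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfkurtosis)
```

## What this package computes

Task-based *diffusion* functional MRI probes brain activity through changes
in water diffusion rather than through blood oxygenation. During a block
paradigm of alternating rest and stimulus intervals, diffusion-weighted
volumes are acquired at several diffusion times $\Delta$, each volume is
labeled by the condition in force when it was acquired, and voxel-wise mean
diffusivity (MD) and mean kurtosis (MK) are estimated per condition and per
$\Delta$. Two families of questions follow:

1. **Amplitude**: does stimulation change MD or MK in a region, and by how
   much (percent change relative to rest)?
2. **Time dependence**: does the functional state change the *shape* of
   $\mathrm{MD}(\Delta)$ and $\mathrm{MK}(\Delta)$ — in particular the
   inter-compartmental water exchange time that controls the kurtosis
   decay?

The package implements the full chain on synthetic data: block scheduling
and volume bookkeeping, a seeded generator of diffusion and BOLD series
from two-compartment exchange substrates, the fast two-shell MD/MK
estimator, five time-dependence models compared by corrected AIC, and the
ROI-level mixed-effects statistics with FDR control, plus the BOLD arm
(epoch normalization and a boxcar GLM with family-wise error control).

## The fast MD/MK estimator

The signal model is the two-term cumulant expansion
$$\ln S(b) = \ln S_0 - b\,D(\mathbf n) + \tfrac16 b^2 D(\mathbf n)^2 K(\mathbf n),$$
inverted exactly from two shells ($b_1 = 1$, $b_2 = 2\ \mathrm{ms/\mu m^2}$)
along each gradient direction:
$$D = \frac{b_2^2 y_1 - b_1^2 y_2}{b_1 b_2 (b_2-b_1)},\qquad
  K = \frac{6\,(b_2 y_1 - b_1 y_2)}{D^2\, b_1 b_2 (b_2-b_1)},$$
with $y_i = -\ln(S(b_i)/S_0)$. Per repetition the protocol acquires 3
$b_0$ images and 9 directions per shell (21 measurements); the two
repetitions per condition are averaged to 19 images per condition (18
diffusion-weighted + 1 pooled $b_0$) before estimation.

Averaging over directions requires the direction set to reproduce the
isotropic moments of the sphere: the plain average of $D(\mathbf n)$ equals
$\mathrm{tr}(\mathbf D)/3$ exactly when the second moments of the set are
isotropic, and the tensor-weighted average
$\mathrm{MK} = \tfrac19\sum_n (D_n/\mathrm{MD})^2 K_n$ equals the full
kurtosis-tensor mean $\bar W = W_{iijj}/5$ exactly when the fourth moments
are isotropic. The shipped 9-direction set was obtained by numerical
optimization of both conditions to machine precision and is checked by
`verify_direction_set()`; any user set passing the gate can be substituted.
The common 3-axes + 6-face-diagonals set fails the fourth-order condition
($\langle n_x^4\rangle / \langle n_x^2 n_y^2\rangle = 4 \ne 3$) and is
rejected. The tensor-mean MK convention is the default; a plain mean of
$K_n$ is available via `mk_convention = "plain-mean"`.

Noise handling: signals are clipped below at `signal_floor * S0`
($10^{-6}$ by default) before logs, and voxels with non-positive MD,
negative MK, or non-finite estimates are excluded by `mask_unphysical()` —
these are noise or partial-volume artifacts and never enter ROI statistics.

## Time-dependence models

Five candidate models describe $\mathrm{MD}(\Delta)$ and
$\mathrm{MK}(\Delta)$ in gray matter:

* **1D structural disorder** (intracellular water in thin processes):
  $v(\Delta) = c_\infty + 2A\,\Delta^{-1/2}$ — 2 parameters.
* **2D–3D structural disorder** (extracellular geometry):
  $v(\Delta) = c_\infty + A\,\ln(\Delta/t_c)/\Delta$ — 3 parameters.
* **Two-compartment exchange (Kärger) kurtosis decay**:
  $$\mathrm{MK}(\Delta) = K_0\,\frac{2 t_{ex}}{\Delta}
    \Big[1 - \frac{t_{ex}}{\Delta}\big(1 - e^{-\Delta/t_{ex}}\big)\Big],$$
  with $\mathrm{MK}\to K_0$ as $\Delta\to 0^+$, monotone decay, and
  $\mathrm{MK}\approx 2K_0 t_{ex}/\Delta$ for $\Delta \gg t_{ex}$.

The disorder amplitudes are written with the $2A\Delta^{-1/2}$ and
$A\ln(\Delta/t_c)/\Delta$ factor conventions; the factor only rescales $A$
and cannot affect fit quality or model ranking.

Fitting is Levenberg–Marquardt least squares on the mean curve (5 points at
$\Delta = 9.5, 15, 20, 25, 30$ ms), unweighted by default because the
source protocol does not state a weighting (SE-weighting is a flag).
Initialization is multi-start: for the exchange model
$t_{ex}\in\{10,25,50,100,200\}$ ms with $K_0 = \max(\mathrm{curve})$; the
disorder forms are seeded from their exact linear-in-parameters solves
(both are linear after reparameterization, which also makes the noiseless
round trips exact). Bounds: $t_{ex}\in(1,10^3)$ ms,
$t_c\in(10^{-3},10^3)$ ms, $K_0\in(0,10)$; amplitudes unbounded in sign.
Parameter covariance is the Jacobian-based estimate scaled by
$\mathrm{RSS}/(n-k)$.

Model comparison uses the Gaussian small-sample AIC,
$\mathrm{AICc} = n\ln(\mathrm{RSS}/n) + 2k + 2k(k+1)/(n-k-1)$, undefined
when $n \le k+1$ (such fits are excluded). An exact fit gives
$\mathrm{AICc}=-\infty$ and stays in the comparison; ties break toward
fewer parameters. On the 5-point grid the exchange model's Jacobian at
$(K_0\approx0.86,\ t_{ex}\approx50\,\mathrm{ms})$ is full rank with
condition number $\sim 10^3$, so both parameters are identifiable.

```{r roundtrip}
grid <- c(9.5, 15, 20, 25, 30)
curve <- timedep_curve(grid,
  eval_model("karger_mk", c(K0 = 0.86, t_ex = 53.8), grid), metric = "MK")
fit_timedep(curve, "karger_mk")$params
```

## The synthetic study

`make_study()` emulates the full experiment: 10 rats with 5 functional
runs each (two rats contribute 4), the stimulated forepaw alternating
between runs and the starting side alternating between rats, so that the
24 + 24 runs split evenly into contralateral and ipsilateral groups
(quantification is in one hemisphere; a run is contralateral when the
opposite forepaw is stimulated). Per run: five diffusion acquisitions
(84 volumes each, 3 epochs of 28 s rest / 28 s stimulus at TR = 2 s) and
one BOLD series (336 volumes, 6 epochs at TR = 1 s). Within an interval,
volumes follow scheme order ($b_0$ first, then direction-major, b-minor);
repetitions are split across epochs. These orderings are configurable —
the protocol leaves them open, and nothing downstream depends on them
because estimation uses condition-averaged images.

Voxels are isotropic two-compartment exchange substrates. The baseline is
$f = (0.5, 0.5)$, $D = (1.075, 0.325)\ \mathrm{\mu m^2/ms}$,
$t_{ex} = 53.8$ ms, giving $\mathrm{MD} = 0.70$, $K_0 = 0.86$. MD is
time-independent in this substrate; MK decays with $\Delta$ through
$t_{ex}$ only. Stimulus-condition substrates are derived per region:
joint scaling of the diffusivities sets the MD change (leaving $K_0$
untouched), and the MK change at the reference time
$\Delta_{ref} = 20$ ms is realized by adjusting $t_{ex}$ (MK decreases
map to shorter exchange times, i.e. higher membrane permeability). The
generator's ground-truth signal uses the same cumulant truncation the
estimator inverts, so noiseless round trips are exact to $10^{-9}$ and
fitting behavior is isolated from model mismatch; an anisotropic mode
(per-region diffusion + kurtosis tensors, directional cumulant form)
exists for estimator-validation studies. Rician noise is the magnitude of
two Gaussian channels with $\sigma = S_0/\mathrm{SNR}$; the $b_0$ SNR
profile mimics a surface coil, from 20 in cortical regions down to 10 in
the deepest region.

**Effect calibration.** Region effects are stated as the percent changes
the *measured* maps should show (around −1.1% MD and −4.9% MK in the
S1FL-like region; +1.3 to +2.4% in the S2-like and subcortical-like
regions; null in two control regions). At low SNR the estimator
attenuates contrasts — Rician bias plus the unphysical-voxel mask
truncate the MK distribution — so injecting the target change directly
would under-produce it in deep regions. The generator therefore divides
each target by a frozen attenuation gain, calibrated once by large-voxel
Monte Carlo at $\Delta_{ref}$ (from 0.94/0.95 for MD/MK at SNR 20 down to
0.73/0.47 at SNR 10). The reported maximum-amplitude change across
$\Delta$ will still exceed the $\Delta_{ref}$ target when the exchange
mechanism makes the MK change grow with $\Delta$; the calibration pins the
$\Delta_{ref}$ value, not the maximum.

The BOLD generator adds a boxcar response (percent of baseline), a linear
drift (0.2 %/min) and two Gaussian noise components: voxel-independent
(1% of baseline) and spatially common (0.2%), the latter mimicking
global physiological fluctuations and setting the noise floor of ROI-mean
time courses. Because the common component is shared, ROI estimates are
correlated across regions within a run; per-ROI tests remain calibrated,
but in occasional seeds all null regions drift together to a weak
(q ≈ 0.02–0.05) shared flag — a faithful property of correlated
physiological noise, not a bias (noise-free null series give exactly zero
condition difference).

Seeding: one master seed; per-series seeds are derived from
(rat, run, $\Delta$ index, condition) by a fixed integer hash kept below
$2^{31}$, so any single series is reproducible in isolation.

What the generator does **not** emulate: spatial anatomy (regions are
voxel blocks), EPI distortion, motion, slice timing, partial volume,
non-exchange MD time-dependence, and vascular (T2-weighted) leakage into
the diffusion signal. Passing tests therefore validate the estimators and
statistics under the stated noise model, not robustness to acquisition
artifacts — the preprocessing that removes those artifacts is outside
this package's scope.

## ROI statistics

ROI means use valid voxels only. Percent change is
$100(\text{stim}-\text{rest})/\text{rest}$, computed per $\Delta$ from
condition means pooled across runs; the reported amplitude is the
elementwise maximum of $|\text{change}|$ across the five $\Delta$, sign
kept, with the $\Delta$ at which it occurs.

The condition test is a linear mixed model per ROI and metric: condition
and diffusion time (categorical, 5 levels) as fixed effects, random
intercepts for run and subject, ML fits, and a likelihood-ratio test for
the condition effect. LRT was chosen over Wald/Satterthwaite as the
simplest well-defined p-value for a single fixed-effect contrast at this
design size (240 measurements per ROI and laterality: 24 runs × 5
diffusion times × 2 conditions). If the full model fails or is singular,
random terms are dropped in turn (run, then subject, finally a
fixed-effects LRT); the diffusion-time fixed effect is always retained,
because dropping it would pour the (large) MK time-dependence variance
into the residual of the condition contrast. The fallback level is
recorded with each result.

FDR control is Benjamini–Hochberg within each metric family (all ROIs of
MD; of MK; of BOLD), with stars at 0.05/0.01/0.001 on q-values.

The BOLD arm mirrors the diffusion sensitivity: ROI-mean time courses are
high-pass filtered (discrete cosine basis below 0.01 Hz plus a linear
trend; the task boxcar is included in the drift regression but not
removed, so drift estimation cannot absorb task-locked signal), each
epoch is normalized by its mean over the 14 s preceding stimulation, the
response function is the pointwise mean across epochs, and one amplitude
per condition is obtained by averaging all rest and all stimulus
timepoints (paired condition test across epochs within a run; mixed model
across runs). The voxel-wise GLM regresses each time course on
[intercept, boxcar, drift basis], with two-sided t-tests,
Bonferroni family-wise correction over in-mask voxels at 0.05, no
cluster-size threshold, and a depth mask excluding voxels below 10% of
the mean cortical signal (mean rather than median — the choice is
unstated in the source protocol and immaterial at these SNRs).

## Numerical choices

* The exchange decay $h(x) = (2/x)[1-(1-e^{-x})/x]$ uses `expm1` and
  switches to its Taylor expansion below $x = 10^{-6}$.
* Degenerate substrates with all-zero diffusivities return MK = 0; the
  fraction and non-negativity invariants are enforced at construction.
* `nlsLM` runs with `ftol = ptol = 1e-15` and 500 iterations; the best
  converged start by RSS wins, and a fit that never converges is flagged
  and excluded from comparisons rather than silently reported.
* BH q-values come from `p.adjust(method = "BH")`; the step-up property
  (q ≥ p, monotone in sorted order) is asserted in tests.

## Problem sizes

The default synthetic grid is 20 × 20 × 6 voxels with region sizes of
200–600 voxels (the in-vivo ROIs span roughly 100–1400 voxels), chosen so
that a full study simulates and estimates in about ten seconds and the
whole chain stays comfortably testable. The test suite runs the
end-to-end sign-recovery property over 12 seeded full-scale replicates,
the null calibrations over 500–1000 replicates, and model-recovery over
200 noisy curves per family.

## Known limitations

* The mixed model treats run and subject as crossed random intercepts;
  with 4–5 runs per subject the run variance is weakly identified and the
  singular-fit fallback is exercised regularly at small scales.
* MK estimates at SNR 10 carry large variance and truncation bias; the
  calibration gains correct the *mean* contrast, not the per-voxel
  distribution.
* The exchange model and the 1D-disorder model fit 5-point MK curves
  comparably well at realistic noise; model selection between them on
  measured curves is reliable only at the noise levels the tests
  demonstrate.
* Percent-change maxima over $\Delta$ are extreme-value statistics: under
  the null they are biased away from zero, which is why significance is
  assessed by the mixed model on all rows, never on the maximum itself.
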