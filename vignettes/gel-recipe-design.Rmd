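---
title: "Designing tunable MRI phantom hydrogels: models, solver and in-silico validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing tunable MRI phantom hydrogels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelphantom)
```

## The problem

Quantitative MRI needs test materials whose longitudinal relaxation time
T1, transverse relaxation time T2 and apparent diffusion coefficient
(ADC) are *simultaneously* set to tissue-like values. `gelphantom`
models a three-ingredient aqueous hydrogel in which Gd-DTPA acts as the
T1 modifier, agarose as the dominant T2 modifier and soy lecithin as the
ADC modifier. The complication — and the reason a solver is needed at
all — is that the modifiers are not orthogonal: lecithin also shortens
T1 and T2, and Gd-DTPA also shortens T2.

## Forward models and their assumptions

Relaxation rates (R = 1/T, handled internally in s⁻¹; the API speaks ms)
are affine in the concentrations:

$$R_1 = R_{1w} + r_{1,Gd}\,C_{Gd} + r_{1,lec}\,C_{lec}$$
$$R_2 = R_{2w} + r_{2,Gd}\,C_{Gd} + r_{2,lec}\,C_{lec} + r_{2,a}\,C_a$$

and the ADC depends only on the lecithin load, through a biexponential
decay (plausibly reflecting two water pools as lecithin vesicles restrict
diffusion):

$$ADC(C_{lec}) = a_f\,e^{-k_f C_{lec}} + a_s\,e^{-k_s C_{lec}}.$$

Assumptions baked into this structure:

* **No interaction terms.** Each ingredient contributes additively to the
  rates; the calibration data support this within the calibrated ranges
  (Gd ≤ 0.2 mM, agarose ≤ 4 %, lecithin ≤ 5 % wt/vol). Outside those
  ranges `predict_triple()` still evaluates the models but attaches an
  extrapolation warning; at lecithin ≥ 3 % an additional flag notes that
  measured ADCs become more variable, so the targeted ADC is less
  accurate there.
* **Agarose does not touch R1.** Its longitudinal relaxivity is
  negligible in the composite gel, so the relaxivity table simply has no
  `r1_agar` entry. This is what makes the three-step inversion triangular.
* **Fixed temperature and field.** The shipped constants are for 3 T and
  20 °C; no temperature or field scaling is modelled. The solvent
  baseline object records both as metadata so every downstream number can
  state its conditions.

### Default parameter values

| quantity | default | units |
|---|---|---|
| `a_fast`, `k_fast` | 0.36, 2.79 | 10⁻³ mm²/s, (% wt/vol)⁻¹ |
| `a_slow`, `k_slow` | 1.60, 0.13 | 10⁻³ mm²/s, (% wt/vol)⁻¹ |
| `r1_gd`, `r2_gd` | 3.78, 4.24 | s⁻¹ mM⁻¹ |
| `r1_lec`, `r2_lec` | 0.10, 0.69 | s⁻¹ (% wt/vol)⁻¹ |
| `r2_agar` | 6.62 | s⁻¹ (% wt/vol)⁻¹ |
| `t1w_ms`, `t2w_ms` | 3000, 2000 | ms |

Two of these deserve comment. First, published characterizations of this
gel system quote the agarose transverse relaxivity inconsistently — a
tabulated 6.62 versus a narrative 6.23 s⁻¹ (% wt/vol)⁻¹. The default
table uses 6.62; because agarose is solved *last*, this choice only
rescales the agarose concentration (by ~6 %) and never affects
feasibility of T1 or ADC. Users who trust the other value can supply it
via `relaxivity_table()` or the YAML config. Second, the pure-water
baselines are not part of the published calibration at all; T1w =
3000 ms and T2w = 2000 ms are literature-typical values for deionized
water near 20 °C at 3 T. All feasibility outputs carry the baseline used,
since boundary numbers (e.g. the maximum T1 at a given ADC) shift with
it.

The shipped tissue table (`tissue_targets()`) uses a liver ADC of 1.40;
the higher in-vivo figure of ~1.45 sometimes quoted for liver is strongly
perfusion-influenced, which a diffusion-only gel should not chase.

## The three-step inversion

`solve_recipe()` exploits the triangular dependency:

1. **Lecithin from ADC.** The biexponential is strictly decreasing, so
   the root is unique. It is found by bisection on [0, 10] % wt/vol with
   an ADC residual tolerance of 1e-10 — effectively exact, and
   independent of any derivative information. Targets above the water
   ADC (1.96 with the default coefficients) or below the bracket's ADC
   are structured infeasibility errors.
2. **Gd-DTPA from T1**, closed form. A negative numerator means the
   lecithin load already pulled T1 below the target — the upper T1
   boundary of the achievable region.
3. **Agarose from T2**, closed form. A negative numerator means the
   target T2 exceeds the agarose-free *baseline T2*.

Numerical conventions: boundary equality (a concentration of exactly 0)
is feasible and flagged `near-boundary`; infeasibility is always
attributed to exactly one step. Because steps 2 and 3 are closed forms
and step 1 is solved to 1e-10, the round trip
`predict_triple(solve_recipe(t))` reproduces the target to better than
1e-9 relative — a property the test suite checks on the shipped tissue
triples and on 1000 randomly drawn feasible targets.

`feasibility_grid()` rasterizes the achievable (ADC, T1) region and the
baseline T2; the default 121 × 131 grid over ADC 0.8–2.0 × 10⁻³ mm²/s and
T1 700–2000 ms covers the clinically interesting domain at steps of 0.01
and 10 ms. With the default calibration the maximum T1 at ADC = 0.9 is
about 1289 ms (hence gray matter, wanting T1 ≥ 1500 ms at that ADC, is
out of reach), and the minimum baseline T2 over the grid is about 208 ms
— comfortable headroom for agarose to shorten T2 into the tissue range.

## Calibration fitting

* `fit_relaxivity()` is ordinary least squares of rates on
  concentration (`stats::lm`), the standard definition of a relaxivity;
  the slope standard error comes from the residual variance.
* `fit_adc_model()` fits the biexponential by unweighted
  Levenberg–Marquardt in natural response space (`minpack.lm::nls.lm`),
  multi-started from all 21 ordered pairs of a 7-point log-spaced decay
  grid over 0.05–10 (% wt/vol)⁻¹ with amplitudes seeded from the endpoint
  ADCs; the best start by SSE wins and components are reordered so
  `k_fast > k_slow`. Natural-space unweighted fitting matches how such
  calibrations are presented; log-space fitting would implicitly
  down-weight the (well-measured) high-ADC points.
* **Degeneracy.** Biexponentials are famously ill-conditioned. A nested
  single-exponential fit is always run alongside; when it explains the
  data equally well (SSE difference below 1e-9 of the signal energy) the
  biexponential parameters are not identifiable, the result is flagged
  degenerate and the single-component solution is reported in the slow
  component. Nearly equal decay constants (ratio < 1.5) raise an
  ill-conditioning warning rather than an error.

On noiseless data generated from the default coefficients at the seven
study concentrations (0, 0.5, 1, 2, 3, 4, 5 %), the fit recovers all four
parameters to machine precision. With 1 % multiplicative noise the
dominant slow component stays within ~5 %, while the small fast amplitude
— which carries little signal — is only determined to ~15 %; the test
suite asserts exactly this, per component, rather than pretending all
parameters are equally identifiable.

## The synthetic scanner

`render_phantom()` emulates three 2-D acquisitions over a tube-in-housing
layout (default: five 14 mm-radius tubes on a 60 mm circle in a water
disc, 128 × 128 matrix, 200 mm FOV):

* **IR-TSE** (T1): nine inversion times log-spaced 25–6400 ms (a factor
  of 2 per step — the published protocol states the range but not the
  spacing, so the spacing is this package's convention), TR 10000 ms. The
  signal model keeps the finite-TR recovery term,
  $|M_0(1 - 2e^{-TI/T_1} + e^{-TR/T_1})|$; decay during the 9.9 ms
  readout is neglected (≲ 20 % amplitude for the shortest in-scope T2 and
  irrelevant to T1 estimation, which is driven by the TI dependence).
* **CPMG** (T2): 32 echoes, 10–320 ms equally spaced, mono-exponential
  decay.
* **DWI** (ADC): b = 0, 50, 500, 1000 s/mm², mono-exponential in b with
  `s0` equal to the proton density; echo-time attenuation is recorded as
  metadata but not applied, so the noise level is uniform across tubes.

Magnitude (not complex) data are produced, with Rician noise
$\sqrt{(x+n_1)^2 + n_2^2}$ — which deliberately forces the mapping module
to handle inversion-recovery polarity, as with real scanner magnitude
output. What the simulator does *not* emulate: k-space/EPI artifacts,
partial-volume averaging at tube edges (voxels are assigned by center
point), B0/B1 inhomogeneity, magnetization transfer, kurtosis, or
perfusion. Passing simulate-then-fit tests therefore demonstrates the
self-consistency of models, solver and estimators under realistic noise —
not robustness to scanner physics outside the model.

## Voxel-wise mapping

All exponential fits profile the amplitude out analytically (for a fixed
decay time the model is linear in $M_0$), locate the SSE basin on a
coarse log grid, and polish with Levenberg–Marquardt at tight tolerance.
On noiseless data every fitter inverts its simulator to a relative
residual below 1e-8, the core oracle-equivalence property of the package.

* **T1 (IR):** polarity is restored exhaustively — for each candidate
  null index k the first k magnitude points are sign-flipped, the signed
  model is fitted, and the minimum-SSE solution wins.
* **T2 (CPMG):** echoes whose measured magnitude falls below 2.5× the
  estimated noise sigma are excluded from the fit. At the noise floor the
  Rayleigh mean $\sigma\sqrt{\pi/2}$, not the decay, dominates the
  magnitude; fitting those echoes biases short T2 upward by more than 3 %
  at SNR 50 for T2 ≈ 40 ms, while with truncation the bias stays under
  2 %. The sigma estimate comes from the sub-threshold background voxels
  of the first frame (it runs slightly low because the mask clips the
  Rayleigh tail, making the truncation conservative). With sigma 0 all
  echoes are used, preserving noiseless exactness. No amplitude-domain
  Rician correction is applied; the residual positive bias at short T2 is
  a documented caveat.
* **ADC (DWI):** ordinary least squares of log signal on b, fully
  vectorized; with two b-values it reduces to the closed-form two-point
  slope. Voxels with non-positive signal are flagged.
* **Masking:** voxels whose first-point signal is below 5 % of the series
  maximum are excluded; flagged voxels are removed from the output mask.

All estimates are invariant to uniform signal scaling, and Monte-Carlo
suites verify median recovery at SNR 50 within 2 % (T1, ADC) and 3 %
(T2), with bias shrinking as SNR grows over 10–100.

## End-to-end demo and stability check

`run_demo()` chains solve → simulate → map → validate for a target table,
continuing past infeasible entries, and writes CSV/NIfTI/JSON artifacts
whose manifest records the calibration provenance (relaxivities and
solvent baseline) behind every number. One master seed fans out
deterministically to per-acquisition sub-seeds, so reports are
bit-reproducible. At SNR 50 the five-tube demo recovers every ROI mean
within 3 %; noiseless runs close to better than 0.2 %.

`stability_fixture()` generates a stationary 12-week series of ROI means
with 1 % measurement scatter (the scale of batch-to-batch variation seen
in repeat gel preparations) and `stability_report()` flags drift when the
95 % confidence interval of the weekly trend excludes zero. On the
stationary fixture the flag rate is the nominal 5 % type-I error — which
is what a synthetic fixture *can* establish; real shelf-life (dehydration,
agarose ageing) is outside its reach. An injected 1 %/week drift is
reliably flagged.

## Problem sizes

The shipped defaults are the study conditions: 128 × 128 matrix, five
tubes, SNR 50, the protocols above. Unit tests exercise smaller grids
(24–64 voxels a side, 300–500 Monte-Carlo replicates) chosen as the
smallest sizes at which the statistical assertions have comfortable
sampling margins; the acceptance-style checks run the full-size phantom.

## Known limitations

* Validity is bounded by the calibrated ranges; extrapolation is flagged,
  not forbidden. Lecithin and agarose are natural products — other
  product sources need re-characterization (`fit_relaxivity()`,
  `fit_adc_model()` on new titrations).
* No "closest feasible recipe" suggestion for infeasible targets; they
  are reported with the violated boundary only.
* Single-slice 2-D geometry; no partial-volume handling at tube edges.
* The T2 noise-floor truncation needs a background region (or a known
  sigma) to estimate the noise level; series without either fall back to
  the all-echo fit and inherit its short-T2 bias.
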