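# hpadyn

Analysis of ACTH–cortisol dynamics during and after major cardiac surgery.

Healthy subjects secrete ACTH and cortisol in tightly coupled ultradian
pulses (period 2.5–3 h) whose amplitude is modulated over the day, with
cortisol trailing ACTH by about 10 minutes. Cardiac surgery disrupts this
coupling, and the disruption is not graded but *patterned*: post-surgical
profiles fall into distinct dynamic phenotypes — a single large excursion,
two slow supra-physiological pulses, or multiple fast pulses with strong
peak dissociation. `hpadyn` is for researchers in computational
endocrinology who want to reproduce, probe or extend this style of analysis
on high-frequency hormone panels (10-minute sampling), using synthetic data
with known ground truth.

## What is inside

**The model.** Cortisol is an open-loop, two-compartment response to the
measured ACTH through a delayed Hill-type adrenal drive:

```
dC_f/dt = −C_f/λ_f + p_f · H(A(t−10))        H(A) = A^m / (K_A^m + A^m)
dC_s/dt = −C_s/λ_s + p_s · H(A(t−10))        C    = C_f + C_s
```

with production rates `p_f, p_s` (nmol/l/min), time constants `λ_f < λ_s`
(min), adrenal sensitivity `K_A` (ng/l), Hill coefficient `m` and a 10-min
input delay. Calibration is an ensemble random search (default 10⁵–10⁶
draws) scored by range-normalised RMSE, keeping the best 0.1% — parameter
*distributions*, not point estimates — with fixed-sensitivity
(`K_A = 50.28`) and fixed-Hill (`m = 2`) scenarios.

**The statistics.** Time-lagged cross-correlation (Spearman) and its
rolling-window form, instantaneous phase synchrony from band-passed
analytic-signal phases, rolling Pearson correlation, hormone ratios,
ultradian period estimation and prominence-based pulse counting — feeding a
rule-based classifier of the dynamic phenotypes, plus a cytokine PCA and a
model-residual-versus-mediator correlation analysis.

**The generator.** Seeded synthetic profiles for healthy controls and all
three disruption regimes, including cytokine responses and an optional
known inflammation→cortisol coupling, so every pipeline stage is testable
end to end.

## Worked example

```r
library(hpadyn)

p <- gen_cabg_profile(regime_spec("two_pulse"), seed = 42)
p
#> <subject_profile> two_pulse_s42: 73 samples at dt = 10 min; cytokines: none;
#>   surgery 55-230 min; regime two_pulse

call <- classify_profile(compute_sync_metrics(p))
call
#> <phenotype_call> two_pulse (pulses 2, period 350 min, lag 10 min, stability 1)
#>   rule2: n_pulses == 2, period 350 >= 240, stability 1.00 >= 0.7

ens <- fit_ensemble(p, n = 20000, keep = 20, seed = 1, scenario = "fixed_both")
ens
#> <fit_ensemble> fixed_both: kept 20 of 20000 draws; epsilon range 0.0257-0.0390
```

The subject's cortisol shows two pulses 350 min apart with a 10-min peak lag
and a stable lag stripe across epochs, so the classifier fires its
two-pulse rule. The ensemble fit under the fixed-sensitivity scenario
reaches a normalised error ε ≈ 0.026; the kept sets' slow half-life
distribution leans high (best set: λ_s ≈ 480 min), the mechanism this
regime is built around.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on a synthetic panel
and write tables under `results/`:

1. `01_simulate_panel.R` — generate the panel (controls + three regimes,
   with cytokines) as canonical long CSV.
2. `02_synchrony.R` — TLCC/RWTLCC/IPS/period/pulse metrics per subject.
3. `03_phenotypes.R` — classification and confusion against the generating
   regime.
4. `04_fit_model.R` — ensemble calibration per regime under free and fixed
   scenarios; parameter distribution summaries.
5. `05_residual_inflammation.R` — cytokine PCA and the subjects × mediator
   residual-correlation matrix.

Each script prints what it found; the methods vignette
(`vignettes/hpa-dynamics.Rmd`) documents the model, the generator's design
and its limitations.

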