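---
title: "Modelling and classifying HPA-axis dynamics around cardiac surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and classifying HPA-axis dynamics around cardiac surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpadyn)
```

## The problem

Under healthy conditions ACTH and cortisol pulse together every 2.5–3 hours,
with pulse amplitudes modulated over the day and cortisol trailing ACTH by
roughly one 10-minute sampling step. Major surgery disrupts this
choreography: total ACTH secretion rises several-fold while cortisol rises
much less, and the two hormones can decouple in characteristic ways. This
package implements a complete analysis chain for paired ACTH–cortisol (and
cytokine) series sampled at 10-minute intervals: a mechanistic cortisol
model, ensemble calibration, a battery of non-stationary synchrony
statistics, a rule-based classifier of post-surgical dynamic phenotypes, and
a residual-versus-inflammation correlation analysis — together with a seeded
synthetic-data generator that emulates the study conditions so that every
stage can be exercised and validated end to end without clinical data.

## The cortisol model

Cortisol is modelled open-loop as two first-order compartments driven by the
measured ACTH through a delayed, saturating adrenal response:

$$\frac{dC_f}{dt} = -\frac{C_f}{\lambda_f} + p_f\,H(A(t-\tau)), \qquad
  \frac{dC_s}{dt} = -\frac{C_s}{\lambda_s} + p_s\,H(A(t-\tau)),$$

with total cortisol $C = C_f + C_s$ and Hill drive
$H(A) = A^m / (K_A^m + A^m)$. The input delay is $\tau = 10$ min. Parameters
and units:

| parameter | meaning | units | default (control calibration) |
|---|---|---|---|
| $p_f$, $p_s$ | fast/slow production rates | nmol l$^{-1}$ min$^{-1}$ | 900, 0.5 |
| $\lambda_f$, $\lambda_s$ | fast/slow time constants | min | 2, 180 |
| $K_A$ | adrenal sensitivity (half-max ACTH) | ng l$^{-1}$ | 50.28 |
| $m$ | Hill coefficient | — | 2 |
| $\tau$ | input delay | min | 10 |

Using an open-loop architecture means the measured ACTH is the input, so no
pituitary feedback needs to be parameterised; the cost is that any
ACTH-side disruption appears in the input rather than being explained.
The initial condition puts the fast compartment at quasi-equilibrium with
the (clamped) delayed drive at the first sample,
$C_f(0) = p_f \lambda_f H(A_{\mathrm{eff}}(0))$, and assigns the remainder of
the observed initial cortisol to the slow compartment, floored at zero.
Before the record starts the delayed input is clamped to the first ACTH
sample: we do not invent pre-record history.

### Control calibration

The control parameter set is chosen once so that model-generated healthy
profiles reproduce healthy physiology: a 12-hour cortisol AUC near
2 900 nmol h l$^{-1}$ against an ACTH AUC near 200 ng h l$^{-1}$, and — the
sharper constraint — a peak time-lagged cross-correlation at the +10-minute
input delay. The second constraint forces the *fast* compartment to dominate
the pulsatile response: a fast time constant of a couple of minutes adds a
negligible filtering lag on a 10-minute grid, whereas a 10–20-minute fast
compartment already drags the rank-correlation peak to +20 or +30 minutes.
The resulting fast production rate (900 nmol l$^{-1}$ min$^{-1}$ at
$\lambda_f = 2$ min, i.e. a fast gain $p_f\lambda_f = 1800$ nmol l$^{-1}$ at
full drive) is large only because $\lambda_f$ is small. This is also why the
default sampling bound for $p_f$ in the random search extends to
$10^3$: with the conventional upper bound of $10^2$ the calibrated
physiology itself would be unreachable and every fit would degenerate into
slow-compartment surrogates.

## Numerical integration

The two compartments are linear, so the only numerical care needed is the
driving signal: ACTH is interpolated linearly between samples and pushed
through the Hill function, giving a smooth drive with kinks at sample times.
Integration uses the classic fixed-step 4th-order Runge–Kutta scheme with a
step of at most 1 min, shrunk further to $\lambda_f/5$ for very fast
compartments so the per-step decay stays well resolved. Steps align with the
10-minute sample grid, so the drive's kinks fall on step boundaries and the
scheme keeps its full order; against an adaptive reference integrator at
tolerance $10^{-10}$ the maximum relative error on pulsatile inputs is below
$10^{-6}$ (the test suite asserts $10^{-5}$). The core loop is implemented
in C++ because ensemble calibration evaluates $10^5$–$10^6$ parameter sets.

## Ensemble calibration

Calibration is a pure random search: draw parameter sets (log-uniformly for
rates, time constants and sensitivity; uniform integers 1–5 for the Hill
coefficient; rejection keeps $\lambda_f < \lambda_s$), simulate, score with
the range-normalised RMSE
$\varepsilon = \mathrm{RMSE}/(\max C_{obs} - \min C_{obs})$, and keep the
best 0.1%. The result is a *distribution* of good fits rather than a single
optimum, which is what the group comparisons consume. Two fixed-parameter
scenarios mirror the headline analysis: `fixed_KA` pins the adrenal
sensitivity at the control median 50.28, and `fixed_m` pins the Hill
coefficient at 2.

Identifiability is itself part of the analysis: on noiseless self-generated
data the composite gain $p_f\lambda_f + p_s\lambda_s$ is recovered far more
tightly than $p_f$ or $\lambda_f$ individually (the acceptance suite asserts
at least a two-fold ratio of relative IQRs under the fixed-sensitivity
scenario). With $K_A$ and $m$ free, even that composite is only identified
jointly with the drive: a lower $K_A$ trades against a lower gain, which is
why the recovery experiment is run in the fixed-sensitivity configuration.

## The synchrony battery

* **Hormone ratio** and **rolling Pearson correlation** (60-min centred
  window) describe time-local association.
* **TLCC**: Spearman correlation at every shift of a whole sampling step
  within ±180 min; positive peak lag means ACTH leads. Ties break toward the
  smallest absolute lag. Spearman is used for lag scans (robust to the
  heavy-tailed pulse amplitudes), Pearson for the rolling window.
* **RWTLCC**: the TLCC recomputed in rolling epochs. The package default is
  a 240-min window advanced by 30 min with a ±90-min lag range — a window
  must hold at least $2 \times \text{max lag} + 3$ samples for the scan to
  be defined, which a 180/180 combination on a 10-min grid would violate.
  The **stability score** is the fraction of epochs whose peak lag falls
  within one sampling step of the modal peak lag ("vertical stripe" = 1).
* **IPS**: both series are z-scored, band-passed to ultradian periods
  (60–480 min, order-2 Butterworth, forward–backward), and analytic-signal
  phases extracted via an FFT Hilbert construction. The synchrony trace is
  $1 - |\sin(\Delta\phi/2)|$, mapping phase agreement to 1 and antiphase to
  0. The formula is a stated convention: the analysis names the statistic
  but not its algebra.
* **Ultradian period**: first prominent positive autocorrelation peak after
  subtracting a 6-h moving average, falling back to the mean peak-to-peak
  interval for sparse-pulse records; constant or single-pulse records raise
  an undefined-period condition.
* **Pulse count**: local maxima with topographic prominence of at least 20%
  of the trace range and at least 60 min separation; boundary extrema are
  never counted because their prominence is undefined.

## Phenotype classification

Four ordered rules operationalise the qualitative groupings (thresholds all
config-exposed): one pulse → single-pulse; two pulses with period ≥ 240 min
and stability ≥ 0.7 → two-pulse; three or more pulses with period ≤ 210 min
and |lag| ≥ 40 min → multiple-pulse; three or more pulses with |lag| ≤
20 min and stability ≥ 0.7 → control-like. Anything else resolves to the
nearest rule under a normalised distance (1 pulse ≡ 60 min of period ≡
20 min of lag ≡ 0.2 of stability; undefined period counts as a fixed
2-unit deficit), with ties going to the earlier rule; the fired rule is
recorded in the call's `rule_trace`. The control-like class extends the
three patient phenotypes so healthy profiles are classifiable; by
construction it never applies to records with fewer than three pulses.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is checked.

* **Controls** (24 h): Gaussian ACTH pulses (SD 15 min) on an 8 ng l$^{-1}$
  baseline, inter-pulse intervals drawn from 150–180 min, amplitudes scaled
  by a raised-cosine 24-h envelope peaking at the record start (sampling
  starts in the morning). Cortisol comes from the model under the control
  calibration. Measurement noise is multiplicative (default SD 5% of
  signal) plus a small additive ACTH floor; crucially, the model is driven
  by the *observed* (noisy) ACTH, as in the real analysis where measured
  ACTH is the input — this is what lets rank-based lag statistics resolve
  the 10-minute delay on a 10-minute grid.
* **Two-pulse** (12 h): two tall, narrow ACTH bursts 300–360 min apart;
  model parameters control-like with slower cortisol clearance
  ($\lambda_s = 300$).
* **Multiple-pulse**: bursts every ~120 min with ±15% jitter (the jitter
  prevents the ~100-min dissociation lag from aliasing against the 120-min
  period in lag scans); increased adrenal sensitivity ($K_A = 35$); a
  constant extra ACTH→cortisol lag of ~100 min applied from late surgery
  onwards (partial synchrony).
* **Single-pulse**: one large excursion peaking ~2 h after surgery ends;
  higher slow production and faster slow turnover ($p_s = 3$,
  $\lambda_s = 80$); an unstable mode in which the dissociation lag wanders
  smoothly between 2-h epochs (the warp's slope stays below one so the
  excursion is displaced, never fragmented into spurious extra pulses).
* **Amplitude calibration**: patient ACTH bursts are tall and narrow rather
  than broad. With a saturating Hill drive this is the only way to satisfy
  both fold-change targets at once — a ~6× ACTH AUC increase against only a
  ~2× cortisol increase — because concentrating ACTH into saturated spikes
  raises its AUC without proportionally raising the drive's duty cycle. On
  the pooled panel the generator lands near 6× for ACTH and ~2–2.5× for
  cortisol; the residual excess on the multiple-pulse regime is the price of
  six bursts per record and is accepted rather than tuned away.
* **Cytokines**: smooth rise-and-decay humps starting at the surgery
  midpoint with mediator-specific peak times and gains (IL6 peaking latest,
  ~430 min after the midpoint, and largest at ~250 pg ml$^{-1}$). An
  optional coupling injects a cortisol disturbance proportional to a
  mediator's trace, which is how the residual-correlation analysis is given
  a known ground truth.

What the generator does **not** emulate: assay detection limits and
censoring, inter-assay drift, ragged or missing sampling, between-subject
parameter heterogeneity beyond seed-to-seed pulse-timing variation, and any
mechanistic cytokine→HPA feedback. Passing tests therefore demonstrate that
the pipeline recovers structure *of the kinds generated here*, not that it
is robust to every pathology of clinical data.

## The residual–inflammation analysis

Residuals are observed cortisol minus the best-fit (lowest-$\varepsilon$)
prediction under the fixed-sensitivity/fixed-Hill scenario. After z-scoring
(sample SD throughout), each subject's residual is correlated with each
mediator and with additive combinations (sum of individually z-scored
members, re-z-scored; default set: the four mediators, IL6+TNFα, and its
extensions by IL8/IL10). A PCA over pooled post-surgery-onset time points
(observations = time points, variables = z-scored mediators) identifies the
dominant mediators.

The discrimination experiment in the acceptance suite plants an IL6-coupled
disturbance (gain 6 nmol l$^{-1}$ per pg ml$^{-1}$) in a single-pulse
subject generated in *stable* synchrony mode. Two design points matter and
were settled by construction, not tuning-to-data: (i) the planted mediator
response must rise *and fall after the ACTH drive is spent* — a compact late
hump is outside the model's reachable set, whereas any disturbance coincident
with the excursion, or any sustained late plateau, is absorbed by the slow
compartment and never reaches the residual; (ii) the coupled subject is
generated without the unstable lag-warp, because the warp's unfittable
misfit produces a large dipole-shaped residual that would swamp the planted
coupling and turn the comparison into a test of warp amplitude. With the
warp left in (as in the full workflow's panel), single-pulse subjects still
show the strongest residual–mediator correlations — there the signal *is*
the dissociation itself.

## Problem sizes and determinism

Every random draw flows from an explicit integer seed through an isolated
RNG scope; identical seeds give byte-identical outputs, and the pipeline
never touches the caller's RNG state. The test and acceptance runs use
scaled-down search budgets chosen as the package's own defaults for
interactive work: $10^5$ draws for the recovery experiment (the full-budget
analysis uses $10^6$), $10^4$ draws per subject for residual fits, and
$2\times10^4$ draws per subject/scenario in the workflow scripts. Quantile
summaries, not single optima, are reported throughout, so the scaled budgets
change the tails of the kept-set distributions, not the comparisons drawn
from them.

## Known limitations

* The open-loop model cannot attribute ACTH-side disruption; it can only
  propagate it.
* The $\varepsilon$ cost is range-normalised RMSE; analyses whose original
  cost function differs will rank borderline fits differently.
* The classifier's thresholds are an operationalisation of qualitative
  descriptions; they are config-exposed and should be re-examined before
  applying the rules to data sampled at other rates or durations.
* Period estimation assumes at least two cycles in the record; 12-h records
  of 5–6-h rhythms sit at that boundary and rely on the peak-to-peak
  fallback.
* The residual-correlation analysis inherits the fit: a poor fit manufactures
  structured residuals whose correlations with smooth mediator humps can be
  substantial by chance (73 heavily autocorrelated samples), which is why
  qualitative claims there are framed as coupled-versus-uncoupled contrasts
  rather than absolute correlation values.
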