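---
title: "Harmonic force spectroscopy and myosin kinetics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonic force spectroscopy and myosin kinetics: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfskinetics)
```

## The measurement and the model

In a harmonic-force-spectroscopy (HFS) experiment an actin filament is
stretched between two trapped beads into a dumbbell and lowered onto a
surface sparsely decorated with single myosin motors, while the microscope
stage oscillates sinusoidally (200 Hz here). Because binding is stochastic
relative to the stage phase, each actomyosin interaction experiences a mean
load $F$ (assistive or resistive) plus a sinusoidal component of amplitude
$\Delta F$. Detachment is a thermally activated, load-sensitive step, so the
instantaneous detachment hazard of a bound head is

$$k(t) = k_0 \exp\!\left[-\frac{\delta\,(F + \Delta F\cos(2\pi f t + \phi))}{k_B T}\right],$$

with $k_0$ the unloaded detachment rate (s⁻¹) and $\delta$ (nm) the distance
parameter measuring force sensitivity. Averaged over one oscillation period
this hazard has the closed form

$$k_{det}(F, \Delta F) = k_0\, I_0\!\left(\frac{\Delta F\,\delta}{k_B T}\right) \exp\!\left(-\frac{F\,\delta}{k_B T}\right),$$

where $I_0$ is the zero-order modified Bessel function — the factor by which
the oscillation *raises* the mean detachment rate (Jensen's inequality: the
exponential hazard gains more on the downswing than it loses on the
upswing). `detachment_rate()` implements this form; `bessel_i0()` exposes
the correction factor.

Ensemble mechanics follow once the actin-activated turnover $k_{cat}$ and
the step size $d$ are known. Treating the ATPase cycle time $1/k_{cat}$ as
attached time $1/k_0$ plus detached time $1/k_{attach}$ gives the
force-independent attachment rate $k_{attach} = (1/k_{cat} - 1/k_0)^{-1}$
(`attachment_rate()`; it requires $k_{cat} < k_0$, and the constructors
refuse inconsistent inputs). The duty ratio, per-head ensemble force,
gliding velocity and average power are then

$$r(F) = \frac{k_{attach}}{k_{attach} + k_{det}(F)},\qquad
F_{av} = F\,r(F),\qquad v(F) = k_{det}(F)\,d,\qquad
P_{av}(F) = v(F)\,F_{av}(F).$$

Two exact identities anchor the implementation and its tests:
$r(0) = k_{cat}/k_0$, and $F_{av}/r \equiv F$.

## Physical constants and defaults

| Parameter | Default | Why |
|---|---|---|
| temperature | 23 °C ($k_BT = 4.0888$ pN·nm) | trap experiments run at room temperature; `trap_constants()` recomputes $k_BT$ from the temperature and refuses inconsistent overrides |
| stage oscillation | 200 Hz | standard HFS stage drive; must stay below a tenth of the sampling rate |
| trap stiffness | 0.09 pN/nm per trap | middle of the usual 0.08–0.10 pN/nm calibration range |
| sampling rate | 5 kHz | 25 samples per oscillation period, enough for clean demodulation at desk-scale data volumes |
| ensemble force grid | 0–10 pN resistive, 0.1 pN | cardiac ensembles work against load; assistive forces are plotted separately if needed |

Force sign convention everywhere: **positive = resistive**. The detachment
rate is strictly decreasing in resistive load and the Bessel factor is
$\ge 1$ with equality only at $\Delta F = 0$.

## The synthetic instrument

`simulate_events()` emulates the per-event table an HFS rig produces. Per
event: $F \sim U(-5, 5)$ pN, $\Delta F \sim U(1, 4)$ pN, binding phase
$\phi \sim U(0, 2\pi)$ — the experimental distributions of per-event loads
are not published, so these ranges are package choices representing a
typical spread of dumbbell geometries; they are stated once here and not
revisited. Dwell times are drawn *exactly* from the time-varying hazard by
thinning: propose exponential waiting times at the envelope rate
$k_0 e^{-\delta(F-\Delta F)/k_BT}$ (the hazard maximum, at the assistive
peak of the swing) and accept with probability $k(t)/k_{env}$. No
discretization is involved, so the empirical mean rate of $10^5$ draws
reproduces the Bessel-corrected closed form within Monte-Carlo error — the
central correctness check of the generator, asserted across a grid of
$(F, \Delta F, \delta)$ in the test suite.

Events shorter than `min_detectable_duration` (default two oscillation
periods, 10 ms) are dropped, because a detector that scores amplitude and
phase needs at least a couple of cycles. Displacements are the true step
plus Gaussian noise (1 nm default). Uniform binding phase is what makes the
period-averaged model valid; a numerical check during development showed
that at 200 Hz the inverse mean dwell differs from the closed form by about
0.1 %, far below the estimators' statistical noise.

`simulate_hfs_trace()` renders events into two-bead position records:
unbound beads follow the stage oscillation (25 nm baseline amplitude);
bound segments oscillate at amplitude $\Delta F/\kappa_{sys}$ with a phase
shift and a mean offset, plus Gaussian position noise (2 nm default), where
$\kappa_{sys}$ is the sum of the two trap stiffnesses (a deliberate
simplification of the series dumbbell compliance). The rendered mean offset
is $F/\kappa_{sys}$, so the detector convention *force = stiffness ×
offset* recovers the truth forces. A consequence worth stating: the
trace-level "displacement" is the load-bearing bead deflection, not an
independent working-stroke measurement. Recovering an uncoupled step size
from traces requires ensemble averaging against the oscillation phase,
which is out of scope here; step sizes in this package come from the event
tables, uncorrected for series compliance (and therefore smaller than the
true working stroke, as is conventional for uncorrected trap data).

Bulk-assay generators mirror the plate experiments: Michaelis–Menten means
with multiplicative lognormal replicate noise (mean-corrected so rates are
unbiased) and optional planted outliers; biexponential fluorescence decays
with plateau, dead time and additive noise; linear gel dilution series with
an optionally saturated heavy-chain top load.

### What the generator does *not* emulate

Brownian bead dynamics, trap anisotropy, actin compliance, surface drift,
multiple motors per dumbbell, photobleaching, and day/prep batch effects.
Passing the recovery tests therefore shows the estimators are correct *for
the assumed statistical structure* (exponential dwells under the stated
hazard, Gaussian position and displacement noise); it does not certify
robustness to instrument pathologies absent from the simulator.

## Event detection

`detect_events()` demodulates each bead position against in-phase and
quadrature references at the stage frequency over sliding windows (two
periods long, hopping half a window). Binding changes both the amplitude
and the phase of the bead oscillation, so the detection statistic is the
deviation of the complex oscillation phasor from its unbound baseline
(median phasor across the trace; scale from the MAD). This combines the
two signatures in one number and has a property the amplitude alone lacks:
it is linear in the fraction of a window covered by an event, so the
half-level crossing of the deviation profile locates event edges without
bias — an amplitude-only statistic proved to give edge errors of half a
window during development. Edges are refined in two passes (the bound
level re-estimated from windows fully inside the first-pass edges), with a
small Rician floor correction. Entry requires the deviation to exceed
`threshold_sigmas` (default 5) on *both* beads; exit uses hysteresis at
half the entry threshold. Segments shorter than `min_event_duration` are
discarded.

Per event, with $\kappa_{sys}$ as above: the mean force is $\kappa_{sys}$
times the mean bead offset from the unbound level, the sinusoidal amplitude
is $\kappa_{sys}$ times the bound oscillation amplitude, and the duration
comes from the refined crossings. Traces whose windows look bound more
than 80 % of the time are flagged: the median-phasor baseline is then
contaminated and the detector output untrustworthy (the expected unbound
behaviour — the stage oscillation itself — is used to recognise this).

## Dwell-time estimation and the model fit

A detector with dead time $t_{min}$ sees left-truncated exponential dwells.
By memorylessness the rate MLE is $\hat k = n/\sum_i (t_i - t_{min})$ with
$SE = \hat k/\sqrt n$ (`mle_bin_rate()`); at 200 Hz the truncation point is
a whole number of oscillation periods, which keeps the phase distribution
uniform at $t_{min}$ and the truncated law exact. Ignoring the dead time
(the `t_min = 0` estimator, available for comparison) is *downward* biased:
the surviving dwells are inflated by $t_{min}$, so
$E[n/\sum t] = 1/(t_{min} + 1/k) < k$. The test suite asserts this
direction.

`fit_hfs()` bins each molecule's events by mean load (1 pN bins, ≥ 5 events
per kept bin — chosen so a few-hundred-event molecule yields at least six
usable bins), estimates a rate per bin, and fits the Bessel-corrected Bell
model by weighted nonlinear least squares. Two numerical choices matter:

- **The fit runs on the log-rate scale with weights $n_i$.** Weighting raw
  rates by $1/SE^2$ looks natural but couples the weights to the sampling
  noise (the SE estimate is proportional to the observed rate), which in
  calibration runs biased $\hat k_0$ down by about 4 % at realistic bin
  occupancies. On the log scale the sampling variance is $\approx 1/n$
  independent of the rate, decoupling weights from noise.
- **The exact finite-sample offset of a log Gamma-MLE is subtracted.** For
  $n$ exponential dwells, $E[\log\hat k] - \log k = \log n - \psi(n)$
  ($\psi$ the digamma function) — about $+2.5\%$ at $n = 20$. Subtracting
  it makes the binned fit unbiased down to a handful of events per bin;
  calibration over 20 seeded replicates of a 10-molecule experiment
  recovers the group-mean $k_0$ within 1 % with 2-SEM coverage above 80 %.

A full per-event truncated-likelihood fit (`method = "mle"`), in which each
event contributes $\log k(F_i, \Delta F_i) - k\,(t_i - t_{min})$ with its
own Bessel factor, serves as the cross-check mode; binned and per-event
fits agree within 5 % ($k_0$) and 10 % ($\delta$) on large synthetic
samples, and the per-event mode is preferred after trace detection, where
heavy censoring leaves too few events per bin.

Group characteristic values are plain molecule averages — mean ± SEM for
$k_0$ and $\delta$, mean ± SD for the step — with Welch t-tests (each
molecule one replicate) for group contrasts and ratio-propagated SEMs for
percent changes. Molecules whose fit fails to converge or pins $\delta$ at
zero are excluded with a message, never silently.

## Ensemble curves and error propagation

`ensemble_curves()` evaluates the four curves on the resistive grid from
the point estimates, and propagates parameter uncertainty by Monte Carlo:
$10^4$ independent Gaussian draws of $(k_0, \delta, k_{cat}, d)$ at their
SEMs, truncated to the physical region $k_0 > k_{cat} > 0$, $\delta \ge 0$
by redrawing (a redraw rate above 20 % aborts — the uncertainty budget is
then inconsistent with the model's validity region). Bands are pointwise
16th/84th percentiles, seeded and reproducible. A first-order delta-method
propagation (`delta_method_bands()`) is the analytic cross-check; for
relative uncertainties under 10 % the two agree within 15 % of the band
half-width. Independence of the four parameter errors is an assumption
worth flagging: within a molecule $\hat k_0$ and $\hat\delta$ are
correlated, but group means are averaged across molecules, which justifies
treating them as independent to first order.

$\Delta F = 0$ in the ensemble detachment rate: the sinusoidal load is an
instrument artifact, not physiology, so the Bessel factor is switched off
by default (the `dF` argument re-enables it for instrument-facing
calculations).

## Bulk assays

**Michaelis–Menten.** Unweighted least squares of $v = k_{cat}A/(K_{app}+A)$
in rate space (plate-reader practice; a variance-weighted option exists).
Basal (zero-actin) wells are reported separately, never mixed into the
hyperbola. Within technical triplicates, a measurement is rejected when it
differs from *both* companions by more than 50 % of the companion value —
the companion, not the triplet mean, is the reference, which matters for
cases like {10, 16, 30} where 30 is rejected. At most one value per triplet
is dropped; if several qualify the one farthest from the median goes. At
the generator's 5 % noise this rejects well under 5 % of points. Fitted
$K_{app}$ beyond the highest tested actin concentration is flagged as an
extrapolation.

**Single-ATP turnover.** Five-parameter biexponential
$A_f e^{-k_f t} + A_s e^{-k_s t} + C$, fitted by Levenberg–Marquardt with
non-negative amplitudes after a rate-grid profile search for starting
values (amplitudes are linear given rates, so the grid search is cheap and
global). The slow fraction of the decaying amplitude,
$100\,A_s/(A_f+A_s)$, is the %SRX; the plateau is excluded from the
denominator — the alternative (including it) is not used because the
normalization convention pins the fitted intercept to 1 and the plateau to
0, which makes the decaying amplitude the natural base. "Ambiguous" fits
are operationalized as: rate separation under 3×, an amplitude 95 % CI
touching zero, or optimizer failure — single-exponential data therefore
come back flagged, not as exceptions.

**Gel stoichiometry.** Per chain, integrated density is regressed on load;
the highest load is greedily pruned while its removal improves $R^2$ by
more than 0.02 (at least 3 points retained) — the operational form of
removing saturated, non-linear top loads, which affects the heavy chain
first. Stoichiometries are slope ratios with ratio-propagated SEs; paired
t-tests against same-day controls use `paired_t_test()`.

**Degenerate statistics.** Identical zero-variance groups return
$t = 0, p = 1$ rather than erroring, so pipelines over synthetic edge cases
keep running.

## Problem sizes

The packaged validation runs at desk scale, chosen to finish a full test
cycle in about a minute while leaving the statistical assertions
well-powered: recovery simulations use 10 molecules × 150–300 events;
thinning checks use $10^5$ draws; the trace-level closure benchmark
simulates 10 molecules × 3000 attempted events (≈ 6000 detected after
censoring) and recovers $(k_0, \delta)$ within 10 %; Monte-Carlo
calibrations use $10^4$ replicates. The acceptance script's synthetic
experiment is 10 molecules × 300 events.

## Known limitations

- Step sizes carry no series-compliance correction and underestimate the
  true working stroke; trace-derived displacements are load deflections.
- The detector is a clean-room design against the stated contract
  (amplitude/phase change in both traps), not a reimplementation of any
  published instrument code; its force-from-offset rule is validated only
  against the package's own simulator.
- Left truncation handles detector dead time, but there is no
  deconvolution of duration measurement noise; the end-to-end benchmark
  bounds the residual bias at a few percent.
- Parameter-error independence in the ensemble bands is approximate, and
  $k_{cat}$ must be supplied externally (with its own SEM) — it is not
  estimable from trap data.
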