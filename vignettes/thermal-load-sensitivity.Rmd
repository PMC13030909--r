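---
title: "Thermal load sensitivity: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal load sensitivity: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermload)
```

## The problem

Early plant life stages — developing pollen, imbibed seeds, newly
emerged seedlings — are far more vulnerable to extreme heat than mature
vegetation, and they live in microclimates that standard weather data
do not describe: dry, sun-exposed soil can run 20 °C hotter than the
air at 1.2 m. `thermload` estimates heat failure probability for such
stages by integrating a damage–repair balance over height-resolved
temperature series.

## The model

### Thermal death time curves

Heat tolerance is not a single temperature: the tolerated temperature
declines log-linearly with exposure duration. We parameterise each
stage by

$$t_\mathrm{fail}(T) = t_\mathrm{ref}\,10^{(CT_\mathrm{max} - T)/z},$$

with `CTmax` the temperature tolerated for exactly `t_ref = 1` minute
and `z` (°C per decade) the sensitivity of tolerance to duration.
`fit_tdt()` estimates both by ordinary least squares of
`log10(failure time)` on assay temperature — failure time is the
measured response, so it sits on the left-hand side — and converts
slope/intercept to `(CTmax, z)` with delta-method standard errors. A
non-negative fitted slope is reported as an error rather than silently
returned: such data simply do not show TDT behaviour.

### Damage and repair

Instantaneous damage accrues at $d(T) = 1/t_\mathrm{fail}(T)$ per
minute, so constant exposure reaches total damage 1 exactly at the TDT
failure time. Repair follows an Arrhenius form

$$r(T) = r_\mathrm{ref}\,
  \exp\!\left[\frac{E_a}{k_B}\left(\frac{1}{T_\mathrm{ref,K}} -
  \frac{1}{T_K}\right)\right],$$

with $k_B = 8.617\times10^{-5}$ eV K$^{-1}$ and a default activation
energy $E_a = 0.65$ eV, a mid-range value for enzymatic processes. A
Gaussian-peaked shape is available as an alternative for repair
machinery with a thermal optimum, and `shape = "off"` disables repair.

Rather than asking users for an (unmeasurable) absolute repair rate,
`calibrate_repair()` anchors it: given a crossover temperature
`t_cross` (default 31 °C), `r_ref` is set so that repair and damage
balance exactly there. Below `t_cross`, temperatures are *permissive*
(net repair); above it, *stressful*. Because the damage slope
$\ln 10 / z \approx 0.77$ °C$^{-1}$ (for $z = 3$) far exceeds the
Arrhenius slope ($\approx 0.008$ °C$^{-1}$ near 30 °C), the crossover
is unique on any practical bracket, and the net damage rate escalates
by $10^{1/z} - 1 \approx 115\%$ per °C in the stressful range — the
physiological tipping-point behaviour the framework is built around.
`permissive_boundary()` recovers the crossover by bisection to
$10^{-6}$ °C.

One consequence of calibrating at 31 °C with a pollen-like curve
(`CTmax = 46`, `z = 3`) is that the absolute repair rate is small
(`r_ref = 1e-5`/min): full recovery from 50% damage under constant
permissive temperature takes on the order of weeks. Cool interludes
between heatwaves therefore repair only a few percentage points of
damage — which is precisely why residual damage "ratchets" across
recurrent heat events in the simulations.

### From damage to failure probability

The damage-to-probability map is a genuinely open modelling choice; we
use the simplest one with no extra parameters: $p = D$ clamped to
$[0, 1]$, with $p = 1$ absorbing (mortality is irreversible; no
post-failure repair). This reproduces all the qualitative behaviours
the framework calls for — decline under repair, ratcheting across
recurrent events, saturation at 1 — and is isolated in one place so a
hazard-based map could be swapped in. Population-level probability is
the arithmetic mean of individual probabilities (not the failed
fraction; the two converge as individuals saturate).

### Individual variation

`draw_population()` draws `n` individuals (default 100) with
independent normals $CT_{\max,i} \sim N(CT_\mathrm{max},
\sigma_{CT})$, $z_i \sim N(z, \sigma_z)$ truncated at $z \ge 0.5$. No
`CTmax`–`z` correlation is imposed (none is established). Defaults
$\sigma_{CT} = 1$ °C and $\sigma_z = 0.25$ give the "relatively minor"
between-individual spread typical of within-population tolerance
assays while still separating individual fates under marginal
exposures. When repair is specified as a crossover temperature, each
individual's repair is calibrated against its *own* TDT curve, so the
permissive boundary is a stage-level property shared by all
individuals; passing a single `repair_params` object instead shares
the absolute rate.

### Microclimate

Near-ground temperature is modelled as the 1.2 m air temperature plus
an excess

$$\Delta T(h) = a_0 \cdot \mathrm{solar} \cdot \mathrm{dryness} \cdot
  (1 - \mathrm{shade}) \cdot e^{-h/h_s},$$

with a small nocturnal deficit (default 2 °C at the surface) when
solar input is zero. This is deliberately *not* a soil energy-balance
model: it is a two-parameter surrogate calibrated to the printed
exemplar offsets of +20 °C at 0 cm and +8 °C at 1 cm under clear, dry,
unshaded conditions, which forces $a_0 = 20$ °C and $h_s = 1/\ln 2.5
\approx 1.09$ cm. Organ temperature is taken to equal microclimate
temperature at the organ's height (50 cm pollen, 1 cm seedling, 0 cm
imbibed seed); leaf-mode biophysics (radiation balance of the tissue
itself, wind, transpiration) is out of scope and a stated limitation.
Real microclimate model exports can be supplied as CSV
(`read_microclimate_csv()`), bypassing the surrogate entirely. Shade
is a single scalar per run, bounded at 0.6 (thin canopy); runs at 0%
and 60% shade bracket the exposure range.

## The synthetic weather generator

`generate_weather()` emulates the features the damage model is
sensitive to, with known ground truth:

* a smooth diurnal cycle: half-sinusoid rise from `tmin` at sunrise to
  `tmax` at 5/7 of the daylength after sunrise (15:00 for the default
  14 h daylength), quarter-cosine fall to `tmin` at sunset, linear
  night interpolation towards the next day's `tmin`;
* heatwave days (additive `tmax` boost) and rain days (solar proxy
  zero, `tmax` reduced, soil dryness reset to 0 with linear recovery
  over `dryness_recovery_days`);
* a solar proxy that peaks (value 1) at the same instant as the
  temperature, so that the surface-excess worked examples compose
  exactly (air max 30 °C → surface max 50 °C on a clear dry day).

It does **not** emulate: stochastic weather persistence, humidity/VPD,
wind, cloud other than the binary rain day, or within-day rain timing.
A green test against this generator therefore establishes correctness
of the damage arithmetic and plumbing under controlled forcing — not
realism of any particular site's climate. The bundled
`scenario_heatwave.yaml` fixture (10 days, mid-period heatwave, one
rain day, late recurrent heatwave, run under 60% shade in
`config_heatwave.yaml`) is an explicit stand-in chosen so damage
concentrates in the heatwaves and the rain-day repair and recurrence
ratcheting are visible; it is not a reproduction of any real weather
record. With the default stage parameters the shaded soil surface
still exposes seeds to thermal loads comparable to pollen's, so the
stages' final risks are closer together than their tolerances alone
would suggest — exactly the exposure-versus-tolerance trade-off the
height stratification is meant to surface.

TDT assays are generated with log-normal noise (normal on the log10
scale, default sd 0.1), matching the regression model of `fit_tdt()`
so that parameter-recovery experiments are well posed.

## Numerical choices

* **Integration.** The temperature series is piecewise-constant
  between samples (left-Riemann). Within each interval the net rate is
  constant, so the explicit-Euler sub-stepping limit has a closed
  form; we use it directly. Updates are exact at step boundaries
  (`D(t) = t / t_fail(T)` with repair off), and the crossing of
  `D = 1` is located exactly within the interval, so simulated
  constant-temperature failure times equal the analytic TDT value to
  machine precision. The `dt` argument is retained for interface
  stability but no longer trades accuracy for speed.
* **Clamps and absorption.** Damage is clamped at 0 (nothing to
  repair) and absorbed at 1 (permanent failure) at every step.
* **Bisection** for the crossover runs to `1e-6` °C and refuses
  brackets without a sign change (e.g. repair off) rather than
  returning an endpoint.
* **Degenerate inputs.** Fewer than two distinct assay temperatures,
  non-positive durations, non-finite temperatures, empty series,
  out-of-range solar/dryness, and unsorted strict-mode CSVs all raise
  classed errors (`tl_*`) that the CLI maps to exit status 2.
* **Determinism.** All randomness flows through explicit seeds; the
  pipeline derives per-stage sub-seeds by hashing the master seed with
  the stage name (kept below $2^{31}$), so adding a stage never
  perturbs another stage's draws, and reruns are byte-identical.

## Default stage parameters

| stage | height (cm) | CTmax (°C @ 1 min) | z (°C/decade) |
|---|---|---|---|
| pollen | 50 | 46 | 3.0 |
| seedling | 1 | 52 | 3.5 |
| imbibed seed | 0 | 58 | 4.5 |

These defaults are package choices, ordered to reflect the established
tolerance ranking (imbibed seeds most tolerant, pollen least, with
tolerance differences compressing at long exposures); every value is
overridable per run via the YAML config. The common repair crossover
default of 31 °C is likewise configurable per stage (`t_cross`), since
whether repair differs among stages is an open empirical question.

## Known limitations

* No soil heat conduction, humidity/VPD, wind or leaf energy balance;
  dryness is a single scalar acting on the surface excess.
* Damage and repair are phenomenological rates, not biochemical
  mechanisms (ROS, heat-shock proteins), and repair carries no
  energetic cost; priming/cross-tolerance effects are absent.
* The damage→probability identity map is an assumption; alternatives
  (e.g. a dose–response on `D`) would change absolute probabilities
  but not orderings driven by exposure.
* Population "probability" averages individual probabilities;
  fraction-failed is also reported in run summaries so users can pick
  either reading.
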