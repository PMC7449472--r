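---
title: "Calibrating carbonyl emissions to atomizer geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating carbonyl emissions to atomizer geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coiltox)
```

## The problem and the model

Thermal degradation of the e-liquid solvents propylene glycol and
glycerol at the heating coil produces a panel of toxic carbonyls:
formaldehyde, acetaldehyde, acetone, propanal, butyraldehyde and
benzaldehyde. How much a device emits depends on how its coil delivers
heat and how its wick replenishes liquid — quantities that vary by orders
of magnitude across commercial builds and are not captured by the power
setting alone.

`coiltox` predicts *relative* emission levels from three bench
measurements. The geometric score of a device is

$$\mathrm{score} = \frac{L}{SA \times n},$$

where $L$ is total coil wire length (mm), $SA$ the wick's outer surface
area (mm²), and $n$ the wraps per coil. The reasoning: coil length tracks
the thermal energy delivered to the wick (coil surface area would also
count heat shed to passing air); wick surface area sets how much liquid
can absorb that energy, cooling the contact zone; wrap count spreads the
contact, suppressing hot spots. Each effect is monotone, so their ratio
orders devices by expected degradation.

Measured emission factors $y$ — micrograms of total panel carbonyls per
gram of e-liquid consumed in a session — relate to the score through

$$y = a\,e^{b\,\mathrm{score}},$$

an exponential form motivated by the roughly exponential temperature
dependence of vaporization and degradation (Clausius–Clapeyron
behaviour). Normalizing by e-liquid consumed, rather than per puff,
absorbs most of the power dependence of aerosol production.

## Units and conventions

All geometry is fixed to mm and mm² at the boundary; readers convert.
Analyte amounts are micrograms per session; a session table may declare
`unit = "nmol"` and is converted through a fixed molar-mass table at read
time. Emission factors are µg/g.

Three conventions close gaps that bench practice leaves open:

* **Multi-coil aggregation.** For parallel and dual builds, wire lengths
  sum over the two wires and wick areas over the physical wicks, while
  wraps stay per-coil. This makes the score invariant under duplicating
  an identical coil+wick unit: a dual build scores exactly like one of
  its halves, so singles and duals sit on one axis. Inventories that
  record totals per coil instead can set `aggregation = "per_coil"` in
  `effective_geometry()` and the run functions.
* **Wick area.** Cylindrical wicks contribute lateral area
  $\pi d \ell$ only; the end faces abut the tank and are not heated
  contact surface. Non-cylindrical wicks supply a measured area.
* **Parallel coils.** Two wires share one wick; both lengths count, the
  wick counts once. No extra term models the zero inter-wire spacing —
  that effect is left to the data.

## Replicate screening

Devices are measured in at least triplicate; occasional sessions fail
high (burnt coil, bad resistance reading, irregular build). Screening
uses the two-sided Grubbs test on the per-session *normalized totals* of
one device (the downstream regression consumes totals, so per-analyte
screening would test a quantity the model never sees):

$$G = \max_i \frac{|y_i - \bar y|}{s}, \qquad
G_{crit}(n,\alpha) = \frac{n-1}{\sqrt n}
\sqrt{\frac{t^2_{\alpha/(2n),\,n-2}}{\,n-2+t^2_{\alpha/(2n),\,n-2}}}.$$

While $G > G_{crit}$ the single most extreme value is removed, never
taking the kept count below 2. Defaults: $\alpha = 0.05$, two-sided.
Ties in the extreme deviation resolve to the *larger* value, because the
physical failure modes are high-side. Zero-variance replicate sets (and
sets whose spread is pure floating-point jitter, below $10^{-10}$ of the
data magnitude) define $G = 0$: identical replicates contain no outlier.

A structural limitation worth knowing: with $k$ replicates the statistic
cannot exceed $(k-1)/\sqrt{k}$. At $k = 4$ that bound (1.5) sits barely
above $G_{crit}(4, 0.05) = 1.4813$, so a single gross outlier is caught
essentially always, but *two* co-occurring high outliers in one device
drag the mean and mask each other completely. Screening at small
replicate counts protects against isolated failures only; fleets where
multiple sessions fail simultaneously need more replicates, not a looser
$\alpha$.

## Calibration and evaluation

`fit_exponential()` offers two estimators.

* `method = "loglinear"` (default): OLS of $\ln y$ on the score;
  $a = e^{\hat\beta_0}$, $b = \hat\beta_1$. This is what spreadsheet
  exponential trendlines compute, and it is the exact maximum-likelihood
  fit under the multiplicative lognormal error model the data display
  (spread grows with the mean). Requires $y > 0$.
* `method = "nls"`: direct minimization of
  $\sum (y_i - a e^{b x_i})^2$ via Levenberg–Marquardt
  (`minpack.lm::nlsLM`), initialized from the log-linear solution. A
  convergence failure raises an error carrying the log-linear fallback.

Both report $R^2 = 1 - SS_{res}/SS_{tot}$ on the **original** scale so
the methods are comparable; the log-linear fit also reports the log-scale
$R^2$ that trendline software prints, since published values may follow
either convention. Degenerate cases are defined, not clamped: constant
$y$ at distinct scores yields $b = 0$, $a = \bar y$, $R^2 = 1$ (perfect
flat fit); constant scores are a degenerate design and error. Weights
default to none — matching the apparent treatment of visibly
heteroscedastic data in this field — with inverse-variance weighting
available as an option.

Predictive accuracy on an evaluation fleet uses the identity-line
coefficient of determination,

$$R^2_{pred} = 1 - \frac{\sum (y_i - \hat y_i)^2}{\sum (y_i - \bar y)^2},$$

with the predictions taken as-is rather than re-regressed. The choice is
forced by what the statistic must express: a candidate score whose
calibration transfers badly produces predictions *worse than the mean*,
and only this form goes negative there; a squared correlation cannot.
The evaluation set may overlap training (the reference design trains on
nine devices and evaluates all twelve); both id sets are recorded so
strict held-out evaluation is equally expressible.

`rank_models()` evaluates a registry of candidate scores — monomial
expressions over $L$, $SA$, $n$ and power $W$ — and sorts by descending
predictive $R^2$, breaking ties lexicographically by name for
reproducibility. Models that fail on a device (a power model on a fleet
without power settings) surface as failed rows rather than vanishing.
The monomial restriction (products, quotients, powers) covers every
printed candidate and keeps user-supplied expressions safe to evaluate
and dimensionally interpretable; score units only rescale $b$, never the
$R^2$ values.

## What the synthetic generator emulates

`synthetic_config()` encodes the study conditions all statistical
guarantees are stated under:

* **Fleet**: 12 devices, geometry sampled uniformly within plausible
  commercial ranges (wire 50–120 mm, 5–12 wraps, wick ⌀ 2–4 mm × 8–15 mm,
  10–80 W), styles mixed over single/parallel/dual × horizontal/vertical.
  These ranges give model-1 scores of roughly 0.02–0.5 mm⁻¹ and, with
  the defaults below, emission factors of about 6–230 µg/g — a realistic
  two-order spread.
* **Truth**: $y = a\,e^{b\,\mathrm{score}}$ with $a = 5$ µg/g, $b = 8$
  per score unit.
* **Noise**: multiplicative lognormal, $\sigma = 0.2$ on the log scale,
  4 replicate sessions per device. Multiplicative noise reproduces the
  field observation that high-emitting devices show larger absolute
  error bars (constant coefficient of variation); an additive option is
  deliberately omitted so every test states its noise law exactly.
* **Outliers**: high-side only — a ×20 multiplier applied per session
  with configurable probability — mimicking burnt-coil/dry-wick
  failures. The generator's truth table records every injected outlier.
* **Analyte split**: the session total divides across the six carbonyls
  in fixed proportions (0.30/0.40/0.10/0.08/0.07/0.05,
  formaldehyde/acetaldehyde dominant). The split never affects
  totals-based analysis; it exists so session files are structurally
  complete.
* **Determinism**: everything derives from the config seed. Noise and
  outlier draws are consumed for every session whatever the parameters,
  so two configs differing only in `outlier_rate` differ only where
  outliers strike.

What the generator does **not** emulate: puff topography, coil
temperature dynamics, analyte-specific chemistry, device-to-device
differences in the analyte split, or calibration drift in the analytical
chain. Passing tests therefore demonstrate that the *pipeline* recovers
the assumed data-generating process; they cannot certify the geometric
model against real devices beyond what the original measurements showed.

## Numerical choices

Problem sizes in the test suite and acceptance script were chosen as
standard simulation practice for this kind of estimator check: 200
fleets for parameter recovery, model selection and screening rates, 20
datasets for the grid-search cross-checks, a 101–201-point grid per
parameter. The grid-search minimizer used as an oracle is independent of
the fitting code and compares each estimator against its own objective
(original-scale SS for NLS, log-scale SS for log-linear OLS).

## Known limitations

* The amplitude $a$ is an extrapolation to score 0; with scores bounded
  away from zero, different estimators can disagree on $a$ by more than
  they disagree anywhere in the observed range. Compare fitted curves,
  not amplitudes.
* Grubbs masking at small replicate counts (above): session-level
  detection of co-occurring outliers is structurally impossible at
  $k = 4$.
* The score registry restricts expressions to monomials; candidates with
  additive structure are out of scope.
* Only the six-panel gas-phase carbonyls are modelled; particle-phase
  degradants and other variables known to influence degradation (coil
  material catalysis, additives, topography) are outside the model.
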