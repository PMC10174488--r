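---
title: "Methods: cell-cycle Markov modelling of drug combination responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-cycle Markov modelling of drug combination responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclecombo)
```

## The model

`cyclecombo` models a proliferating cancer cell population as a
discrete-time Markov process over three cell-cycle states: G0/G1 (state 1),
late G1/S (state 2) and G2/M (state 3). In each one-hour step a proportion
$M_i$ of the cells in state $i$ advances along the cycle; the rest stay
put. The G2/M to G0/G1 edge carries division, so each transitioning mother
contributes two daughters:

$$
\begin{aligned}
x_{1,t+1} &= (1 - M_1 - M_{1,\varphi})\,x_{1,t} + 2 M_3\, x_{3,t}\\
x_{2,t+1} &= (1 - M_2 - M_{2,\varphi})\,x_{2,t} + M_1\, x_{1,t}\\
x_{3,t+1} &= (1 - M_3 - M_{3,\varphi})\,x_{3,t} + M_2\, x_{2,t}
\end{aligned}
$$

where $x_{i,t}$ is the cell count in state $i$ at hour $t$ and
$M_{i,\varphi}$ is an optional per-hour death probability (zero without
drug). The engine propagates expected real-valued counts: the update
equations are the mean-field description of the underlying jump process,
and their linearity means all relative quantities are independent of the
seeding number. Integer stochastic sampling of the same process exists
separately in the synthetic-plate generator, where well-to-well noise is
the point.

Because the update is linear, the long-run behaviour is governed by the
dominant eigenvalue $\lambda$ of the $3 \times 3$ update matrix (the
hourly growth factor, with doubling time $\ln 2 / \ln \lambda$) and its
right eigenvector (the stationary distribution of cells over cell-cycle
phases during balanced growth). `growth_eigensystem()` exposes this
closed form; the simulation route and the eigen route agree and serve as
mutual checks.

## Growth calibration

Two experimentally accessible observables calibrate the three transition
probabilities of a cell line: the population doubling time $\tau_d$ and
the steady-state cell-cycle fractions. `fit_transition_params()` forms
the target count vector after 72 h of exponential growth from 100 cells,
$100\, e^{72 \ln 2 / \tau_d}$ split by the state fractions, and
minimises the sum of squared differences between that target and a 72-h
simulation started from 100 cells at the same fractions. Three
constraints (two independent fractions plus $\tau_d$) determine three
parameters, so the optimum attains essentially zero residual and is
unique in practice; the fit is repeated from five random starts drawn
uniformly on $[0,1]^3$ and a uniqueness flag records whether all starts
agree within $10^{-4}$.

The simulated-endpoint objective (rather than the eigen closed form) is
deliberate: it matches how the calibration is defined operationally, and
it leaves the eigen route free to act as an independent oracle in the
test suite. Built-in constraint sets for the U87 and U251 glioma lines
(doubling times 31.13 h and 24.93 h; fractions 0.602:0.235:0.163 and
0.581:0.225:0.194, with literature minimum/maximum variants for the
sensitivity sweep) ship as a plain-CSV fixture.

## Drug action

Each drug targets exactly one transition. Dose $D$ (µM) maps to an
effective transition probability through a Hill factor,

$$M_i(D) = M_{i0}\left(1 - \frac{(D/\mathrm{EC}_{50})^{n}}{1 + (D/\mathrm{EC}_{50})^{n}}\right),$$

and to a drug-induced death probability through a saturating hyperbola
with unit Hill coefficient,

$$M_{i,\varphi}(D) = E_{\max,\varphi}\,\frac{D/\mathrm{EC}_{50,\varphi}}{1 + D/\mathrm{EC}_{50,\varphi}}.$$

The death exponent is fixed at 1 by design; no extra parameter is
introduced. The packaged drug panel maps PD0325901 (MEK1/2 inhibitor) to
the G0/G1 exit, abemaciclib (CDK4/6 inhibitor) to the late G1/S exit and
TAK-960 (PLK1 inhibitor) to the G2/M exit; the mapping is configurable
for other drugs, but one drug per transition and one transition per drug
is a hard constraint of this release.

`relative_cell_count()` is the model's observable: the treated total
after 72 h divided by the untreated total, both simulations starting from
the no-drug stationary composition (cells settle into balanced growth
overnight before drug is added). Normalisation is to the vehicle control,
not to the seeded cell number; an absolute-count reading can be obtained
from the trajectories directly if needed.

## Single-drug fitting and model comparison

`fit_drug_params()` estimates $(\mathrm{EC}_{50}, n)$ and optionally
$(E_{\max,\varphi}, \mathrm{EC}_{50,\varphi})$ by least squares on mean
relative counts per dose, using multi-start Levenberg–Marquardt
(`minpack.lm::nls.lm`) under box bounds: both EC50s inside
$[10^{-5}, 10^{3}]$ µM and searched on the log10 scale, Hill coefficient
in $(0, 10]$, and $E_{\max,\varphi}$ capped so that
$M_i + M_{i,\varphi} \le 1$ holds at every dose. Default 20 starts with
EC50 starts log-uniform over the observed dose range and Hill starts in
$[0.3, 3]$; solver function/step tolerances are $10^{-15}$ so that
noise-free generate-and-refit experiments recover parameters to well
under 1%.

The objective is plain (unweighted) SSE. Standard-deviation-normalised
residuals enter only the likelihood used for AIC, where each residual is
scored against the standard normal density after dividing by its
experimental sd, floored at 1% of the mean so that noise-free data do
not produce infinite weights. `compare_aic()` pools log-likelihoods and
parameter counts over matched fit sets (three drugs by two cell lines
gives the 24- vs 12-parameter comparison) and reports
$\Delta\mathrm{AIC} = \mathrm{AIC}_{\text{death}} - \mathrm{AIC}_{\text{no death}}$,
negative values favouring the death terms.

## Combination prediction

`predict_grid()` evaluates the calibrated model at every dose pair of an
8×8 checkerboard with no refitting of any kind — the model object is
immutable after fitting, and prediction only reads it. Margins of the
predicted surface reproduce the single-agent curves exactly, and the
prediction commutes under swapping the drug pair. Default dose series
are the experimental ones: a 3.16-fold series from 0.001 to 10 µM
(plus vehicle) for single-drug assays, and a 4-fold series up to 5 µM
(PD0325901, abemaciclib) or 0.05 µM (TAK-960) for checkerboards.

One property deserves a caution. Although each drug's dose maps
monotonically onto its own rates, the *combination* surface is not
guaranteed to be monotone in every direction: when the partner drug
carries an active death term, increasing the upstream blocker's dose
holds cells in a state where they are safe from the partner's
state-specific killing, and the predicted relative count can rise very
slightly (order $10^{-3}$) along that axis. This is a real consequence
of arrest–death coupling in the model — the same sequential-blockade
logic that makes the pairs mildly antagonistic — and not a numerical
artefact; the test suite documents it rather than hiding it.

## Excess over Bliss

Synergy scoring follows the robust excess-over-Bliss recipe. Relative
counts become inhibition effects $y = 1 - \text{count}$. Every row and
every column of the 8×8 inhibition matrix is fitted with a
four-parameter logistic curve
$y = E_{\min} + E_{\max} (D/\mathrm{EC}_{50})^n / (1 + (D/\mathrm{EC}_{50})^n)$,
and each cell's final fitted inhibition is the mean of its row-fit and
column-fit values — 16 fits per grid, smoothing single-well noise.
Single-agent curves $y_A$, $y_B$ are read off the averaged surface at
the zero-dose margins (the spec of the method leaves open whether to use
the raw marginal fits instead; the averaged surface is used here for
internal consistency, and the difference is within fit tolerance on
smooth surfaces). The Bliss null is $y_A + y_B - y_A y_B$ and
$\mathrm{EOB} = y_{AB} - y_{\mathrm{Bliss}}$, positive meaning synergy.

4PL bounds are $E_{\min} \in [-0.5, 1]$, $E_{\max} \in [0, 1.5]$,
EC50 within (min nonzero dose)/10 to (max dose)×10, $n \in (0, 10]$ —
wide enough to tolerate noise and stimulation, tight enough to keep fits
in the physically meaningful inhibition range. Constant rows fall back
to a flagged flat fit. Two summaries are always reported: the mean EOB
(with SE) over all 64 cells, and over the 49 cells where both doses are
nonzero. The margins have EOB near zero by construction, so the all-cell
mean is diluted by roughly 49/64 relative to the interior mean; both
numbers are printed so the reader can pick the convention explicitly.

## The synthetic plate generator

`generate_plate()` emulates the experimental workflow so the entire
pipeline runs without external data: 500 cells seeded per well at the
stationary composition, 72 h of *integer* stochastic dynamics
(multinomial stay/transition/die splits per state per hour, division on
the G2/M exit), then staining arithmetic — total-stain count minus
dead-stain count is the live count. Noise has three components chosen to
resemble realistic well-level variability: per-nucleus detection with
probability 0.95, a common mean-1 lognormal per-well factor with 10% CV
scaling both stain counts, and a dead-cell pool of which only 50% remains
stainable (dead cells detach or lyse). Layouts follow the experimental
design: 10 dose levels in biological duplicate × technical triplicate
for single drugs, 8×8 checkerboards in biological triplicate for
combinations. Every well's random stream derives deterministically from
the single spec seed through the well index, so identical specs produce
byte-identical tables.

What the generator does *not* emulate: image segmentation and its
artefacts, plate-edge effects, spatial structure, contact inhibition or
medium exhaustion, drug degradation over the 72 h, and pipetting error
correlated across a dilution series. Passing recovery tests on this
generator therefore demonstrate correctness of the estimation machinery
under the stated noise model, not robustness to every failure mode of
real plates.

A consequence worth stating plainly: at this noise level (roughly 4–6%
effective standard error on per-dose means after replicate averaging),
the EC50 of a *shallow* dose-response curve (Hill coefficient near 0.5)
with a free death term is structurally weakly identified — distinct
parameter combinations fit the data near-equally well, and repeated
plate-level refits scatter well beyond 25% around the generator truth.
Steep responders (Hill coefficient near 3) recover reliably. The test
suite measures exactly this, and the recovery study over 50 seeded
plates is reported as observed.

## Numerical choices and degenerate inputs

* Time step fixed at 1 h; horizons must be integer hours (default 72).
* Rates validated so that $M_i + M_{i,\varphi} \le 1$; violations are
  hard errors at construction or rate-assembly time, not silent clamps.
* Eigen decomposition: among eigenvalues sharing the spectral radius
  (the rigid cycle $M = (1,1,1)$ has a complex pair on the circle), the
  real nonnegative Perron root is selected; blocked cycles (some
  $M_i = 0$) report a non-growing factor and an infinite doubling time
  instead of failing.
* All nonlinear fits: Levenberg–Marquardt with box bounds, ftol/ptol
  $10^{-15}$, EC50-type parameters on the log10 scale; reported
  parameters are the best of the multi-start set by SSE, and fits are
  bit-reproducible given the seed.
* Zero doses are stored as literal 0 (the 4PL and Hill forms evaluate
  exactly to their zero-dose limits); log-axis plots place the control
  at a display offset without touching the data.
* Dose units are µM internally; CSV readers accept a `dose_unit`
  column (`nM`/`uM`) and convert on ingestion.

## Problem sizes used by the test and acceptance suites

Deterministic checks run the 72-h horizon at the full dose series.
Stochastic checks use 300 replicate wells (unit tests) and 1000 wells
(acceptance) for the law-of-large-numbers comparison, and 50 seeded
plate-generation/refit repetitions for the EC50 recovery study —
sizes chosen so each check is statistically meaningful while the whole
suite stays comfortably interactive.

## Known limitations

* Fixed three-state cycle; no arbitrary networks, no additional fates
  (senescence, reversible quiescence), no spatial or co-culture effects.
* One drug per transition and one transition per drug; no time-varying
  or sequential dosing, no pharmacokinetics.
* Combination surfaces can be very slightly non-monotone along one axis
  when the partner drug kills from its target state (see above).
* Multi-start spread is the only uncertainty measure for calibration;
  no profile likelihoods or posteriors for the drug parameters.
* EOB summaries quantify deviation from Bliss independence only; Loewe,
  HSA, ZIP and Chou–Talalay indices are out of scope.
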