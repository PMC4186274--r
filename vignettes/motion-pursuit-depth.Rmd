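---
title: "Modelling perceived depth from motion parallax: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perceived depth from motion parallax: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parallaxdepth)
```

## The problem

When an observer translates laterally while fixating a point in the scene,
objects nearer or farther than fixation slide across the retina. The retinal
speed of a non-fixated point, $d\theta$ (deg/s), together with the
compensatory eye-rotation speed that maintains fixation, $d\alpha$ (deg/s),
geometrically determines relative depth through the motion/pursuit law

$$\frac{d}{f} = \frac{d\theta}{d\alpha}\cdot\frac{1}{1 - d\theta/d\alpha},$$

with $f$ the viewing distance (cm) and $d$ the depth of the point relative
to fixation (cm). For the small motion/pursuit ratios used in
depth-matching experiments ($d\theta/d\alpha \le 0.25$) the first-order
approximation $d/f \approx d\theta/d\alpha$ is conventionally used as the
geometric prediction; both forms are exposed (`exact_relative_depth()`,
`approx_depth()`), with the first-order form as default prediction because
the standard worked example (ratio 0.25 at 36 cm giving 9 cm) uses it.
Ratios at or above 1 have no depth interpretation and raise errors; this
package works with depth magnitudes only (the peak-to-trough matching task
does not distinguish near from far sign).

Human observers, however, see far less depth from motion parallax than this
geometry predicts — roughly an order of magnitude less. The package's core
model is the *empirical* motion/pursuit ratio, which passes each rate
through a power-law transducer before combination:

$$d_{mp} = k\, f\, \frac{d\theta^{\,r}}{d\alpha^{\,e}},$$

with dimensionless exponents $r$ (retinal motion) and $e$ (pursuit) and a
scaling constant $k$ whose value is tied to the angular unit of the rates.
Defaults are $r = 0.416$, $e = 0.192$, $k = 0.0313$ with rates in deg/s
(`transducer_model()`); converting rates by a factor $c$ rescales
$k' = k / c^{\,r - e}$ and changes nothing else (`rescale_model()`). Because
$r > e$, increases in retinal motion raise perceived depth faster than
increases in pursuit speed; at a fixed motion/pursuit ratio, perceived
depth grows as $d\alpha^{\,r-e}$. (The literal statement "increasing in
$d\alpha$" is only true at fixed ratio; at fixed $d\theta$ the model
decreases in $d\alpha$, and the test suite asserts the fixed-ratio
version.)

Perceived depth magnitude is measured against a binocular disparity
comparison stimulus. Disparity $\delta$ (arcmin) converts to depth via the
small-angle distance-square law $d = f^2 \delta / i$
(`disparity_to_depth()`), with inter-ocular distance $i$ defaulting to the
standard adult 6.5 cm — a value chosen because it reproduces the printed
control-condition depths (1.35 cm at 36 cm, 1.08 cm at 72 cm) exactly; it
is overridable everywhere it appears.

## Psychometric estimation

Each stimulus is paired with 9 disparity levels of the comparison stimulus
in a 2IFC task ("which interval had more depth?"). Proportions of "stereo
deeper" responses are aggregated over blocks and pooled over leftward and
rightward translations (`aggregate_trials()`), then fitted with a
two-parameter cumulative normal $\Phi((\delta - \mathrm{PSE})/\sigma)$ by
unweighted nonlinear least squares (`fit_cumulative_normal()`). The PSE is
the 50% point: the disparity whose depth matches the motion-parallax
stimulus, so $d_{mp} = f^2\,\mathrm{PSE}/i$ (`pse_to_depth()`); $\sigma$
converts the same way into a depth discrimination threshold
(`sigma_to_depth_threshold()`).

Numerical choices:

* Optimisation is Nelder–Mead on $(\mathrm{PSE}, \log\sigma)$ (the log
  keeps $\sigma$ positive) at `reltol = 1e-14`, followed by a BFGS polish;
  the better of the two is kept. Initial values come from linear
  interpolation of the first 0.5 crossing and a quarter of the level range.
  Because initialisation and objective transform exactly under shifts and
  scalings of the disparity axis, the fit is shift- and scale-equivariant
  to optimizer tolerance.
* No lapse or guess parameters are fitted: the analysis reports only PSE
  and $\sigma$, and the data regime (proportions spanning 0 to 1 over 9
  levels) does not constrain a lapse rate usefully.
* Degenerate data are flagged rather than fitted: flat proportions return
  `converged = FALSE`; data that never cross 0.5 are marked
  `extrapolated`, as is any PSE outside the tested levels. Unconverged
  fits refuse to produce depth estimates.
* A binomial probit GLM (`method = "probit"`) is available as a
  likelihood-based alternative; it is a cross-check and robustness option,
  not the default estimator.

## The synthetic observer

No trial-level data are distributed with the experimental design this
package models, so the package carries a seeded generative observer
(`simulation_config()`, `simulate_trials()`) that produces sessions with
the statistical structure the analysis assumes:

* **Stimulus grid.** Six conditions — four head-stationary (36, 54, 72 cm,
  with two pursuit-speed ranges at 36 cm) and two head-translating (36,
  72 cm) — each with 13 $(d\theta, d\alpha)$ stimuli and 9 disparity
  levels (1–9 pixels at 0.244 mm/pixel), i.e. 117 trial types per block,
  20 blocks per condition, 7 observers. The published design states the
  ranges (ratios 0.042–0.25, pursuit 1.1–11.57 deg/s, retinal motion
  0.14–1.65 deg/s) and several anchor values but not the full 13-stimulus
  assignment; `default_stimulus_pairs()` is therefore a *declared* default
  that contains every printed anchor (including the 4.95 deg/s speed in
  both 36 cm stationary conditions) and interpolates the rest, keeping
  stationary $d\theta$ inside the printed range.
* **Response model.** On each trial the observer forms an internal
  motion-parallax depth $d_{mp}\,\varepsilon_1$ and an internal stereo
  depth $d_{stereo}\,\varepsilon_2$, with independent mean-1 lognormal
  noise per interval (no inter-trial learning, per the 2IFC independence
  assumption), and reports whichever is larger. Noise is multiplicative
  because depth is positive and discrimination is Weber-like; the default
  coefficient of variation 0.15 puts fitted $\sigma$ values in the
  1–3 arcmin range reported for this task, and is overridable.
* **Head translation.** Translating trials draw a per-trial head speed
  (truncated normal, mean 11.0 cm/s at 36 cm and 12.1 cm/s at 72 cm, SDs
  0.9 and 1.2 cm/s, emulating a self-paced ~0.5 Hz translation) and
  convert it to a total compensatory eye speed. Only the pursuit fraction
  of that signal — default `pursuit_gain = 0.4`, since the translational
  VOR is reported to contribute about 60% of gaze stabilisation — is
  available to the depth mechanism. The stimulus maintains its nominal
  motion/pursuit ratio on every trial, and the effective signals entering
  the depth computation are $d\alpha_{\mathrm{eff}} = g \cdot
  d\alpha_{\mathrm{total}}$ with $d\theta_{\mathrm{eff}} =
  \mathrm{ratio}\cdot d\alpha_{\mathrm{eff}}$. This makes a translating
  stimulus behave exactly like a stationary one at the pursuit-scaled
  rate, which is the empirically observed equivalence; the alternative
  (full retinal $d\theta$ with only $d\alpha$ reduced) would predict
  *more* depth during head translation, contrary to observation, because
  the model decreases in $d\alpha$ at fixed $d\theta$.
* **Depth-constancy control.** Two simultaneous-comparison conditions
  across a doubling of distance (standard 23.3 arcmin at 36 cm vs variable
  at 72 cm; standard 4.66 arcmin at 72 cm vs variable at 36 cm), 9
  observers, 2 blocks of 90 trials. Three observer models: perfect
  constancy (distance-square law with true distances), disparity matching
  (ignores distance; a four-fold depth mismatch), and a fractional
  distance mis-estimate applied to the variable stimulus (overestimated at
  36 cm, underestimated at 72 cm), which shifts the PSE by the squared
  factor.

What the generator does **not** emulate: ocular-motor dynamics (pursuit
latency and gain curves), fixation error, stimulus rendering (dot density,
contrast), sequential dependencies, lapses, and between-observer parameter
heterogeneity (all synthetic observers share one transducer). Passing
recovery tests therefore show that the *analysis pipeline* is consistent —
that it recovers the parameters of data generated under its own
assumptions at the study's trial counts — not that those assumptions hold
for human observers.

## Transducer estimation

Converged depth matches $d_{mp}$ from the head-stationary conditions enter
an unweighted ordinary least-squares fit of

$$\ln(d_{mp}/f) = \ln k + r \ln d\theta - e \ln d\alpha$$

(`fit_empirical_mpr()`; natural logarithms throughout). Whether the
original analysis weighted the 52 condition-level means by their SEs is
unstated, so the default is unweighted with an optional `weights`
argument. Points with non-positive or unconverged $d_{mp}$ cannot enter a
log fit and are excluded with a warning and a count; a rank-deficient log
design (collinear $\ln d\theta$, $\ln d\alpha$) is an error naming the
deficiency. The coefficient $R^2$ is reported; on noiseless
model-generated data the plane is an interpolation ($R^2 = 1$,
coefficients exact to numerical precision). The hypothetical
stereo-distortion correction multiplies each match by the linear
perceived/veridical ratio $2.015 - 0.011 f$ before refitting
(`johnston_adjust_and_refit()`); a distance-independent scaling provably
moves only $k$, while the distance-dependent default also moves the
exponents.

## Pipeline and screening

`run_full_pipeline()` chains simulation, per-observer fitting, outlier
screening, group fitting, plane fitting, the head-translating pursuit
decomposition (inverting the fitted model at each translating stimulus for
the equivalent stationary pursuit speed, reported as a percentage of the
total via `pursuit_fraction()`), and the control analysis, deterministically
given a seed.

The outlier rule "PSEs more than 3 SD from the group means" does not define
how deviations aggregate across conditions and stimuli, so the rule here is
declared: per (condition, stimulus) cell, an observer's PSE is compared
against the leave-one-out mean and SD of the remaining observers
(|z| > 3, strict); an observer is excluded when a strict majority of its
cells are flagged. Leave-one-out statistics are used because a single
aberrant observer inflates an inclusive group SD enough to mask itself at
realistic group sizes; both the SD threshold and the majority fraction are
configurable. With fewer than 3 observers screening is skipped with a
warning.

Group depth estimates are computed two ways — a fit to the pooled
proportions of retained observers, and the mean of per-observer estimates —
and the two agree within a couple of percent at the default trial counts,
which the test suite asserts at the condition-mean level.

## Problem sizes and tolerances

The test suite exercises the pipeline at sizes chosen to balance
statistical resolution against runtime: structural tests use 2–3 observers
and a few blocks; recovery assertions use the full 52-stimulus
head-stationary design with 7 observers and 20 blocks over 10 seeds
(transducer recovery within ±0.05 on the exponents and ±20% on $k$), 500
Bernoulli replicates at 20 trials/level (PSE bias < 2%, $\sigma$ bias
< 10%), and 100–300 blocks for single-stimulus monotonicity and
equivalence checks. Exact identities (normal equations, unit rescaling,
disparity round trips) are asserted at $10^{-8}$–$10^{-12}$. One
identifiability caveat: with zero noise the responses form an exact 0/1
step across disparity levels, so the PSE is only identified to within one
level spacing; the corresponding test asserts bracketing, not point
recovery. The plane-fit $R^2$ of noisy synthetic sessions is reported but
deliberately never asserted against the published 0.875, because the
noise level of the real observers is unknown.

## Known limitations

* The 52 published depth-match points themselves are not redistributable
  here; all quantitative recovery claims are therefore about synthetic
  sessions. A CSV import path (`read_trials()`) accepts transcribed real
  data in the same dialect.
* The linear stereo-distortion scaling is an extrapolation below its
  calibrated distance range and its printed coefficients imply a unity
  crossing near 92 cm (not the otherwise-reported 96 cm); the package
  evaluates the printed coefficients as given and does not force
  agreement.
* The empirical model is calibrated for ratios 0.042–0.25 at 36–72 cm;
  nothing constrains its extrapolation to large distances or large ratios,
  and `exact_relative_depth()` diverges as the ratio approaches 1.
* Signed (near vs far) depth, adaptive staircases, lapse modelling and
  bootstrap confidence intervals are out of scope.
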