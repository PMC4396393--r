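---
title: "Models and methods behind trxss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trxss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trxss)
```

trxss analyses femtosecond pump–probe X-ray solution scattering of
photoexcitable proteins. This vignette documents the models the package
implements, the choices made where the design was genuinely open, the
parameters that matter with their defaults and units, and the known
limitations — in particular what the synthetic-data generator does and
does not emulate, and hence what a passing test suite does and does not
demonstrate about real beamline data.

## The structural-response model

After photolysis of the chromophore–ligand bond, the protein's global
shape parameters respond on the picosecond scale. The generator (and the
kinetic fitter, which shares the same closed form) models each
observable as a step plus a damped cosine, convolved with a Gaussian
instrument response function (IRF):

$$
f(t) = \mathrm{IRF}_\sigma \ast \Big[ H(t - t_0)\,\big(A +
A_{osc}\cos(2\pi (t-t_0)/T + \varphi)\, e^{-(t-t_0)/\tau}\big) \Big]
$$

For the radius of gyration the defaults are a 1 Å step with a 0.3 Å
oscillation of period 3.6 ps and decay time 6 ps. The protein volume
follows the same family with its step delayed by `vp_delay` (default
1 ps — the volume expansion lags the mass redistribution), a 220 ų step
amplitude, a 60 ų oscillation, and an additional exponential relaxation
(time constant `tau_relax`, default 20 ps) from the step level toward a
small residual expansion (`dVp_residual`, default 20 ų), so that by
100 ps the volume has settled ~20 ų above its ground state. The IRF
FWHM defaults to 0.5 ps, the experimental time resolution of the
femtosecond X-ray source this emulates.

Two generator amplitudes are not published quantities: the oscillation
amplitudes of R~g~ and V~p~ (only the fitted period and decay are
printed in the source experiment). The defaults, 0.3 Å and 60 ų, make
the oscillation visually comparable to its step — large enough to be
recoverable, small enough not to dominate — and both are plain
arguments of `trajectory_params()`. `tau_relax = 20` ps reproduces
"relaxed by a few tens of ps" while leaving the 100 ps value within a
few ų of the residual plateau.

### Numerical evaluation of the IRF convolution

Both the step and the damped cosine are convolved with the Gaussian IRF
in closed form. Writing the damped cosine as the real part of
$e^{i\varphi} e^{-k(t-t_0)}$ with complex rate $k = 1/\tau - 2\pi i/T$,
the convolution of $H(t)e^{-kt}$ with a Gaussian of s.d. $\sigma$ is
$\tfrac12 e^{\sigma^2k^2/2 - k\Delta t}\,\mathrm{erfc}\!\big(
(\sigma^2 k - \Delta t)/(\sigma\sqrt2)\big)$, evaluated through the
scaled complementary error function of complex argument so that the
exponentials never overflow (the combined exponent collapses to
$-\Delta t^2/2\sigma^2$). For moderate arguments the scaled function is
computed from the series complex error function; beyond $|z| = 4$ a
Laplace continued fraction takes over. The closed form is verified in
the test suite against brute-force numerical quadrature of the
convolution integral to ~10⁻¹⁰, and `irf_fwhm = 0` disables the
convolution entirely (the response is then the exact discontinuous
model).

## The scattering model and reduction

A laser-on frame at delay $t$ is generated as the Guinier term plus a
time-independent solvent background,

$$
I(q) = (\Delta\rho\,V_p)^2 e^{-q^2 R_g^2/3} + B(q), \qquad
\Delta\rho\,V_p = N_e - \rho_b V_p,
$$

with the electron count $N_e$ = 9,900 e and buffer density $\rho_b$ =
0.34 e Å⁻³ held fixed. $B(q)$ is a broad water-like peak centred near
2 Å⁻¹; its only structural role is to give the normalization window
(1.4 ± 0.1 Å⁻¹) realistic, protein-free signal. Because the Guinier
term is utterly negligible at 1.4 Å⁻¹ for a ~17 Å protein, laser-on and
reference frames normalize to the same level and the sub-percent
photoinduced difference survives the subtraction — that is the physical
point of normalizing there, and the package's end-to-end test verifies
that a noiseless simulated run reduces to the analytic two-state
difference curve to within 0.1% of its peak amplitude at every delay.

Reduction choices that the underlying experiment leaves open:

* **Normalization statistic.** "Normalized at 1.4 ± 0.1 Å⁻¹" does not
  specify mean vs integral; the package uses the window mean (for
  patterns on a common grid the two differ only by a constant). Window
  centre and half-width are configurable.
* **Difference-then-screen order.** Differences are formed per laser-on
  frame against its nearest interleaved reference (ties toward the
  earlier one), and the *differences* are screened — corrupted shots
  distort a difference far more, relative to its amplitude, than an
  absolute pattern.
* **Iterated screen.** The reduced-χ² screen (threshold 2.0, not a
  published value; configurable) recomputes the accepted-set mean after
  each rejection round until a fixed point. A single-pass variant is
  available (`iterate = FALSE`). With the default contamination (20% of
  repetitions carrying a smooth ~2% multiplicative distortion against
  0.1% per-bin noise) the screen separates corrupted from clean frames
  by orders of magnitude in χ²~red~, so the rejection fraction equals
  the planted fraction and lands in the 15–25% band reported for the
  real experiment — a consistency check, not an independent validation,
  since the contamination rate is ours to choose.
* **Uncertainty of the averaged difference.** Laser-on frames in a block
  share their paired reference, so the differences at one delay are not
  independent; the naive standard error of the mean understates the
  uncertainty by roughly $\sqrt{1 + r}$ with $r$ the
  frames-per-reference ratio. The package instead propagates the stated
  per-frame uncertainties through the pairing weights. Monte-Carlo
  replicates in the test suite confirm the resulting ΔR~g~/ΔV~p~ errors
  match the replicate scatter within a few percent (the asserted
  tolerance is 30%).

## Difference-Guinier fitting

`fit_difference()` minimises the error-weighted squared residual of the
two-state model over a low-q window, default 0.02–0.08 Å⁻¹ (so that
$qR_g \lesssim 1.4$, inside Guinier validity; the experiment's exact
SAXS fit range is not published). Free parameters are ΔR~g~ and ΔV~p~;
1-s.d. errors come from the unscaled covariance $(J^TWJ)^{-1}$, which
is the calibrated choice when the stated per-point uncertainties are
trustworthy.

The ground-state volume $V_{p0}$ cannot be measured from difference
data; the default 23,000 ų corresponds to a typical protein electron
density ($N_e/V_{p0} \approx 0.43$ e Å⁻³) and is configurable. A global
amplitude α (the photoexcited fraction) is fixed at 1 by default —
difference patterns reduced by this package carry their normalization
factor, so their absolute scale is known; for data of unknown scale
`free_alpha = TRUE` fits α, with the caveat that α trades against ΔV~p~
(both scale the difference amplitude; only the q-dependence separates
them).

## Kinetic fitting and identifiability

`fit_kinetics()` fits the step-plus-damped-cosine to a
(delay, value, error) series by weighted least squares. The surface is
multimodal in period and phase, so the optimiser multi-starts over a
period × phase grid (1–8 ps × four phases by default), pre-ranks the
starts by their initial deviance, polishes the winners, and returns the
best. Box constraints keep the solution interpretable: the period is
bounded below by twice the finest delay spacing (anything smaller is a
sub-Nyquist alias) and both the period and decay time are bounded above
by the series span (a decay longer than the observation window is
indistinguishable from no decay). Solutions pinned at the decay bound
are flagged, as are fits whose oscillation amplitude is consistent with
zero. The fitted phase is reported in (−π, π] with a non-negative
amplitude, and the IRF width is fixed at 0.5 ps by default (it is an
instrument property, measured independently in the real experiment).

One identifiability property deserves emphasis, because it sets what
parameter-recovery tests can show. With the default study conditions —
0.3 Å oscillation, 0.1 Å noise, delays every 0.5 ps out to 10 ps and
every 5 ps beyond — the *period* is recovered to within 10% in the
large majority of replicates, but the oscillation *decay time* is
weakly identified: the envelope has decayed into the noise after
~2 periods, the late sparse points undersample the oscillation, and the
likelihood in τ is nearly flat beyond ~10 ps. Across seeded replicates
the reported 1-s.d. error on τ is typically ~4 ps against a generating
value of 6 ps, the generating value lies within 1 reported s.d. in
~80% of replicates, and a sizable minority of replicates run to the
span bound. This is a property of the measurement design, not of the
optimiser: no estimator extracts a sharp τ from these conditions. The
error-calibration test therefore checks 1-s.d. coverage (~68%) in a
lower-noise regime (0.03 Å) where the likelihood is unimodal and the
covariance errors are meaningful, and the recovery tests assert the
period sharply but the decay time only through its reported
uncertainty.

The oscillation-only variant (`include_step = FALSE`) supports series
whose equilibrium has already been subtracted, mirroring the published
description of the fitted curve as "a damped oscillation around the
equilibrium value"; the default fits step and oscillation jointly.

## The elastic sphere in a fluid

The observed volume/R~g~ oscillation is compared against the breathing
(spheroidal, angular order 0) modes of a homogeneous elastic sphere
immersed in a fluid — order 0 because a volume oscillation is a pure
monopole. Displacements inside the sphere derive from the scalar
potential $j_0(k_l r)$; imposing continuity of radial traction and
velocity at the surface against an outgoing monopole sound wave in the
fluid gives the characteristic equation

$$
d_P v_l^2\, j_0(s) \;-\; 4 d_P v_t^2\, \frac{j_1(s)}{s}
\;-\; i\, v_l\, Z(s)\, j_1(s) \;=\; 0,
\qquad s = \frac{\omega R}{v_l},
$$

with the pulsating-sphere radiation impedance
$Z(s) = d_m v_m \, i k_m R/(i k_m R - 1)$, $k_m = \omega/v_m$, in the
$e^{-i\omega t}$ convention. For $d_m = 0$ the impedance vanishes and
the equation reduces to the classical free-sphere (Lamb) breathing-mode
equation with real roots — the package's vacuum-limit test checks the
solver against an independent real-axis bisection of that closed form.
With fluid loading the roots move into the lower half plane:
$\mathrm{Re}\,\omega$ gives the oscillation period $2\pi/\mathrm{Re}\,
\omega$ and $\mathrm{Im}\,\omega < 0$ the radiative damping time
$\tau_D = -1/\mathrm{Im}\,\omega$. (The damping relation is
implemented as $-1/\mathrm{Im}\,\omega$, the only dimensionally
consistent reading of the published relation, and the one that
reproduces the published picosecond damping times.) The characteristic
function satisfies $F(-\bar s) = \overline{F(s)}$, so physical roots
come in $(s, -\bar s)$ pairs and only the $\mathrm{Re}\,s > 0$ member
is reported.

Roots are located by a coarse scan of $|F|$ over a box in the lower
half s-plane (default Re s ∈ [0.1, 12], Im s ∈ [−3, 0], 600 × 150
grid), refining every local minimum with Muller's method, discarding
residuals above 10⁻¹⁰, deduplicating within 10⁻⁶ and sorting by real
frequency. Purely relaxational (overdamped) solutions near the
imaginary axis — the fluid-loaded problem has one — fall outside the
box's lower real edge and are excluded: they are not vibrational modes.
Two grid resolutions agreeing to 10⁻⁸ and the exact doubling of every
frequency under halving of R are asserted in the tests.

### Material parameters

The experiment's supplementary material-parameter table is not
reproducible from the text, so `mb_sphere_material()` ships a
reconstructed, literature-guided set, every value overridable:

| parameter | default | basis |
|---|---|---|
| R | √(5/3) · 17 ≈ 21.95 Å | uniform sphere with the protein's R~g~ = 17 Å |
| v~l~ | 2000 m s⁻¹ | the ~20 Å ps⁻¹ strain propagation speed the R~g~ rise itself implies |
| v~t~ | 1000 m s⁻¹ | v~t~/v~l~ = ½, i.e. Poisson ratio ⅓, typical of globular proteins |
| d~P~ | 1350 kg m⁻³ | standard protein mass density |
| d~m~, v~m~ | 1000 kg m⁻³, 1483 m s⁻¹ | water at room temperature |

With these values the three lowest breathing modes have periods
2.73 / 1.15 / 0.75 ps and damping times 1.24 / 1.69 / 1.74 ps — all
within 5% of the published model results, which is the tolerance the
acceptance suite asserts. The agreement across all six numbers from
four independently-motivated physical inputs is the justification for
the reconstruction.

## Problem sizes used by the tests and acceptance script

Monte-Carlo tests use 200 replicates (Guinier bias and error
calibration, kinetic error calibration) and 11 replicates for the
noisy-series period recovery; the reduction tests use a 50-repetition
single-delay run (the per-delay size of the emulated experiment) and
smaller multi-delay runs for the end-to-end checks. The acceptance
script fits one 35-point ΔR~g~(t) series and one 50-repetition
reduction at 0.5% noise. All synthetic inputs are regenerated at run
time from seeds.

## Known limitations

* The generator's WAXS region is a phenomenological static background;
  it carries no photoinduced difference signal, so the pipeline's WAXS
  output is only exercised as "no false signal", and nothing here
  validates structural interpretation of real WAXS features.
* Shot noise is Gaussian and multiplicative with ground-truth stated
  uncertainties. Real detectors add correlated readout structure,
  timing jitter mixes delays near t₀, and stated errors are themselves
  estimates — the calibration results (errors matching replicate
  scatter) lean on the stated uncertainties being correct and transfer
  to real data only to the extent that theirs are.
* Corrupted shots are smooth multiplicative distortions; a screen tuned
  here may behave differently against pathologies with fine q-structure.
* The elastic-sphere model is homogeneous and isotropic with purely
  acoustic (radiative) damping — no internal viscosity, no hydration
  layer, no mode-to-signal amplitude coupling; it predicts periods and
  damping times, not oscillation amplitudes.
* The kinetic model's decay time is weakly identified at the default
  noise (see above); reported τ values near the span bound mean "not
  measurable from this series", and the flag should be honoured.
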