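---
title: "A fiber-fraction-weighted hyperelastic model of the periodontal ligament"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A fiber-fraction-weighted hyperelastic model of the periodontal ligament}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdlhyper)
```

## The material and the model

The periodontal ligament (PDL) is the thin band of dense connective tissue
that suspends a tooth root in its alveolar socket. Its tensile response
under transient loading is dominated by collagen fiber bundles which, after
preconditioning, align with the loading direction. How stiff a given region
of the ligament is correlates with how much of its cross-section is
collagen: the fiber *volume fraction* `Vf`, measured as an area fraction on
Masson-stained sections (collagen stains blue; `Vf = Px / PI` for `Px`
fiber pixels inside a region of interest of `PI` pixels).

`pdlhyper` models the ligament as an incompressible, transversely isotropic
hyperelastic solid whose strain-energy density is an explicit mixture of a
matrix phase and a fiber phase, weighted by the measured volume fractions:

$$W = V_m\, c_1\left(e^{Q_1} - 1\right) + V_f\, c_2\left(e^{Q_2} - 1\right),$$

$$Q_1 = c_3 (I_1 - 3)^2 + c_4 (\lambda - 1)^4, \qquad
  Q_2 = c_5 (I_1 - 3)^2 + c_6 (\lambda - 1)^4,$$

with $V_m + V_f = 1$. Here $\lambda$ is the axial stretch ("strain ratio";
$\lambda = \sqrt{1 + 2\varepsilon}$ for Green strain $\varepsilon$),
$I_1 = \mathrm{tr}\,C$ is the first invariant of the right Cauchy–Green
tensor and the fiber invariant is $I_4 = N \cdot C \cdot N^T = \lambda^2$
for the fiber direction $N = (1,0,0)$ aligned with the load. Under
incompressibility the lateral stretches are $\lambda^{-1/2}$, so
$I_1 = \lambda^2 + 2/\lambda$. The second invariant $I_2$ and the coupling
invariant $I_5$ are neglected: matrix–fiber interaction is assumed weak in
uniaxial tension.

Differentiating the energy and eliminating the incompressibility pressure
$p$ through the condition $\sigma_{22} = \sigma_{33} = 0$ gives the
closed-form axial Cauchy stress implemented in
`cauchy_stress_uniaxial()`:

$$\sigma_{11} = \left(\lambda^2 - \tfrac{1}{\lambda}\right)
  \left[4 V_m c_1 e^{Q_1} c_3 (I_1 - 3) + 4 V_f c_2 e^{Q_2} c_5 (I_1 - 3)\right]
  + 4\lambda(\lambda - 1)^3\left[c_4 V_m c_1 e^{Q_1} + c_6 V_f c_2 e^{Q_2}\right].$$

Two points about this expression deserve a note, because printed versions
of such models are easy to mistranscribe:

* **Fiber exponent.** Both phase exponents use $(\lambda - 1)^4$. A
  $(\lambda - 4)^4$ variant sometimes seen in print is inconsistent with
  the $(\lambda-1)^3$ terms of the stress above and with the $I_4$
  derivative $\partial W/\partial I_4 \propto (\sqrt{I_4} - 1)^3$; this
  package uses the internally consistent form throughout.
* **Units.** Only $c_1, c_2$ carry stress units (MPa). The exponent
  coefficients $c_3 \dots c_6$ multiply dimensionless strain measures and
  are therefore dimensionless, whatever unit labels accompany tabulated
  values.

No sign or convexity restriction is imposed on $c_1 \dots c_6$: fitted PDL
coefficient sets include negative stress scales. `energy_diagnostics()`
reports whether a set stores negative energy or softens over a stretch
range instead of forbidding it.

## Verifying the stress: three independent routes

The closed form is the package's central formula, so it is checked against
two independent derivations rather than trusted:

1. **Tensor pipeline** (`cauchy_via_tensor()`): assemble
   $S = 2\,\partial W/\partial I_1\, E + 2\,\partial W/\partial I_4\, N
   \otimes N - p\, C^{-1}$ and push forward $\sigma = F S F^T$ (with
   $J = 1$). $C$ is diagonal here, so $C^{-1}$ is taken analytically —
   no numerical inversion, no tolerance pollution.
2. **Energy derivative** (`cauchy_via_finite_difference()`): on the
   incompressible uniaxial path $\sigma_{11} = \lambda\, dW/d\lambda$,
   evaluated by central differences.

`verify_stress_triangle()` reports the worst pairwise discrepancies over a
stretch grid plus the largest lateral stress magnitude, which must vanish —
that is the defining property of the pressure term:

```{r triangle}
p <- pdl_region_presets()[["neck_central"]]
verify_stress_triangle(p)
```

Numerical choices: the default difference step is $h = 10^{-6}$, balancing
$O(h^2)$ truncation against round-off for stresses of order 1 MPa.
Discrepancies are reported relative to the larger stress with a floor of
$10^{-3}$ MPa (1 kPa): below that scale the central difference is dominated
by round-off of order $10^{-10}$ MPa and a pure relative measure would be
noise. The exponential is guarded at $|Q| > 700$ with an informative error
naming the offending stretch, rather than returning `Inf`.

## Fitting: a three-coefficient non-redundant reduction

On a single uniaxial curve the six-coefficient model is redundant, so
fitting works on the free triplet $(c_1, c_3, c_5)$ with the dependent
coefficients tied by affine constraints (the defaults of
`constraint_set()`):

$$c_2 = 0.39571\,c_1 + 6.30991,\quad
  c_4 = -5.38351\,c_3 - 8.07826,\quad
  c_6 = -5.53492\,c_5 + 4.62974.$$

The fiber fraction is a *measured input*, fixed at its regional mean —
never a fitted quantity; that is the point of the model. `fit_pdl()`
minimises the unweighted sum of squared Cauchy-stress residuals (no error
model for the test machine is assumed) with Levenberg–Marquardt
(`minpack.lm::nls.lm`), the standard choice for a small smooth
least-squares problem. Defaults: neutral start $(1,1,1)$, box
$[-100, 100]$ on each free coefficient (fitted magnitudes stay well below
that), and an optional seeded multistart that jitters the start with
Gaussian noise (sd 5) and keeps the best solution. The multistart exists
because the exponential model genuinely has local minima: one of the six
regional presets is *not* recovered from the neutral start alone, but all
six are with `multistart = 8`. With a fixed `init` and a single start the
fit is fully deterministic. An unconstrained six-coefficient mode
(`constraints = NULL`) is available for comparison; since the constrained
model is nested inside it, starting the six-coefficient search from the
expanded constrained solution can only improve the fit.

```{r fit}
preset <- pdl_region_presets()[["apex_central"]]
curve <- generate_curve(preset, noise_sd = 0)
fit <- fit_pdl(curve, vf = preset$vf)
summary(fit)
```

### What parameter recovery can and cannot show

Self-generated noise-free curves are recovered essentially exactly (the
acceptance tests require $10^{-3}$ relative; the achieved errors are near
machine precision). Under additive noise the picture changes qualitatively:
the three-coefficient exponential model is *sloppy* on uniaxial data. At a
noise level of 0.01 MPa the least-squares optimum routinely attains a
lower objective than the generating truth while sitting far from it in
coefficient space — the objective has near-flat ridges along which very
different triplets produce nearly identical curves. Curve-level
predictions are therefore stable, but coefficient-level recovery is not,
and for the low-stress apex presets (peak stress ~0.1–0.2 MPa on the
default grid) even the true coefficients leave an $R^2$ below 0.99 at that
noise level. The test suite records this honestly: the noisy
coefficient-recovery assertions fail for the weakly identified presets,
and the acceptance script reports the measured recovery errors as they
are. Users should treat fitted triplets as a compact curve description,
not as independently meaningful material constants, unless data from more
than one deformation mode are available.

## Fiber fraction measurement

`volume_fraction(px, pi)` is the strict count-based entry point
(`px > pi` is an error: segmentation leaked outside the ROI);
`mask_fraction(fiber, roi)` consumes binary masks and *clips* fiber pixels
outside the ROI, because interactively traced ROIs routinely overlap a
segmentation computed on the whole frame. Colour segmentation of stained
images is deliberately out of scope: published pipelines select ROIs
interactively without stated thresholds, so any colour recipe here would
be invention; the package consumes already-binarised masks (PNG/TIFF via
`read_mask()`) or pixel counts. The fraction is an area fraction on 2-D
sections with no stereological correction, matching how such measurements
are reported. `region_summary()` averages per-section fractions per root
region; applied to the bundled section table `pdl_section_fractions()` it
yields the regional means (neck 60.312%, middle 63.142%, apex 51.988%)
used as the fixed `Vf` inputs of the six presets.

## The synthetic data generator

No raw tensile curves are available for this study system, so the package
generates its own inputs and treats the generator as first-class, tested
code:

* `generate_curve()` evaluates the closed form on a stretch grid and adds
  homoscedastic Gaussian noise. Defaults — 30 points on
  $\lambda \in [1, 1.20]$, noise sd 0.01 MPa — encode the tensile regime
  the model targets: curves are flat below $\lambda \approx 1.05$, steepen
  past 1.1, and peak stresses stay below ~1.5 MPa, so a 0.01 MPa noise
  floor is small relative to the signal for the stiff regions yet
  non-trivial for the compliant apex. The grid stops at 1.20 rather than
  the damage threshold because that is the regime the model describes.
* `generate_fiber_mask()` places exactly `round(vf * h * w)` fiber pixels
  by seeded sampling, so the measured fraction is exact by construction.

What the generator does **not** emulate: rate dependence (loading-rate
labels are metadata only; the hyperelastic model is rate-independent, and
viscoelastic behaviour is explicitly out of scope), preconditioning
cycles, heteroscedastic or serially correlated measurement error, and the
spatial texture of real fiber bundles in masks. Passing tests on synthetic
data therefore demonstrate the *software* is correct and the fitting
machinery recovers what it is pointed at — they do not validate the
constitutive model against real tissue.

## Problem sizes and reproducibility

The verification and recovery studies run at modest sizes chosen to pin
the mathematics without ceremony: 200 random material states for the
three-route stress agreement, six presets × 30-point curves for recovery,
eight multistart draws per fit. Every stochastic step (noise, multistart
jitter, masks) is seeded, and `simulate → fit → report` with fixed seeds
is byte-reproducible; `write_fit_report()` records the initial point,
iteration count and convergence flag so a fit is auditable from its JSON
report.

## Known limitations

* Uniaxial, tension-only scope: no shear, no compression, no 3-D boundary
  value problems, no viscoelasticity.
* The affine constraint coefficients are taken as given; the data from
  which they were derived are not public, so they cannot be re-estimated
  here.
* Coefficient sloppiness under noise, as discussed above.
* The fiber direction is fixed to the loading axis; regionally varying
  fiber architecture (radial in the apex, horizontal in the neck) enters
  only through `Vf`, not through orientation.
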