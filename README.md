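# pdlhyper

Hyperelastic constitutive modelling of the human periodontal ligament
(PDL), weighted by the collagen fiber volume fraction.

The PDL is the connective tissue that suspends a tooth root in its bony
socket and transmits orthodontic forces to the alveolar bone. Its tensile
stiffness varies along the root (neck / middle / apex) with how much of
the tissue is collagen fiber. `pdlhyper` is for biomechanics researchers
who want to fit, verify and simulate that behaviour: it implements a
transversely isotropic, incompressible hyperelastic model whose strain
energy is an explicit two-phase mixture,

```
W  = Vm · c1 (e^Q1 − 1) + Vf · c2 (e^Q2 − 1)
Q1 = c3 (I1 − 3)² + c4 (λ − 1)⁴        (matrix phase)
Q2 = c5 (I1 − 3)² + c6 (λ − 1)⁴        (fiber phase)
```

with `Vf` the fiber volume fraction measured on stained sections
(`Vm = 1 − Vf`), `λ` the axial stretch, and `I1 = λ² + 2/λ` the first
invariant of the right Cauchy–Green tensor under incompressible uniaxial
tension along the fiber axis. The closed-form axial Cauchy stress

```
σ11 = (λ² − 1/λ)[4 Vm c1 e^Q1 c3 (I1−3) + 4 Vf c2 e^Q2 c5 (I1−3)]
      + 4 λ (λ−1)³ [c4 Vm c1 e^Q1 + c6 Vf c2 e^Q2]
```

is verified in-package against two independent derivations (the full
tensor pipeline `σ = F S Fᵀ` and a finite-difference derivative of the
energy, `σ11 = λ dW/dλ`). Parameter fitting uses Levenberg–Marquardt
least squares on the non-redundant free triplet `(c1, c3, c5)`, with
`c2, c4, c6` tied by affine constraints and `Vf` fixed at its measured
value.

The package also measures fiber fractions from segmented masks or pixel
counts (`Vf = Px / PI`, aggregated per root region), and generates seeded
synthetic tensile curves and fiber masks so the whole pipeline runs
without any external data.

## Worked example

Fit the model to a synthetic tensile curve from the middle-region
(central incisor) preset, with 0.01 MPa measurement noise:

```r
library(pdlhyper)

preset <- pdl_region_presets()[["middle_central"]]   # c1=24.30, c3=-15.23, c5=18.00, Vf=0.63142
curve  <- generate_curve(preset, noise_sd = 0.01, seed = 42)
fit    <- fit_pdl(curve, vf = preset$vf, multistart = 8, seed = 1)
summary(fit)
#> Hyperelastic PDL model fit (middle, central)
#>   three free coefficients, affine constraints
#>   coefficients (c1, c2 in MPa; c3..c6 dimensionless):
#>        c1        c2        c3        c4        c5        c6        vf        vm
#>  23.78138  15.72044 -15.29116  74.24184  17.92222 -94.56831   0.63142   0.36858
#>   n = 30, R^2 = 0.999079, residual sd = 0.0129 MPa, iterations = 26
```

The fitted free triplet (23.78, −15.29, 17.92) sits close to the
generating one (24.30, −15.23, 18.00); `R² = 0.9991` says the model
explains essentially all of the stress variance at this noise level.
`plot(fit)` overlays the fitted curve on the data, and
`predict(fit, newdata = 1.15)` evaluates the calibrated stress at any
stretch.

Verify the stress algebra and reproduce the regional fiber fractions:

```r
verify_stress_triangle(preset)
#> Stress-route triangle agreement over 25 stretches in [ 1.001 , 1.25 ]
#>   closed form vs tensor pipeline : 4.17e-14 (rel.)
#>   closed form vs finite diff     : 5.22e-07 (rel.)
#>   tensor vs finite diff          : 5.22e-07 (rel.)
#>   max |lateral Cauchy stress|    : 6.09e-15 MPa

region_summary(pdl_section_fractions())
#> Fiber volume fraction by root region
#>  region n_sections mean_vf min_vf max_vf
#>    neck          5  60.312 51.991 67.895
#>  middle          5  63.142 58.249 65.771
#>    apex          5  51.988 41.200 62.198
```

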