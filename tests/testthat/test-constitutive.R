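test_that("material_params validates fractions and keeps Vm + Vf = 1", {
  p <- material_params(1, 2, 3, 4, 5, 6, vf = 0.6)
  expect_equal(p$vm + p$vf, 1)
  # negative stress scales are legal (fitted PDL sets contain them)
  expect_silent(material_params(-7.13, 1, 40.93, 1, 55.6, 1, vf = 0.6))
  expect_error(material_params(1, 1, 1, 1, 1, 1, vf = 1.2), "\\[0, 1\\]")
  expect_error(material_params(1, 1, 1, 1, 1, NA, vf = 0.5), "finite")
})

test_that("exponents vanish at rest and match direct arithmetic", {
  p <- unit_params()
  q <- exponents(1, p)
  expect_equal(q$Q1, 0)
  expect_equal(q$Q2, 0)
  zero <- material_params(1, 1, 0, 0, 0, 0, vf = 0.5)
  q0 <- exponents(c(1.05, 1.2), zero)
  expect_equal(q0$Q1, c(0, 0))
  expect_equal(q0$Q2, c(0, 0))
  # lambda = 1.1, c3 = 1, c4 = 0: Q1 = (I1 - 3)^2
  expect_equal(exponents(1.1, p)$Q1, 7.94214876033065e-4, tolerance = 1e-12)
})

test_that("strain energy is zero at rest and matches direct evaluation", {
  p <- unit_params()
  expect_equal(strain_energy(1, p), 0)
  zero <- material_params(3, 4, 0, 0, 0, 0, vf = 0.25)
  expect_equal(strain_energy(c(1.1, 1.2), zero), c(0, 0))
  # half/half unit preset at 1.1: W = e^Q - 1
  expect_equal(strain_energy(1.1, p), 7.945303481797783e-4,
               tolerance = 1e-12)
  # overflow guard names the offending state
  big <- material_params(1, 1, 1e6, 0, 1e6, 0, vf = 0.5)
  expect_error(strain_energy(1.25, big), "out of .* range")
})

test_that("pressure and closed-form stress match frozen direct arithmetic", {
  p <- unit_params()
  expect_equal(pressure_term(1, p), 0)
  noiso <- material_params(1, 1, 0, 2, 0, 3, vf = 0.5)
  expect_equal(pressure_term(c(1.1, 1.2), noiso), c(0, 0))
  expect_equal(pressure_term(1.1, p), 0.1025607617877478, tolerance = 1e-12)

  expect_equal(cauchy_stress_uniaxial(1, p), 0)
  zero <- material_params(5, 5, 0, 0, 0, 0, vf = 0.5)
  expect_equal(cauchy_stress_uniaxial(seq(1, 1.2, 0.05), zero),
               rep(0, 5))
  expect_equal(cauchy_stress_uniaxial(1.1, p), 0.03394761215174455,
               tolerance = 1e-12)
})

test_that("stress-free reference state holds for random parameter sets", {
  set.seed(11)
  for (i in 1:200) {
    expect_equal(cauchy_stress_uniaxial(1, draw_params()), 0)
  }
})

test_that("the two phases enter the stress symmetrically", {
  set.seed(12)
  for (i in 1:25) {
    p <- draw_params()
    swapped <- material_params(p$c2, p$c1, p$c5, p$c6, p$c3, p$c4,
                               vf = p$vm)
    l <- draw_stretch(5)
    expect_equal(cauchy_stress_uniaxial(l, p),
                 cauchy_stress_uniaxial(l, swapped), tolerance = 1e-12)
  }
})

test_that("degenerate phase fractions reduce to single-phase expressions", {
  set.seed(13)
  l <- seq(1.01, 1.2, length.out = 10)
  p <- draw_params()
  matrix_only <- material_params(p$c1, p$c2, p$c3, p$c4, p$c5, p$c6, vf = 0)
  pure_matrix <- material_params(p$c1, 0, p$c3, p$c4, 0, 0, vf = 0)
  expect_equal(cauchy_stress_uniaxial(l, matrix_only),
               cauchy_stress_uniaxial(l, pure_matrix), tolerance = 1e-12)
  fiber_only <- material_params(p$c1, p$c2, p$c3, p$c4, p$c5, p$c6, vf = 1)
  pure_fiber <- material_params(0, p$c2, 0, 0, p$c5, p$c6, vf = 1)
  expect_equal(cauchy_stress_uniaxial(l, fiber_only),
               cauchy_stress_uniaxial(l, pure_fiber), tolerance = 1e-12)
})

test_that("curve_predict vectorises the closed form and carries labels", {
  p <- unit_params()
  cv <- curve_predict(c(1, 1.1), p, region = "neck", tooth = "central")
  expect_s3_class(cv, "stress_strain_curve")
  expect_equal(cv$stress, cauchy_stress_uniaxial(c(1, 1.1), p))
  expect_equal(cv$stress[1], 0)
  expect_equal(attr(cv, "region"), "neck")
  expect_error(curve_predict(c(1.1, 1.0), p), "increasing")
})

test_that("energy diagnostics flag softening parameter sets", {
  ok <- pdl_region_presets()[["apex_central"]]
  d <- energy_diagnostics(ok, stretch = seq(1, 1.2, length.out = 50))
  expect_false(d$energy_negative)
  soft <- material_params(-1, 0, 1, 0, 0, 0, vf = 0)
  expect_true(energy_diagnostics(soft)$energy_negative)
})
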