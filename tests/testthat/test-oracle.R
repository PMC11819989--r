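test_that("energy partials vanish at rest and match finite differences", {
  set.seed(21)
  p <- draw_params()
  pd0 <- energy_partials(1, p)
  expect_equal(pd0$dW_dI1, 0)
  expect_equal(pd0$dW_dI4, 0)

  # dW/dI1 against a central difference in I1 holding I4 fixed: W as an
  # explicit function of (I1, I4), evaluated outside the package's path
  W_of <- function(i1, i4, p) {
    a <- sqrt(i4)
    q1 <- p$c3 * (i1 - 3)^2 + p$c4 * (a - 1)^4
    q2 <- p$c5 * (i1 - 3)^2 + p$c6 * (a - 1)^4
    p$vm * p$c1 * (exp(q1) - 1) + p$vf * p$c2 * (exp(q2) - 1)
  }
  h <- 1e-6
  for (i in 1:20) {
    p <- draw_params()
    l <- draw_stretch()
    i1 <- l^2 + 2 / l; i4 <- l^2
    pd <- energy_partials(l, p)
    fd1 <- (W_of(i1 + h, i4, p) - W_of(i1 - h, i4, p)) / (2 * h)
    fd4 <- (W_of(i1, i4 + h, p) - W_of(i1, i4 - h, p)) / (2 * h)
    expect_equal(pd$dW_dI1, fd1, tolerance = 1e-5)
    expect_equal(pd$dW_dI4, fd4, tolerance = 1e-5)
  }

  # no fiber exponents -> no I4 dependence
  p0 <- material_params(2, 3, 1, 0, -1, 0, vf = 0.4)
  expect_equal(energy_partials(c(1.05, 1.2), p0)$dW_dI4, c(0, 0))
})

test_that("second PK stress is transversely symmetric and annihilates lateral stress", {
  p <- unit_params()
  s0 <- second_pk_stress(1, p)
  expect_equal(s0$S, matrix(0, 3, 3))

  set.seed(22)
  for (i in 1:30) {
    pp <- draw_params()
    l <- draw_stretch()
    pk2 <- second_pk_stress(l, pp)
    expect_equal(pk2$S[2, 2], pk2$S[3, 3], tolerance = 1e-12)
    sig <- with(pk2$deformation, F %*% pk2$S %*% t(F))
    expect_lt(abs(sig[2, 2]), 1e-9)
    expect_lt(abs(sig[3, 3]), 1e-9)
  }
})

test_that("tensor pipeline reproduces the closed-form stress", {
  p <- unit_params()
  expect_equal(cauchy_via_tensor(1, p), 0)
  expect_equal(cauchy_via_tensor(1.1, p), 0.03394761215174455,
               tolerance = 1e-9)
  set.seed(23)
  worst <- 0
  for (i in 1:200) {
    pp <- draw_params()
    l <- draw_stretch()
    a <- cauchy_via_tensor(l, pp)
    b <- cauchy_stress_uniaxial(l, pp)
    worst <- max(worst, abs(a - b) / max(abs(a), abs(b), 1e-3))
  }
  expect_lt(worst, 1e-9)
})

test_that("finite-difference stress agrees and converges at second order", {
  p <- unit_params()
  expect_lt(abs(cauchy_via_finite_difference(1, p)), 1e-8)
  expect_equal(cauchy_via_finite_difference(1.1, p),
               0.03394761215174455, tolerance = 1e-6)

  # halving the step cuts the truncation error about fourfold; use steps
  # large enough that truncation dominates round-off
  pp <- pdl_region_presets()[["neck_central"]]
  exact <- cauchy_stress_uniaxial(1.15, pp)
  e1 <- abs(cauchy_via_finite_difference(1.15, pp, h = 1e-4) - exact)
  e2 <- abs(cauchy_via_finite_difference(1.15, pp, h = 5e-5) - exact)
  expect_equal(e1 / e2, 4, tolerance = 0.2)

  expect_error(cauchy_via_finite_difference(1.1, p, h = 0), "step")
  expect_error(cauchy_via_finite_difference(1.1, p, h = 0.01), "step")
})

test_that("closed-form stress at a fitted preset matches the frozen oracle value", {
  # regression fixture: finite-difference value at stretch 1.15 for the
  # neck/central parameter set, frozen at computation time
  pp <- pdl_region_presets()[["neck_central"]]
  expect_equal(cauchy_stress_uniaxial(1.15, pp), 0.5492920306670451,
               tolerance = 1e-6)
})

test_that("triangle report agrees pairwise over a randomized grid", {
  set.seed(24)
  for (i in 1:8) {
    tri <- verify_stress_triangle(draw_params(),
                                  stretch = sort(draw_stretch(25)))
    expect_lt(tri$max_rel_closed_vs_tensor, 1e-9)
    expect_lt(tri$max_rel_closed_vs_fd, 1e-5)
    expect_lt(tri$max_rel_tensor_vs_fd, 1e-5)
    expect_lt(tri$max_abs_lateral, 1e-9)
  }
})
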