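test_that("mixture density follows the harmonic mass-fraction mixing law", {
  expect_equal(mixture_density(0), 1025)
  expect_equal(mixture_density(1), 1400)
  # hand evaluation: 1 / (0.0029/1400 + 0.9971/1025)
  expect_equal(mixture_density(0.0029), 1 / (0.0029 / 1400 + 0.9971 / 1025),
               tolerance = 1e-12)
  expect_equal(round(mixture_density(0.0029), 1), 1025.8)
  expect_error(mixture_density(-0.1), "0, 1")
  expect_error(mixture_density(1.2), "0, 1")

  # monotone increasing, bounded
  y <- seq(0, 1, length.out = 101)
  r <- mixture_density(y)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 1025 & r <= 1400))
})

test_that("plasma viscosity follows the piecewise concentration law", {
  expect_equal(plasma_viscosity(0), 0.53e-3)
  # continuity at C = 1: both branches give 1.22 mPa.s
  expect_equal((0.37 * 1 + 0.85) * 1e-3, (0.19 * 1 + 1.03) * 1e-3)
  expect_equal(plasma_viscosity(1), 1.22e-3)
  expect_equal(plasma_viscosity(2), (0.19 * 4 + 1.03) * 1e-3)
  expect_error(plasma_viscosity(-1), ">= 0")

  # monotone non-decreasing; the printed discontinuity at C = 0.40 is < 1%
  C <- seq(0, 3, by = 0.01)
  mu <- plasma_viscosity(C)
  expect_true(all(diff(mu) > -1e-15))
  lo <- (1.16 * 0.40 + 0.53) * 1e-3
  hi <- (0.37 * 0.40 + 0.85) * 1e-3
  expect_lt(abs(hi - lo) / lo, 0.01)
})

test_that("mass fraction and concentration conversions are consistent", {
  expect_equal(concentration_from_mass_fraction(0), 0)
  C <- concentration_from_mass_fraction(0.0029)
  expect_equal(round(C, 3), 0.297)
  # round trip is identity
  for (y in c(0, 1e-4, 0.0029, 0.05, 0.3)) {
    expect_equal(mass_fraction_from_concentration(
      concentration_from_mass_fraction(y)), y, tolerance = 1e-12)
  }
})

test_that("inlet mass fraction reproduces the serum-derived boundary value", {
  expect_identical(inlet_mass_fraction(3, 1024), 0.0029)
  expect_identical(inlet_mass_fraction(0, 1024), 0)
  expect_identical(inlet_mass_fraction(3, 1000), 0.0030)
  expect_error(inlet_mass_fraction(3, 0), "positive")
})

test_that("cell property blending interpolates the phase endpoints linearly", {
  pure_plasma <- cell_mixture_properties(1, 0)
  expect_equal(pure_plasma$density, 1025)
  expect_equal(pure_plasma$viscosity, 0.53e-3)
  pure_rbc <- cell_mixture_properties(0, 0)
  expect_equal(pure_rbc$density, 1125)
  expect_equal(pure_rbc$viscosity, 0.0050)
  mid <- cell_mixture_properties(0.55, 0.0029)
  expect_equal(round(mid$density, 1), 1070.4)
  # linearity in alpha_p
  a <- seq(0, 1, by = 0.25)
  dens <- vapply(a, function(x) cell_mixture_properties(x, 0.0029)$density, 0)
  expect_equal(diff(dens), rep(diff(dens)[1], 4), tolerance = 1e-12)
  expect_error(cell_mixture_properties(1.5), "0, 1")
})

test_that("Reynolds number of the inlet blood flow is laminar", {
  expect_equal(reynolds_number(1000, 0.01, 0.0015, 0.001), 15)
  expect_equal(reynolds_number(1000, 0, 0.0015, 0.001), 0)
  expect_error(reynolds_number(1000, 0.01, 0.0015, 0), "positive")
  re <- inlet_reynolds_number()
  expect_equal(round(re), 6)
  expect_lt(re, 2800)
})
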