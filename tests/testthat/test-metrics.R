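test_that("interfacial masses match the area-density oracle", {
  m <- build_mesh(build_layout(), 0.05)
  bc <- boundary_spec(5)
  st <- initialize_state(m, bc)

  # no fibrinogen at t = 0
  expect_equal(interfacial_mass(st, m, "fibrinogen"), 0)

  # full-wetting plasma mass = interfacial area x 1 m depth x 1025 kg/m^3
  a <- mesh_areas(m)
  oracle <- a$interfacial_area * 1e-6 * 1025 * 1e6   # mm^2 -> m^2, kg -> mg
  expect_equal(interfacial_mass(st, m, "plasma"), oracle, tolerance = 1e-12)
  # close to the exact-geometry value 2.5 mm^2 * 1025 kg/m^3 = 2562.5 mg
  expect_within(interfacial_mass(st, m, "plasma"), 2562.5, 0.05)

  # uniform saturation: fibrinogen ceiling = Y0 x plasma-phase mass (~7.4 mg)
  st$Y0[] <- 0.0029
  fib <- interfacial_mass(st, m, "fibrinogen")
  phase <- a$interfacial_area * 1e-6 * mixture_density(0.0029) * 1e6
  expect_equal(fib, 0.0029 * phase, tolerance = 1e-12)
  expect_within(fib, 7.4, 0.06)

  # interfacial + outer = total, exactly
  expect_equal(interfacial_mass(st, m, "fibrinogen", total = TRUE) -
                 interfacial_mass(st, m, "fibrinogen"),
               sum(st$alpha_p[m$zone == "outer" & !is.na(m$zone)] *
                     mixture_density(0.0029) * 0.0029) * (0.05e-3)^2 * 1e6,
               tolerance = 1e-9)
})

test_that("infiltration rate is interfacial over total in percent, with 0/0 guarded", {
  m <- build_mesh(build_layout(), 0.05)
  st <- initialize_state(m, boundary_spec(5))

  # uniform composition: rate equals the area fraction (~20% for the
  # triangular reference geometry)
  st$Y0[] <- 0.0029
  a <- mesh_areas(m)
  expect_equal(infiltration_rate(st, m, "plasma"),
               100 * a$interfacial_area / a$fluid_area, tolerance = 1e-9)
  expect_within(infiltration_rate(st, m, "fibrinogen"), 20, 0.05)

  # all plasma confined to the interfacial zone -> 100%
  st2 <- st
  st2$alpha_p[m$zone == "outer" & !is.na(m$zone)] <- 0
  expect_equal(infiltration_rate(st2, m, "plasma"), 100)

  # zero total -> undefined, not zero
  st$Y0[] <- 0
  expect_true(is.na(infiltration_rate(st, m, "fibrinogen")))
})

test_that("stage averages reproduce closed-form series and the whole-run mean", {
  t <- seq(0, 3, by = 0.01)
  const <- data.frame(t = t, fib_interfacial = rep(5, length(t)),
                      plasma_interfacial = rep(7, length(t)))
  s <- stage_summary(const, "fibrinogen")
  expect_equal(s$value, c(5, 5, 5))
  expect_true(all(s$covered))

  lin <- data.frame(t = t, fib_interfacial = t, plasma_interfacial = 2 * t)
  s <- stage_summary(lin, "fibrinogen")
  expect_equal(s$value, c(0.5, 1.5, 2.5), tolerance = 1e-9)
  # the three stage averages average to the whole-run mean
  expect_equal(mean(s$value), 1.5, tolerance = 1e-9)
  expect_equal(stage_summary(lin, "plasma")$value, c(1, 3, 5), tolerance = 1e-9)

  # short series: uncovered stages flagged
  short <- data.frame(t = seq(0, 1.5, 0.01),
                      fib_interfacial = seq(0, 1.5, 0.01),
                      plasma_interfacial = 0)
  s <- stage_summary(short, "fibrinogen")
  expect_true(s$covered[1])
  expect_false(s$covered[2])
  expect_true(is.na(s$value[3]))
})

test_that("ratio table normalizes by the reference angle", {
  t <- seq(0, 3, by = 0.1)
  mk <- function(scale) {
    stage_summary(data.frame(t = t, fib_interfacial = scale * t,
                             plasma_interfacial = 0), "fibrinogen")
  }
  tab <- ratio_table(list("5" = mk(1), "100" = mk(0.27)))
  expect_equal(tab$ratio_5, c(1, 1, 1))
  expect_equal(tab$ratio_100, c(0.27, 0.27, 0.27))
  expect_error(ratio_table(list("30" = mk(1)), reference = "5"), "missing")
})

test_that("Pearson correlation matches hand-computed references", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$R, 1)
  expect_equal(pearson_correlation(x, -x)$R, -1)
  # hand-computed: cov = 1.5, sd both sqrt(5/3) -> R = 0.9 on these...
  r <- pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$R, 0.8)
  expect_equal(r$n, 4)
  # regression line of a perfect fit
  fit <- pearson_correlation(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_error(pearson_correlation(x, rep(1, 10)), "constant")
  expect_error(pearson_correlation(1:3, 1:4), "lengths")
})
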