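test_that("layout defaults match the reference implant channel and invariants hold", {
  l <- build_layout()
  expect_equal(l$domain_height, 10.0)
  expect_equal(l$domain_width, 1.5)
  expect_equal(l$n_threads, 10L)
  expect_equal(l$thread_height, 1.0)
  expect_equal(l$thread_depth, 0.5)
  expect_equal(l$thread_profile, "triangular")

  # degenerate but valid: plain channel
  expect_silent(l0 <- build_layout(n_threads = 0L))
  expect_equal(l0$n_threads, 0L)

  # invariant violations
  expect_error(build_layout(thread_height = 1.1), "do not fit")
  expect_error(build_layout(domain_width = -1), "positive")
  expect_error(build_layout(thread_depth = 2), "smaller than domain_width")
})

test_that("rasterization produces the expected grid and solid fraction", {
  l <- build_layout()
  m <- rasterize(l, 0.025)
  expect_equal(m$nx, 60)
  expect_equal(m$ny, 400)
  expect_equal(m$nx * m$ny, 24000)

  # triangular threads: total solid area 10 * (1/2 * 1.0 * 0.5) = 2.5 mm^2
  a <- mesh_areas(m)
  expect_equal(a$solid_area_exact, 2.5)
  expect_lt(abs(a$solid_area - 2.5) / 2.5, 0.05)

  # first-order convergence of the rasterized area
  err1 <- abs(mesh_areas(rasterize(l, 0.05))$solid_area - 2.5)
  err2 <- abs(mesh_areas(rasterize(l, 0.0125))$solid_area - 2.5)
  expect_lt(err2, err1)

  m0 <- rasterize(build_layout(n_threads = 0L), 0.05)
  expect_true(all(m0$is_fluid))

  expect_error(rasterize(l, 0.6), "thread_depth")
  expect_error(rasterize(l, 0.07), "divide")
})

test_that("zone partition splits fluid cells at the thread-peak line", {
  m <- build_mesh(build_layout(), 0.025)
  a <- mesh_areas(m)
  # interfacial fluid area = 10 * 0.5 - 2.5 = 2.5 mm^2 (grid-converging)
  expect_lt(abs(a$interfacial_area - 2.5) / 2.5, 0.05)
  finer <- mesh_areas(build_mesh(build_layout(), 0.0125))
  expect_lt(abs(finer$interfacial_area - 2.5), abs(a$interfacial_area - 2.5) + 1e-9)

  # every fluid cell labeled exactly once
  expect_true(all(!is.na(m$zone[m$is_fluid])))
  expect_true(all(is.na(m$zone[!m$is_fluid])))
  expect_equal(sum(m$zone == "interfacial", na.rm = TRUE) +
                 sum(m$zone == "outer", na.rm = TRUE), sum(m$is_fluid))

  # no threads: interfacial area is the full 10 x 0.5 strip
  m0 <- build_mesh(build_layout(n_threads = 0L), 0.05)
  expect_equal(mesh_areas(m0)$interfacial_area, 5.0, tolerance = 1e-9)

  # partition invariant to refinement (area within one cell row of the line)
  expect_lt(abs(mesh_areas(m0)$interfacial_area -
                  mesh_areas(build_mesh(build_layout(n_threads = 0L), 0.025))$interfacial_area),
            0.05 * 10 + 1e-9)
})

test_that("boundary tags cover the perimeter with the documented conventions", {
  m <- build_mesh(build_layout(), 0.05)
  bf <- boundary_faces(m)
  expect_setequal(unique(bf$tag),
                  c("ALVEOLAR_BONE", "BLOOD_INLET", "BLOOD_OUTLET",
                    "IMPLANT_SURFACE"))
  # left edge: one face per row, all alveolar bone
  expect_equal(sum(bf$tag == "ALVEOLAR_BONE"), m$ny)
  expect_equal(sum(bf$tag == "BLOOD_INLET"), sum(m$is_fluid[, 1]))
  expect_equal(sum(bf$tag == "BLOOD_OUTLET"), sum(m$is_fluid[, m$ny]))
  # implant faces: right-edge fluid cells plus all fluid-solid faces
  n_right <- sum(m$is_fluid[m$nx, ])
  expect_gte(sum(bf$tag == "IMPLANT_SURFACE"), n_right)
  # the tagged faces cover at least the full domain perimeter
  expect_gte(nrow(bf), 2 * m$nx + 2 * m$ny - (sum(!m$is_fluid[m$nx, ]) * 2))

  # no threads: implant surface is exactly the right edge
  m0 <- build_mesh(build_layout(n_threads = 0L), 0.05)
  bf0 <- boundary_faces(m0)
  expect_equal(sum(bf0$tag == "IMPLANT_SURFACE"), m0$ny)
  expect_equal(nrow(bf0), 2 * m0$nx + 2 * m0$ny)
})
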