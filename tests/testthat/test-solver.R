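# Solver operator tests on small meshes; the full scenario is exercised in
# the acceptance suite.

test_that("initial state is quiescent fibrinogen-free plasma", {
  m <- build_mesh(build_layout(), 0.05)
  bc <- boundary_spec(5)
  st <- initialize_state(m, bc)
  expect_equal(interfacial_mass(st, m, "fibrinogen"), 0)
  expect_within(interfacial_mass(st, m, "plasma"), 2563, 0.05)
  expect_true(all(st$alpha_p >= 0 & st$alpha_p <= 1))
  expect_true(all(st$Y0 >= 0 & st$Y0 < 1))
  expect_equal(max(abs(st$u), abs(st$v)), 0)
  expect_equal(st$time, 0)
})

test_that("VOF advection preserves uniform fields and transports a patch exactly", {
  m <- small_channel(height = 20, width = 2)
  bc <- boundary_spec(90, inlet_speed = 0.01, inlet_hematocrit = 0.45,
                      inlet_Y0 = 0, left_inlet = FALSE)
  st <- initialize_state(m, bc)

  # uniform alpha equal to the inflow composition + uniform velocity: invariant
  st$alpha_p[] <- bc$inlet_alpha_p
  st$v[] <- 0.01
  res <- advance_vof(st, m, 0.05, bc)
  expect_equal(res$alpha_p, st$alpha_p, tolerance = 1e-12)

  # zero velocity: invariant
  st2 <- initialize_state(m, bc)
  st2$v[] <- 0
  res2 <- advance_vof(st2, m, 0.05, bc)
  expect_equal(res2$alpha_p, st2$alpha_p)

  # square patch in uniform upward flow: centroid moves v*t, volume conserved
  bc0 <- boundary_spec(90, inlet_speed = 0.01, inlet_hematocrit = 1,
                       inlet_Y0 = 0, left_inlet = FALSE)
  st3 <- initialize_state(m, bc0)
  st3$alpha_p[] <- 0
  patch <- outer(abs(m$x - 1) < 0.4, abs(m$y - 3) < 0.4)
  st3$alpha_p[patch] <- 1
  st3$v[] <- 0.01
  vol0 <- sum(st3$alpha_p)
  wy <- outer(rep(1, m$nx), m$y)
  cy0 <- sum(st3$alpha_p * wy) / vol0
  # the advection operator alone, against the analytic displacement
  # (interface compression is a sharpening model term, off here)
  res3 <- advance_vof(st3, m, 1.0, bc0, cfg = solver_config(c_compress = 0))
  vol1 <- sum(res3$alpha_p)
  cy1 <- sum(res3$alpha_p * wy) / vol1
  expect_lt(abs((cy1 - cy0) - 10), m$cell_size)        # 0.01 m/s x 1 s = 10 mm
  expect_lt(abs(vol1 - vol0) / vol0, 1e-10)
  expect_true(all(res3$alpha_p >= 0 & res3$alpha_p <= 1))
})

test_that("species transport is conservative, bounded, and advection-consistent", {
  m <- small_channel(height = 10, width = 2)
  bc <- quiet_bc()
  st <- initialize_state(m, bc)

  # uniform Y0, no inflow gradient: invariant under advection + diffusion
  st$Y0[] <- 0.0029
  st$v[] <- 0.005
  bc_in <- boundary_spec(90, inlet_speed = 0.005, inlet_hematocrit = 0,
                         inlet_Y0 = 0.0029, left_inlet = FALSE)
  res <- advance_species(st, m, 0.1, bc_in)
  expect_equal(res$Y0, st$Y0, tolerance = 1e-12)

  # closed box, zero velocity, artificially large diffusivity: total
  # fibrinogen mass constant to machine precision
  props <- fluid_properties(D_fib = 1e-8)
  st2 <- initialize_state(m, bc)
  st2$Y0 <- matrix(0.003 * exp(-((outer(m$x, rep(1, m$ny)) - 1)^2 +
                                   (outer(rep(1, m$nx), m$y) - 5)^2) / 0.5),
                   m$nx, m$ny)
  m0 <- interfacial_mass(st2, m, "fibrinogen", props, total = TRUE)
  res2 <- advance_species(st2, m, 5, bc, props)
  m1 <- interfacial_mass(res2, m, "fibrinogen", props, total = TRUE)
  expect_lt(abs(m1 - m0) / m0, 1e-12)
  expect_true(all(res2$Y0 >= 0 & res2$Y0 < 1))
  # diffusion actually happened
  expect_lt(max(res2$Y0), max(st2$Y0))
})

test_that("surface tension force vanishes on uniform fields and pulls interfaces", {
  m <- small_channel(height = 4, width = 4, cell = 0.1)
  st <- initialize_state(m, quiet_bc())
  f <- compute_csf_force(st, m)
  expect_equal(max(abs(f$fx)), 0)
  expect_equal(max(abs(f$fy)), 0)

  # a circular drop: force points inward (toward the drop center)
  st$alpha_p[] <- 0
  inside <- outer((m$x - 2)^2, rep(1, m$ny)) +
    outer(rep(1, m$nx), (m$y - 2)^2) <= 1^2
  st$alpha_p[inside] <- 1
  f <- compute_csf_force(st, m, bc = quiet_bc())
  ix <- which(m$x > 2.6 & m$x < 3.2)       # right rim: inward force is -x
  iy <- which.min(abs(m$y - 2))
  expect_lt(sum(f$fx[ix, iy]), 0)
})

test_that("momentum advance respects quiescence and global mass balance", {
  m <- small_channel(height = 6, width = 1.5, cell = 0.1)
  # no inflow, no interface: velocity stays identically zero
  bc0 <- quiet_bc()
  st <- initialize_state(m, bc0)
  res <- advance_momentum(st, m, 0.01, bc0)
  expect_equal(max(abs(res$u), abs(res$v)), 0)

  # with both inlets at 0.01 m/s, outflow balances inflow each step
  bc <- boundary_spec(90, inlet_speed = 0.01, inlet_hematocrit = 0,
                      inlet_Y0 = 0)
  st <- initialize_state(m, bc)
  res <- advance_momentum(st, m, 0.02, bc)
  h <- m$cell_size * 1e-3
  qin <- 0.01 * (m$nx + m$ny) * h
  qout <- sum(res$v[, m$ny + 1]) * h
  expect_lt(abs(qout - qin) / qin, 1e-8)
})

test_that("a coupled step advances time by dt and keeps every invariant", {
  m <- build_mesh(build_layout(domain_height = 2, n_threads = 2L,
                               thread_height = 1.0), 0.05)
  props <- fluid_properties()
  bc <- boundary_spec(5)
  cfg <- solver_config(dt = 1e-4)
  st <- initialize_state(m, bc)
  for (k in 1:3) {
    st <- step(st, m, props, bc, cfg)
    expect_equal(st$time, k * cfg$dt, tolerance = 1e-12)
    expect_true(all(st$alpha_p >= 0 & st$alpha_p <= 1))
    expect_true(all(st$Y0 >= 0 & st$Y0 < 1))
    expect_lt(attr(st, "fib_mass_residual"), cfg$inner_tolerance)
  }
  # velocity is zero inside solid cells
  solid <- which(!m$is_fluid, arr.ind = TRUE)
  for (r in seq_len(min(nrow(solid), 20))) {
    i <- solid[r, 1]; j <- solid[r, 2]
    expect_equal(st$u[i, j], 0)
    expect_equal(st$u[i + 1, j], 0)
    expect_equal(st$v[i, j], 0)
    expect_equal(st$v[i, j + 1], 0)
  }
})

test_that("closed-domain plasma and fibrinogen are conserved through full physics", {
  # closed box with an off-center plasma blob in RBC ambient, surface
  # tension on: flux-form transport keeps both totals to machine precision
  m <- small_channel(height = 2, width = 2, cell = 0.1)
  bc <- quiet_bc(theta = 70)
  props <- fluid_properties()
  st <- initialize_state(m, bc)
  st$alpha_p[] <- 0.2
  blob <- outer((m$x - 0.8)^2, rep(1, m$ny)) +
    outer(rep(1, m$nx), (m$y - 1)^2 ) <= 0.5^2
  st$alpha_p[blob] <- 1
  st$Y0[] <- 0.002
  vol0 <- sum(st$alpha_p)
  fib0 <- interfacial_mass(st, m, "fibrinogen", props, total = TRUE)
  cfg <- solver_config(dt = 1e-4, t_end = 0.02)
  a <- implantflow:::core_args(m, props, bc, cfg)
  out <- implantflow:::core_run(a$solid, a$interfacial, a$dx, a$props, a$bc,
                                a$cfg, st$alpha_p,
                                implantflow:::state_q(st, props),
                                st$u, st$v, st$p, 0, 0.02)
  expect_lt(abs(sum(out$alpha) - vol0) / vol0, 1e-10)
  st1 <- st
  st1$alpha_p <- out$alpha
  st1 <- implantflow:::state_set_q(st1, out$q, props)
  fib1 <- interfacial_mass(st1, m, "fibrinogen", props, total = TRUE)
  expect_lt(abs(fib1 - fib0) / fib0, 1e-10)
  expect_true(all(out$alpha >= 0 & out$alpha <= 1))
})

test_that("runs are deterministic and t_end = 0 yields only the initial sample", {
  lay <- build_layout(domain_height = 1, n_threads = 1L, thread_height = 1.0)
  props <- fluid_properties()
  bc <- boundary_spec(50)
  cfg0 <- solver_config(dt = 1e-4, t_end = 0)
  r0 <- run_simulation(lay, props, bc, cfg0, cell_size = 0.1)
  expect_equal(nrow(infiltration_series(r0)), 1)
  expect_equal(infiltration_series(r0)$t, 0)

  cfg <- solver_config(dt = 1e-4, t_end = 5e-3)
  r1 <- run_simulation(lay, props, bc, cfg, cell_size = 0.1)
  r2 <- run_simulation(lay, props, bc, cfg, cell_size = 0.1)
  expect_identical(infiltration_series(r1), infiltration_series(r2))
  expect_identical(r1$final$alpha_p, r2$final$alpha_p)
})
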