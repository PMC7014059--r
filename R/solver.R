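#' Boundary conditions of the bone-implant channel flow
#'
#' Two velocity inlets (blood inlet at the bottom edge, alveolar bone at the
#' left edge, both 0.01 m/s by default) inject whole blood at 45% hematocrit
#' with fibrinogen mass fraction 0.0029 in the plasma; the top edge is a
#' zero-gauge-pressure free outlet; the right wall and the threads are the
#' no-slip implant surface where the plasma contact angle is enforced.
#'
#' @param contact_angle Contact angle between the implant surface and the
#'   blood plasma, degrees, in (0, 180). The hydrophilicity control: 5
#'   (superhydrophilic) to 100 (hydrorepellent) in the reference sweep.
#' @param inlet_speed Inlet velocity (m/s) at both inlets.
#' @param inlet_hematocrit RBC volume fraction at the inlets.
#' @param inlet_Y0 Fibrinogen mass fraction in the inlet plasma.
#' @param left_inlet,bottom_inlet Set `FALSE` to turn an inlet into a
#'   no-slip wall (used by the verification benchmarks).
#' @param top_outlet Set `FALSE` to close the top pressure outlet (a no-slip
#'   wall; the closed-box conservation benchmarks).
#' @return An object of class `boundary_spec`; `inlet_alpha_p` is
#'   `1 - inlet_hematocrit`.
#' @export
boundary_spec <- function(contact_angle, inlet_speed = 0.01,
                          inlet_hematocrit = 0.45,
                          inlet_Y0 = inlet_mass_fraction(),
                          left_inlet = TRUE, bottom_inlet = TRUE,
                          top_outlet = TRUE) {
  if (missing(contact_angle)) stop("contact_angle must be given explicitly")
  if (!is.finite(contact_angle) || contact_angle <= 0 || contact_angle >= 180)
    stop("contact_angle must lie strictly between 0 and 180 degrees")
  if (inlet_hematocrit < 0 || inlet_hematocrit > 1)
    stop("inlet_hematocrit must lie in [0, 1]")
  if (inlet_Y0 < 0 || inlet_Y0 >= 1) stop("inlet_Y0 must lie in [0, 1)")
  structure(list(contact_angle = contact_angle,
                 inlet_speed = inlet_speed,
                 inlet_hematocrit = inlet_hematocrit,
                 inlet_alpha_p = 1 - inlet_hematocrit,
                 inlet_Y0 = inlet_Y0,
                 left_inlet = isTRUE(left_inlet),
                 bottom_inlet = isTRUE(bottom_inlet),
                 top_outlet = isTRUE(top_outlet)),
            class = "boundary_spec")
}

#' Solver configuration
#'
#' @param dt Outer time-step size in seconds (the reporting/monitoring step;
#'   the solver sub-steps it internally to satisfy the explicit advective,
#'   viscous and capillary stability limits).
#' @param t_end End time in seconds.
#' @param inner_tolerance Per-step tolerance (kg) on the fibrinogen mass
#'   audit: the change in total fibrinogen mass minus the boundary flux
#'   integral must stay below this value.
#' @param max_inner_iterations Retained for interface compatibility; the
#'   explicit scheme is single-pass, so the audit replaces an inner loop.
#' @param cfl_safety Safety factor (0, 1\] on the stability limits.
#' @param sample_stride Record the mass series every this many outer steps.
#' @param nsmooth Number of smoothing passes on the volume fraction before
#'   curvature evaluation.
#' @param p_tol Pressure-solve convergence target: root-mean-square
#'   divergence residual of the corrected velocity field, in 1/s.
#' @param p_maxit Iteration cap of the preconditioned conjugate-gradient
#'   pressure solve.
#' @param grad_eps Curvature is evaluated only where the smoothed
#'   volume-fraction gradient exceeds this fraction of its maximum.
#' @param alpha_eps Plasma fractions below this treat the fibrinogen mass
#'   fraction as undefined (reported 0).
#' @param c_compress Interface-compression coefficient of the
#'   counter-gradient sharpening flux (1 = compression velocity equal to
#'   the local face speed, the standard choice; 0 disables it).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = 1e-4, t_end = 3.0, inner_tolerance = 1e-9,
                          max_inner_iterations = 1L, cfl_safety = 0.8,
                          sample_stride = 1L, nsmooth = 2L, p_tol = 2e-3,
                          p_maxit = 3000L,
                          grad_eps = 1e-3, alpha_eps = 1e-6,
                          c_compress = 0.5) {
  if (dt <= 0) stop("dt must be positive")
  if (t_end < 0) stop("t_end must be >= 0")
  if (inner_tolerance <= 0) stop("inner_tolerance must be positive")
  if (cfl_safety <= 0 || cfl_safety > 1) stop("cfl_safety must lie in (0, 1]")
  structure(list(dt = dt, t_end = t_end, inner_tolerance = inner_tolerance,
                 max_inner_iterations = as.integer(max_inner_iterations),
                 cfl_safety = cfl_safety,
                 sample_stride = as.integer(sample_stride),
                 nsmooth = as.integer(nsmooth), p_tol = p_tol,
                 p_maxit = as.integer(p_maxit),
                 grad_eps = grad_eps, alpha_eps = alpha_eps,
                 c_compress = c_compress),
            class = "solver_config")
}

# ---- state ------------------------------------------------------------------

#' Initial flow state
#'
#' The channel starts filled with quiescent, fibrinogen-free plasma
#' (`alpha_p = 1`, `Y0 = 0`, zero velocity and gauge pressure): plasma wets
#' the fresh wound site before whole blood flows in.
#'
#' @param mesh A zoned `implant_mesh`.
#' @param bc A [boundary_spec()] (stored with the state).
#' @return An object of class `flow_state` holding `alpha_p` (nx x ny), `Y0`
#'   (nx x ny), staggered velocities `u` ((nx+1) x ny) and `v` (nx x (ny+1)),
#'   `p` (nx x ny) and `time`.
#' @export
initialize_state <- function(mesh, bc) {
  stopifnot(inherits(mesh, "implant_mesh"), inherits(bc, "boundary_spec"))
  nx <- mesh$nx; ny <- mesh$ny
  alpha <- matrix(1, nx, ny)
  alpha[!mesh$is_fluid] <- 0
  structure(list(alpha_p = alpha,
                 Y0 = matrix(0, nx, ny),
                 u = matrix(0, nx + 1, ny),
                 v = matrix(0, nx, ny + 1),
                 p = matrix(0, nx, ny),
                 time = 0),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("flow state at t = %.4g s: alpha_p in [%.3g, %.3g], max |v| = %.3g m/s\n",
              x$time, min(x$alpha_p), max(x$alpha_p),
              max(abs(x$u), abs(x$v))))
  invisible(x)
}

# q = alpha * rho_m(Y) * Y (kg fibrinogen per m^3 of cell)
state_q <- function(state, props) {
  state$alpha_p * mixture_density(state$Y0, props) * state$Y0
}

state_set_q <- function(state, q, props, alpha_eps = 1e-6) {
  s <- q
  s[] <- 0
  ok <- state$alpha_p > alpha_eps
  s[ok] <- q[ok] / state$alpha_p[ok]
  Y <- (s / props$rho_plasma) /
    (1 + s * (1 / props$rho_plasma - 1 / props$rho_fibrinogen))
  Y[Y < 0] <- 0
  state$Y0 <- Y
  state
}

core_args <- function(mesh, props, bc, cfg) {
  list(solid = solid_matrix(mesh),
       interfacial = interfacial_matrix(mesh),
       dx = mesh$cell_size * 1e-3,
       props = unclass(props),
       bc = list(u_in = if (bc$left_inlet) bc$inlet_speed else 0,
                 v_in = if (bc$bottom_inlet) bc$inlet_speed else 0,
                 alpha_in = bc$inlet_alpha_p,
                 Y_in = bc$inlet_Y0,
                 theta_rad = bc$contact_angle * pi / 180,
                 left_inlet = bc$left_inlet,
                 bottom_inlet = bc$bottom_inlet,
                 top_outlet = bc$top_outlet),
       cfg = unclass(cfg))
}

check_state <- function(state, mesh) {
  stopifnot(inherits(state, "flow_state"))
  if (nrow(state$alpha_p) != mesh$nx || ncol(state$alpha_p) != mesh$ny)
    stop("state and mesh dimensions disagree")
  invisible(TRUE)
}

n_substeps_for <- function(state, mesh, props, cfg, dt, momentum = TRUE,
                           sigma = props$sigma) {
  dx <- mesh$cell_size * 1e-3
  umax <- max(abs(state$u), abs(state$v), 1e-12)
  lim <- dx / umax
  if (momentum) {
    numax <- max(props$mu_rbc / props$rho_rbc,
                 plasma_viscosity(3) / props$rho_plasma, 1e-12)
    lim <- min(lim, 0.25 * dx^2 / numax)
    if (sigma > 0) {
      rbar <- 0.5 * (props$rho_plasma + props$rho_rbc)
      lim <- min(lim, sqrt(rbar * dx^3 / (2 * pi * sigma)))
    }
  }
  if (props$D_fib > 0) lim <- min(lim, 0.25 * dx^2 / props$D_fib)
  max(1L, ceiling(dt / (cfg$cfl_safety * lim)))
}

run_core_advance <- function(state, mesh, props, bc, cfg, dt, nsub,
                             do_momentum, do_vof, do_species, do_st) {
  a <- core_args(mesh, props, bc, cfg)
  out <- core_advance(a$solid, a$interfacial, a$dx, a$props, a$bc, a$cfg,
                      state$alpha_p, state_q(state, props),
                      state$u, state$v, state$p,
                      state$time, dt, as.integer(nsub),
                      do_momentum, do_vof, do_species, do_st)
  new <- state
  new$alpha_p <- out$alpha
  new <- state_set_q(new, out$q, props, cfg$alpha_eps)
  new$u <- out$u; new$v <- out$v; new$p <- out$p
  new$time <- out$time
  attr(new, "fib_boundary_flux") <- out$fib_boundary_flux
  attr(new, "p_fail") <- out$p_fail
  new
}

# ---- single-operator advances ----------------------------------------------

#' Advance the plasma volume fraction by conservative VOF transport
#'
#' Flux-corrected transport with a compressive (Superbee-limited) high-order
#' flux: conservative to machine precision and bounded in \[0, 1\]. Face
#' velocities are taken from the state and are not modified.
#'
#' @param state A `flow_state`.
#' @param mesh A zoned `implant_mesh`.
#' @param dt Time increment (s), sub-stepped internally to the advective CFL.
#' @param bc,props,cfg Simulation setup objects.
#' @return The advanced `flow_state`.
#' @export
advance_vof <- function(state, mesh, dt, bc, props = fluid_properties(),
                        cfg = solver_config()) {
  check_state(state, mesh)
  nsub <- n_substeps_for(state, mesh, props, cfg, dt, momentum = FALSE)
  run_core_advance(state, mesh, props, bc, cfg, dt, nsub,
                   do_momentum = FALSE, do_vof = TRUE, do_species = FALSE,
                   do_st = FALSE)
}

#' Advance the fibrinogen mass fraction by advection and Fickian diffusion
#'
#' Fibrinogen is transported inside the plasma phase: advective fluxes ride
#' the limited volume-fraction fluxes (so fibrinogen cannot enter RBC-phase
#' volume) and diffusive fluxes are weighted by the face plasma fraction.
#'
#' @inheritParams advance_vof
#' @return The advanced `flow_state`. Attribute `fib_boundary_flux` carries
#'   the boundary flux integral (kg, influx positive) for mass audits.
#' @export
advance_species <- function(state, mesh, dt, bc, props = fluid_properties(),
                            cfg = solver_config()) {
  check_state(state, mesh)
  nsub <- n_substeps_for(state, mesh, props, cfg, dt, momentum = FALSE)
  run_core_advance(state, mesh, props, bc, cfg, dt, nsub,
                   do_momentum = FALSE, do_vof = FALSE, do_species = TRUE,
                   do_st = FALSE)
}

#' Continuum-surface-force field
#'
#' `F = sigma * kappa * grad(alpha_p)` with the curvature computed from the
#' smoothed volume fraction and the interface normal rotated at
#' implant-adjacent cells to enforce the contact angle.
#'
#' @inheritParams advance_vof
#' @return A list with cell-centered force density components `fx`, `fy`
#'   (N/m^3), face values `fx_face`, `fy_face`, and `kappa` (1/m).
#' @export
compute_csf_force <- function(state, mesh, props = fluid_properties(),
                              bc = boundary_spec(contact_angle = 90),
                              cfg = solver_config()) {
  check_state(state, mesh)
  a <- core_args(mesh, props, bc, cfg)
  core_csf(a$solid, a$dx, a$props, a$bc, a$cfg, state$alpha_p)
}

#' Advance momentum and project to a divergence-free velocity
#'
#' One explicit predictor step of the variable-density, variable-viscosity
#' momentum equation (central advection, face-based CSF body force) followed
#' by a variable-coefficient pressure projection with fixed inlet velocities
#' and a zero-gauge-pressure outlet.
#'
#' @inheritParams advance_vof
#' @param with_surface_tension Include the CSF body force.
#' @return The advanced `flow_state` (composition fields untouched).
#' @export
advance_momentum <- function(state, mesh, dt, bc, props = fluid_properties(),
                             cfg = solver_config(),
                             with_surface_tension = TRUE) {
  check_state(state, mesh)
  nsub <- n_substeps_for(state, mesh, props, cfg, dt, momentum = TRUE,
                         sigma = if (with_surface_tension) props$sigma else 0)
  out <- run_core_advance(state, mesh, props, bc, cfg, dt, nsub,
                          do_momentum = TRUE, do_vof = FALSE,
                          do_species = FALSE, do_st = with_surface_tension)
  if (attr(out, "p_fail") > 0)
    warning(sprintf("pressure solve hit the iteration cap in %d sub-step(s)",
                    attr(out, "sor_fail")))
  out
}

#' One coupled time step
#'
#' Advances momentum/pressure, the plasma volume fraction, and the
#' fibrinogen field by one outer step `cfg$dt`, internally sub-stepped for
#' stability. The per-step fibrinogen mass audit (change in total mass minus
#' boundary flux, threshold `cfg$inner_tolerance`) is attached as attribute
#' `fib_mass_residual`.
#'
#' @param state A `flow_state`.
#' @param mesh A zoned `implant_mesh`.
#' @param props,bc,cfg Simulation setup objects.
#' @return The advanced `flow_state`, `cfg$dt` later.
#' @export
step <- function(state, mesh, props, bc, cfg) {
  check_state(state, mesh)
  m0 <- interfacial_mass(state, mesh, "fibrinogen", props, total = TRUE) * 1e-6
  nsub <- n_substeps_for(state, mesh, props, cfg, cfg$dt, momentum = TRUE)
  out <- run_core_advance(state, mesh, props, bc, cfg, cfg$dt, nsub,
                          do_momentum = TRUE, do_vof = TRUE,
                          do_species = TRUE, do_st = TRUE)
  m1 <- interfacial_mass(out, mesh, "fibrinogen", props, total = TRUE) * 1e-6
  attr(out, "fib_mass_residual") <- abs((m1 - m0) - attr(out, "fib_boundary_flux"))
  out
}

# ---- full run ---------------------------------------------------------------

#' Run a full simulation
#'
#' Integrates the coupled system from t = 0 to `cfg$t_end`, recording the
#' interfacial and total fibrinogen and plasma masses every
#' `cfg$sample_stride` outer steps. Deterministic: no random numbers are
#' used anywhere.
#'
#' @param layout An `implant_layout` (or a ready zoned `implant_mesh` via
#'   `mesh`).
#' @param props A [fluid_properties()] object.
#' @param bc A [boundary_spec()].
#' @param cfg A [solver_config()].
#' @param cell_size Cell size in mm used to rasterize `layout` (ignored when
#'   `mesh` is given).
#' @param mesh Optional pre-built zoned mesh.
#' @param snapshot_times Times (s) at which full field snapshots are kept
#'   (each rounded up to the next sampled step).
#' @return An object of class `implant_run`: `series` (data.frame, see
#'   [infiltration_series()]), `final` (`flow_state`), `snapshots`, `mesh`,
#'   the configuration objects, and solver diagnostics.
#' @export
run_simulation <- function(layout, props, bc, cfg, cell_size = 0.05,
                           mesh = NULL, snapshot_times = numeric()) {
  if (is.null(mesh)) mesh <- build_mesh(layout, cell_size)
  if (is.null(mesh$zone)) mesh <- assign_zones(mesh)
  state <- initialize_state(mesh, bc)
  a <- core_args(mesh, props, bc, cfg)
  times <- sort(unique(c(snapshot_times[snapshot_times > 0 &
                                          snapshot_times <= cfg$t_end],
                         cfg$t_end)))
  if (cfg$t_end == 0) times <- numeric()
  segs <- c(0, times)
  snapshots <- list()
  series_parts <- list()
  diag <- list(n_substeps = 0, max_fib_residual = 0, inner_violations = 0,
               p_fail = 0)
  cur <- state
  for (k in seq_along(times)) {
    out <- core_run(a$solid, a$interfacial, a$dx, a$props, a$bc, a$cfg,
                    cur$alpha_p, state_q(cur, props), cur$u, cur$v, cur$p,
                    segs[k], segs[k + 1])
    cur$alpha_p <- out$alpha
    cur <- state_set_q(cur, out$q, props, cfg$alpha_eps)
    cur$u <- out$u; cur$v <- out$v; cur$p <- out$p; cur$time <- out$time
    sr <- out$series
    series_parts[[k]] <- if (k == 1) sr else sr[-1, , drop = FALSE]
    diag$n_substeps <- diag$n_substeps + out$n_substeps
    diag$max_fib_residual <- max(diag$max_fib_residual, out$max_fib_residual)
    diag$inner_violations <- diag$inner_violations + out$inner_violations
    diag$p_fail <- diag$p_fail + out$p_fail
    if (times[k] %in% snapshot_times || k == length(times))
      snapshots[[sprintf("t=%g", cur$time)]] <- cur
  }
  if (length(series_parts) == 0) {
    # t_end = 0: the series holds only the initial sample
    out <- core_run(a$solid, a$interfacial, a$dx, a$props, a$bc, a$cfg,
                    state$alpha_p, state_q(state, props),
                    state$u, state$v, state$p, 0, 0)
    series_parts[[1]] <- out$series
    cur <- state
  }
  raw <- do.call(rbind, series_parts)
  series <- data.frame(t = raw[, 1],
                       fib_interfacial = raw[, 2] * 1e6,    # kg -> mg
                       fib_total = raw[, 3] * 1e6,
                       plasma_interfacial = raw[, 4] * 1e6,
                       plasma_total = raw[, 5] * 1e6)
  series$fib_rate <- ifelse(series$fib_total > 0,
                            100 * series$fib_interfacial / series$fib_total,
                            NA_real_)
  series$plasma_rate <- ifelse(series$plasma_total > 0,
                               100 * series$plasma_interfacial / series$plasma_total,
                               NA_real_)
  structure(list(series = series, final = cur, snapshots = snapshots,
                 mesh = mesh, layout = mesh$layout, props = props, bc = bc,
                 cfg = cfg, diagnostics = diag),
            class = "implant_run")
}

#' @export
print.implant_run <- function(x, ...) {
  cat(sprintf("implant-channel run: contact angle %g deg, t_end %g s, %d samples\n",
              x$bc$contact_angle, x$cfg$t_end, nrow(x$series)))
  cat(sprintf("  3 s means: fibrinogen %.3g mg (%.3g%%), plasma %.4g mg (%.3g%%)\n",
              mean_infiltration(x, "fibrinogen"), mean_rate(x, "fibrinogen"),
              mean_infiltration(x, "plasma"), mean_rate(x, "plasma")))
  invisible(x)
}
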