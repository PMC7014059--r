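#' Material constants and constitutive laws of the blood model
#'
#' Bundles the material constants: plasma density 1025 kg/m^3, fibrinogen
#' density 1400 kg/m^3, red-blood-cell density 1125 kg/m^3 and viscosity
#' 0.0050 Pa.s, plasma-RBC interfacial tension 0.021 N/m, fibrinogen
#' diffusion coefficient 0.23e-10 m^2/s (its value in water, taken over to
#' plasma), and the piecewise fibrinogen-concentration-dependent plasma
#' viscosity law.
#'
#' The viscosity law gives the plasma viscosity in Pa.s as
#' `(1.16 C + 0.53) e-3` for C in \[0, 0.40), `(0.37 C + 0.85) e-3` for C in
#' \[0.40, 1.00) and `(0.19 C^2 + 1.03) e-3` for C >= 1.00, with C the
#' fibrinogen concentration in g/100 mL. The law is continuous at C = 1.00
#' and has a small (< 1%) printed discontinuity at C = 0.40 which is kept as
#' is.
#'
#' @param ... Named overrides for any constant (e.g. `sigma = 0.05`).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(...) {
  p <- list(
    rho_plasma = 1025,      # kg/m^3, fibrinogen-free plasma
    rho_fibrinogen = 1400,  # kg/m^3
    rho_rbc = 1125,         # kg/m^3
    mu_rbc = 0.0050,        # Pa.s
    sigma = 0.021,          # N/m, plasma-RBC interfacial tension
    D_fib = 0.23e-10,       # m^2/s
    # rows: a, b, c, lo, hi with mu = (a C^2 + b C + c) * 1e-3 on [lo, hi)
    viscosity_pieces = matrix(c(0.00, 1.16, 0.53, 0.00, 0.40,
                                0.00, 0.37, 0.85, 0.40, 1.00,
                                0.19, 0.00, 1.03, 1.00, Inf),
                              nrow = 3, byrow = TRUE,
                              dimnames = list(NULL, c("a", "b", "c", "lo", "hi")))
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown property: ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  sc <- p[c("rho_plasma", "rho_fibrinogen", "rho_rbc", "mu_rbc")]
  if (any(unlist(sc) <= 0)) stop("material constants must be strictly positive")
  if (p$sigma < 0 || p$D_fib < 0) stop("sigma and D_fib must be >= 0")
  structure(p, class = "fluid_properties")
}

#' Density of the plasma-fibrinogen mixture
#'
#' Harmonic (volume-weighted) mixing of fibrinogen (1400 kg/m^3) and
#' fibrinogen-free plasma (1025 kg/m^3) by mass fraction:
#' `rho_m = 1 / (Y0/rho0 + (1 - Y0)/rho1)`.
#'
#' @param Y0 Fibrinogen mass fraction in plasma, in \[0, 1\].
#' @param props A [fluid_properties()] object.
#' @return Mixture density in kg/m^3.
#' @export
mixture_density <- function(Y0, props = fluid_properties()) {
  if (any(!is.finite(Y0)) || any(Y0 < 0 | Y0 > 1))
    stop("Y0 must lie in [0, 1]")
  1 / (Y0 / props$rho_fibrinogen + (1 - Y0) / props$rho_plasma)
}

#' Plasma viscosity as a function of fibrinogen concentration
#'
#' Piecewise law (two linear branches, one quadratic) in the concentration C
#' expressed in g/100 mL; see [fluid_properties()] for the coefficients.
#'
#' @param C Fibrinogen concentration, g/100 mL (>= 0). Vectorized.
#' @param props A [fluid_properties()] object.
#' @return Dynamic viscosity in Pa.s.
#' @export
plasma_viscosity <- function(C, props = fluid_properties()) {
  if (any(!is.finite(C)) || any(C < 0)) stop("C must be >= 0")
  vp <- props$viscosity_pieces
  out <- numeric(length(C))
  for (k in seq_len(nrow(vp))) {
    sel <- C >= vp[k, "lo"] & C < vp[k, "hi"]
    out[sel] <- (vp[k, "a"] * C[sel]^2 + vp[k, "b"] * C[sel] + vp[k, "c"]) * 1e-3
  }
  out
}

#' Convert a fibrinogen mass fraction to a concentration
#'
#' `C = 0.1 * Y0 * rho_m` converts the mass fraction and mixture density
#' (kg/m^3) to g/100 mL (1 kg/m^3 = 0.1 g/100 mL).
#'
#' @param Y0 Fibrinogen mass fraction.
#' @param rho_m Mixture density in kg/m^3 (defaults to
#'   [mixture_density()] of `Y0`).
#' @param props A [fluid_properties()] object.
#' @return Concentration in g/100 mL.
#' @export
concentration_from_mass_fraction <- function(Y0, rho_m = mixture_density(Y0, props),
                                             props = fluid_properties()) {
  0.1 * Y0 * rho_m
}

#' Convert a concentration back to a mass fraction
#'
#' Inverse of [concentration_from_mass_fraction()] under the harmonic mixing
#' law (closed form; the mixing law is linear in 1/rho).
#'
#' @param C Concentration in g/100 mL.
#' @param props A [fluid_properties()] object.
#' @return Fibrinogen mass fraction.
#' @export
mass_fraction_from_concentration <- function(C, props = fluid_properties()) {
  s <- 10 * C                                   # kg fibrinogen per m^3 mixture
  (s / props$rho_plasma) /
    (1 + s * (1 / props$rho_plasma - 1 / props$rho_fibrinogen))
}

#' Inlet fibrinogen mass fraction from serum values
#'
#' Divides the serum fibrinogen concentration by the serum density and
#' rounds to 2 significant figures (the convention used for the default
#' boundary condition: 3 kg/m^3 over 1024 kg/m^3 gives 0.0029).
#'
#' @param serum_fib Serum fibrinogen concentration in kg/m^3 (300 mg/dL = 3).
#' @param serum_density Serum density in kg/m^3.
#' @return Mass fraction, rounded to 2 significant figures.
#' @export
inlet_mass_fraction <- function(serum_fib = 3, serum_density = 1024) {
  if (serum_density <= 0) stop("serum density must be positive")
  if (serum_fib < 0) stop("serum fibrinogen concentration must be >= 0")
  signif(serum_fib / serum_density, 2)
}

#' Blended density and viscosity of a mixed plasma/RBC cell
#'
#' Arithmetic volume-fraction weighting (the standard volume-of-fluid
#' mixture rule): `rho = alpha_p * rho_m(Y0) + (1 - alpha_p) * rho_rbc` and
#' likewise for viscosity with the concentration-dependent plasma viscosity.
#'
#' @param alpha_p Plasma volume fraction in \[0, 1\].
#' @param Y0 Fibrinogen mass fraction in the plasma.
#' @param props A [fluid_properties()] object.
#' @return A list with `density` (kg/m^3) and `viscosity` (Pa.s).
#' @export
cell_mixture_properties <- function(alpha_p, Y0 = 0, props = fluid_properties()) {
  if (any(!is.finite(alpha_p)) || any(alpha_p < 0 | alpha_p > 1))
    stop("alpha_p must lie in [0, 1]")
  rho_m <- mixture_density(Y0, props)
  C <- concentration_from_mass_fraction(Y0, rho_m, props)
  mu_m <- plasma_viscosity(C, props)
  list(density = alpha_p * rho_m + (1 - alpha_p) * props$rho_rbc,
       viscosity = alpha_p * mu_m + (1 - alpha_p) * props$mu_rbc)
}

#' Reynolds number
#'
#' `rho * v * L / mu`.
#'
#' @param rho Density (kg/m^3).
#' @param speed Velocity scale (m/s).
#' @param length Length scale (m).
#' @param mu Dynamic viscosity (Pa.s, > 0).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(rho, speed, length, mu) {
  if (any(mu <= 0)) stop("viscosity must be positive")
  rho * speed * length / mu
}

#' Inlet Reynolds number of the whole-blood flow
#'
#' Uses the channel width as the length scale and the inlet-composition
#' blended density and viscosity (45% RBC phase, plasma carrying fibrinogen
#' at the inlet mass fraction). With the default configuration this rounds
#' to 6, confirming the laminar regime (transition near 2800).
#'
#' @param bc A [boundary_spec()] (for the inlet speed and composition).
#' @param layout An `implant_layout` (for the channel width).
#' @param props A [fluid_properties()] object.
#' @return The Reynolds number (not rounded).
#' @export
inlet_reynolds_number <- function(bc = boundary_spec(contact_angle = 5),
                                  layout = build_layout(),
                                  props = fluid_properties()) {
  mix <- cell_mixture_properties(bc$inlet_alpha_p, bc$inlet_Y0, props)
  reynolds_number(mix$density, bc$inlet_speed,
                  layout$domain_width * 1e-3, mix$viscosity)
}
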