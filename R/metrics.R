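#' Mass of fibrinogen or blood plasma in the interfacial zone
#'
#' Infiltration is the mass of a blood component in the interfacial zone:
#' for fibrinogen the sum over interfacial fluid cells of
#' `alpha_p * rho_m(Y0) * Y0 * cell_area * depth`, for plasma the same with
#' `(1 - Y0)` in place of `Y0`. Masses are per 1 m of depth (the 2D
#' convention) and returned in mg.
#'
#' @param state A `flow_state`.
#' @param mesh A zoned `implant_mesh`.
#' @param species `"fibrinogen"` or `"plasma"`.
#' @param props A [fluid_properties()] object.
#' @param total Sum over all fluid cells instead of the interfacial zone.
#' @return Mass in mg.
#' @export
interfacial_mass <- function(state, mesh,
                             species = c("fibrinogen", "plasma"),
                             props = fluid_properties(), total = FALSE) {
  species <- match.arg(species)
  if (is.null(mesh$zone)) stop("mesh has no zones; call assign_zones() first")
  sel <- if (total) mesh$is_fluid else
    mesh$is_fluid & mesh$zone == "interfacial" & !is.na(mesh$zone)
  V <- (mesh$cell_size * 1e-3)^2 * mesh$depth_m     # m^3 per cell
  a <- state$alpha_p[sel]
  Y <- state$Y0[sel]
  rm <- mixture_density(Y, props)
  frac <- if (species == "fibrinogen") Y else 1 - Y
  sum(a * rm * frac) * V * 1e6                      # kg -> mg
}

#' Infiltration rate
#'
#' Interfacial mass of a component divided by its total mass in the fluid
#' zone, in percent. Undefined (NA) when the total mass is zero.
#'
#' @inheritParams interfacial_mass
#' @return Percent in \[0, 100\], or `NA` when undefined.
#' @export
infiltration_rate <- function(state, mesh,
                              species = c("fibrinogen", "plasma"),
                              props = fluid_properties()) {
  species <- match.arg(species)
  tot <- interfacial_mass(state, mesh, species, props, total = TRUE)
  if (tot <= 0) return(NA_real_)
  100 * interfacial_mass(state, mesh, species, props) / tot
}

#' Infiltration time series of a run
#'
#' @param run An `implant_run`.
#' @return A data.frame with columns `t` (s), `fib_interfacial`,
#'   `fib_total`, `plasma_interfacial`, `plasma_total` (mg per 1 m depth),
#'   `fib_rate` and `plasma_rate` (percent; `NA` where the total mass is
#'   zero, e.g. fibrinogen at t = 0).
#' @export
infiltration_series <- function(run) {
  stopifnot(inherits(run, "implant_run"))
  run$series
}

trapz_mean <- function(t, y) {
  keep <- is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 2) return(if (length(t)) y else NA_real_)
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2) / (max(t) - min(t))
}

#' @importFrom utils head tail
mean_infiltration <- function(run, species = c("fibrinogen", "plasma")) {
  species <- match.arg(species)
  s <- infiltration_series(run)
  col <- if (species == "fibrinogen") "fib_interfacial" else "plasma_interfacial"
  trapz_mean(s$t, s[[col]])
}

mean_rate <- function(run, species = c("fibrinogen", "plasma")) {
  species <- match.arg(species)
  s <- infiltration_series(run)
  col <- if (species == "fibrinogen") "fib_rate" else "plasma_rate"
  trapz_mean(s$t, s[[col]])
}

#' Early/mid/late stage summaries of an infiltration series
#'
#' Splits the run into the early \[0, 1) s, mid \[1, 2) s, and late \[2, 3\] s
#' stages and reports each stage's time-averaged interfacial mass
#' (trapezoidal; numerically the stage time integral in mg.s divided by the
#' 1 s stage length, so the three stage values average to the whole-run
#' mean).
#'
#' @param series An infiltration series data.frame (or an `implant_run`).
#' @param species `"fibrinogen"` or `"plasma"`.
#' @param breaks Stage boundaries in seconds.
#' @return A data.frame with `stage`, `from`, `to`, `value` (mg) and
#'   `covered` (FALSE where the series does not span the stage).
#' @export
stage_summary <- function(series, species = c("fibrinogen", "plasma"),
                          breaks = c(0, 1, 2, 3)) {
  if (inherits(series, "implant_run")) series <- infiltration_series(series)
  species <- match.arg(species)
  col <- if (species == "fibrinogen") "fib_interfacial" else "plasma_interfacial"
  stages <- c("early", "mid", "late")[seq_len(length(breaks) - 1)]
  out <- data.frame(stage = stages, from = head(breaks, -1), to = tail(breaks, -1),
                    value = NA_real_, covered = FALSE)
  tmax <- max(series$t)
  for (k in seq_len(nrow(out))) {
    sel <- series$t >= out$from[k] - 1e-12 & series$t <= out$to[k] + 1e-12
    if (sum(sel) >= 2) {
      out$value[k] <- trapz_mean(series$t[sel], series[[col]][sel])
      out$covered[k] <- tmax >= out$to[k] - 1e-9
    }
  }
  out
}

#' Ratios of stage values to the reference contact angle
#'
#' Reproduces the structure of the stage-integral tables: each (stage,
#' angle) value divided by the 5 degree (reference) value for that stage.
#'
#' @param summaries Named list of [stage_summary()] data.frames, one per
#'   contact angle; names are the angles in degrees.
#' @param reference Reference angle (default `"5"`).
#' @param digits Rounding applied to the reported ratio (2 decimals, the
#'   table convention).
#' @return A data.frame with `stage`, one `value_<angle>` and one
#'   `ratio_<angle>` column per angle.
#' @export
ratio_table <- function(summaries, reference = "5", digits = 2) {
  if (!reference %in% names(summaries))
    stop("reference angle ", reference, " missing from summaries")
  ref <- summaries[[reference]]
  out <- data.frame(stage = ref$stage)
  for (nm in names(summaries)) {
    s <- summaries[[nm]]
    out[[paste0("value_", nm)]] <- s$value
    out[[paste0("ratio_", nm)]] <- round(s$value / ref$value, digits)
  }
  out
}

#' Pearson correlation between two infiltration-rate series
#'
#' Sample Pearson coefficient with a two-sided p-value from the t transform
#' with n - 2 degrees of freedom (via [stats::cor.test()]), plus the
#' regression line for scatter plots.
#'
#' @param x,y Numeric series of equal length (NA pairs dropped).
#' @return A list with `R`, `p_value`, `n`, `slope`, `intercept`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant series")
  ct <- stats::cor.test(x, y, method = "pearson")
  slope <- stats::cov(x, y) / stats::var(x)
  list(R = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       slope = slope, intercept = mean(y) - slope * mean(x))
}
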