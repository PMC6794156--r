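# Steady hyperemic hemodynamics of a stenosed conduit.
#
# Pressure-drop law for a segment at flow q:
#   dP(q) = Rv * q + S * q * |q|
# with Rv the Poiseuille integral 8*pi*mu / A(s)^2 over the segment and S the
# expansion (separation) loss (Kt*rho/2) * (1/A_min - 1/A_out)^2 summed over
# constrictions, A = pi r^2. Internally SI, externally mmHg / mL/s / mm.

MMHG_PER_PA <- 1 / 133.322
ML_PER_M3 <- 1e6
KT_EXPANSION <- 1.52

#' Blood fluid properties
#'
#' @param mu Dynamic viscosity (Pa s), default 0.0035.
#' @param rho Density (kg/m^3), default 1050.
#' @return A list of class `fluid_properties`.
#' @export
fluid_properties <- function(mu = 0.0035, rho = 1050) {
  stopifnot(mu > 0, rho > 0)
  structure(list(mu = mu, rho = rho), class = "fluid_properties")
}

#' Boundary condition terminating the epicardial vessel
#'
#' @param pa Aortic (inlet) pressure, mmHg.
#' @param pv Venous outflow pressure, mmHg.
#' @param r_micro Downstream microvascular resistance, mmHg s/mL.
#' @return A list of class `ffr_bc`.
#' @export
boundary_condition <- function(pa = 90, pv = 0, r_micro) {
  stopifnot(pa > pv, pv >= 0, r_micro > 0)
  structure(list(pa = pa, pv = pv, r_micro = r_micro), class = "ffr_bc")
}

# Clip a profile to [start, end], interpolating the boundary samples.
clip_profile <- function(geom, extent) {
  s <- geom$s_mm
  inside <- s > extent[1] & s < extent[2]
  s_clip <- c(extent[1], s[inside], extent[2])
  r_clip <- c(radius_at(geom, extent[1]), geom$r_mm[inside],
              radius_at(geom, extent[2]))
  keep <- c(TRUE, diff(s_clip) > 1e-12)
  list(s = s_clip[keep], r = r_clip[keep])
}

# Poiseuille resistance integral over an extent, mmHg s / mL.
poiseuille_resistance <- function(geom, extent, fluid) {
  prof <- clip_profile(geom, check_extent(geom, extent))
  if (any(prof$r <= 0)) stop("non-positive radius in extent", call. = FALSE)
  a_m2 <- pi * (prof$r * 1e-3)^2
  integrand <- 8 * pi * fluid$mu / a_m2^2          # Pa s / m^3 per m
  s_m <- prof$s * 1e-3
  rv_si <- sum(diff(s_m) * (utils::head(integrand, -1) + utils::tail(integrand, -1)) / 2)
  rv_si * MMHG_PER_PA / ML_PER_M3
}

# Expansion-loss coefficients of the constrictions inside an extent.
# Returns mmHg s^2 / mL^2 per constriction (possibly length 0) together with
# the throat and exit positions used to localize each loss.
expansion_losses <- function(geom, extent, fluid, min_pct = 5, edge_frac = 1e-4) {
  empty <- tibble::tibble(s_throat = numeric(), s_exit = numeric(),
                          coeff = numeric())
  prof <- clip_profile(geom, check_extent(geom, extent))
  if (length(prof$s) < 10) {  # short extent: densify before envelope fitting
    s_dense <- seq(prof$s[1], prof$s[length(prof$s)], length.out = 21)
    prof <- list(s = s_dense, r = stats::approx(prof$s, prof$r, xout = s_dense)$y)
  }
  s <- prof$s; r <- prof$r
  env <- concave_majorant(s, r)
  inside <- (1 - r / env) > edge_frac
  if (!any(inside)) return(empty)
  runs <- rle(inside)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  out <- purrr::map_dfr(which(runs$values), function(k) {
    i0 <- run_start[k]; i1 <- run_end[k]
    i_min <- i0 - 1L + which.min(r[i0:i1])
    pct <- 100 * (1 - r[i_min] / env[i_min])
    if (pct < min_pct) return(empty)
    # exit = first sample past the run; a run truncated by the extent
    # boundary expands into whatever lumen the boundary presents
    i_exit <- min(i1 + 1L, length(s))
    a_min <- pi * (r[i_min] * 1e-3)^2
    a_out <- pi * (r[i_exit] * 1e-3)^2
    if (a_out <= a_min) return(empty)
    coeff_si <- (KT_EXPANSION * fluid$rho / 2) * (1 / a_min - 1 / a_out)^2
    tibble::tibble(s_throat = s[i_min], s_exit = s[i_exit],
                   coeff = coeff_si * MMHG_PER_PA / ML_PER_M3^2)
  })
  out
}

# Rv and total S for an extent; the analytic coefficients of dP(q).
segment_coefficients <- function(geom, extent, fluid) {
  list(rv = poiseuille_resistance(geom, extent, fluid),
       s = sum(expansion_losses(geom, extent, fluid)$coeff))
}

#' Pressure drop across an extent at a given flow
#'
#' Evaluates the viscous + expansion-loss law `Rv q + S q |q|` on the sampled
#' profile: `Rv` by trapezoidal integration of the Poiseuille integrand and
#' `S` summed over the constrictions detected inside the extent.
#'
#' @param geom A [vessel_geometry()].
#' @param extent `c(start_mm, end_mm)` within the vessel.
#' @param q Flow rate, mL/s.
#' @param fluid A [fluid_properties()].
#' @return Pressure drop, mmHg (non-negative for `q >= 0`; exactly 0 at 0).
#' @export
segment_dp <- function(geom, extent, q, fluid = fluid_properties()) {
  geom <- as_vessel_geometry(geom)
  coef <- segment_coefficients(geom, extent, fluid)
  coef$rv * q + coef$s * q * abs(q)
}

#' Fine-grid steady flow and pressure solution (the project's ground truth)
#'
#' Resamples the vessel onto a fine grid, assembles the epicardial
#' pressure-drop law, and finds the flow `q > 0` satisfying
#' `pa - pv = dP_epicardial(q) + r_micro * q` by bracketed root-finding with a
#' Newton polish (residual below `1e-9 * (pa - pv)`). The pressure profile is
#' accumulated from the inlet; each constriction's expansion loss is recovered
#' linearly between its throat and its exit.
#'
#' @param geom A [vessel_geometry()].
#' @param bc A [boundary_condition()].
#' @param fluid A [fluid_properties()].
#' @param ds Fine-grid spacing, mm (default 0.05).
#' @return An object of class `ffr_solution`: flow `q_ml_s`, a `profile`
#'   tibble (`s_mm`, `p_mmHg`, `ffr`) and solver metadata.
#' @export
oracle_solve <- function(geom, bc, fluid = fluid_properties(), ds = 0.05) {
  geom <- resample_vessel(as_vessel_geometry(geom), ds = ds)
  pa_pv <- bc$pa - bc$pv

  a_m2 <- pi * (geom$r_mm * 1e-3)^2
  integrand <- 8 * pi * fluid$mu / a_m2^2
  ds_m <- diff(geom$s_mm) * 1e-3
  rv_steps <- ds_m * (utils::head(integrand, -1) + utils::tail(integrand, -1)) / 2
  rv_cum <- c(0, cumsum(rv_steps)) * MMHG_PER_PA / ML_PER_M3
  rv_tot <- rv_cum[length(rv_cum)]

  losses <- expansion_losses(geom, range(geom$s_mm), fluid)
  s_cum <- rep(0, nrow(geom))
  if (nrow(losses) > 0) {
    for (i in seq_len(nrow(losses))) {
      frac <- pmin(1, pmax(0, (geom$s_mm - losses$s_throat[i]) /
                                max(losses$s_exit[i] - losses$s_throat[i], 1e-9)))
      s_cum <- s_cum + frac * losses$coeff[i]
    }
  }
  s_tot <- sum(losses$coeff)

  f <- function(q) pa_pv - rv_tot * q - s_tot * q^2 - bc$r_micro * q
  lo <- 1e-6; hi <- 50
  if (f(lo) <= 0 || f(hi) >= 0) {
    stop(sprintf(
      "no flow bracket in [%g, %g] mL/s (f(lo)=%.3g, f(hi)=%.3g); check the boundary condition",
      lo, hi, f(lo), f(hi)), call. = FALSE)
  }
  q <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  for (i in 1:4) {  # Newton polish; f is smooth and strictly decreasing
    q <- q + f(q) / (rv_tot + 2 * s_tot * q + bc$r_micro)
  }
  if (abs(f(q)) > 1e-9 * pa_pv) {
    stop("flow solve did not converge to the required residual", call. = FALSE)
  }

  p <- bc$pa - rv_cum * q - s_cum * q^2
  new_ffr_solution(
    q = q,
    profile = tibble::tibble(s_mm = geom$s_mm, p_mmHg = p, ffr = p / bc$pa),
    bc = bc, fluid = fluid,
    meta = list(method = "fine-grid", ds = ds, rv_total = rv_tot,
                s_total = s_tot, losses = losses,
                label = vessel_label(geom))
  )
}

new_ffr_solution <- function(q, profile, bc, fluid, meta = list()) {
  structure(list(q_ml_s = q, profile = profile, bc = bc, fluid = fluid,
                 meta = meta),
            class = "ffr_solution")
}

#' @export
print.ffr_solution <- function(x, ...) {
  cat(sprintf("<ffr_solution> %s: q = %.3f mL/s, distal FFR = %.3f (%d samples)\n",
              x$meta$label %||% "vessel", x$q_ml_s,
              utils::tail(x$profile$ffr, 1), nrow(x$profile)))
  invisible(x)
}

#' FFR at a position along the vessel
#'
#' @param sol An `ffr_solution`.
#' @param pos_mm Position(s) along the vessel, mm.
#' @return FFR linearly interpolated at `pos_mm`.
#' @export
ffr_at <- function(sol, pos_mm) {
  prof <- sol$profile
  if (any(pos_mm < min(prof$s_mm) - 1e-9 | pos_mm > max(prof$s_mm) + 1e-9)) {
    stop("position outside the vessel", call. = FALSE)
  }
  stats::approx(prof$s_mm, prof$ffr, xout = pos_mm, rule = 2)$y
}

#' Distal (end-of-vessel) FFR of a solution
#'
#' @param sol An `ffr_solution`.
#' @return The FFR at the most distal sample.
#' @export
distal_ffr <- function(sol) utils::tail(sol$profile$ffr, 1)

#' Plot an FFR / pressure profile
#'
#' @param object An `ffr_solution`.
#' @param ... Unused.
#' @return A ggplot of FFR against arc length.
#' @export
autoplot.ffr_solution <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$s_mm, y = .data$ffr)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "arc length from ostium (mm)", y = "FFR",
                  title = sprintf("%s: q = %.2f mL/s",
                                  object$meta$label %||% "vessel",
                                  object$q_ml_s)) +
    ggplot2::ylim(min(object$profile$ffr) * 0.98, 1)
}
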