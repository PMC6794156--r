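# Hyperemic microvascular boundary conditions from three physiological
# principles: allometric scaling of resting coronary flow with myocardial
# mass, scaling of supplied mass with vessel caliber, and a fixed fractional
# reduction of microvascular resistance under maximal (adenosine) hyperemia.

#' Physiological model for boundary-condition construction
#'
#' @param myocardial_mass_g Myocardial mass subtended by the vessel, g.
#' @param q_scale Resting-flow coefficient (mL/s per g^k).
#' @param k Allometric exponent relating flow to mass (default 0.75, the
#'   metabolic scaling exponent).
#' @param hyperemia_factor Multiplicative microvascular-resistance reduction
#'   under maximal hyperemia, in (0, 1); default 0.24, the canonical adenosine
#'   value used throughout the CT-FFR literature.
#' @param radius_ref_mm,radius_exp Reference inlet radius (mm) and exponent of
#'   the caliber-mass allometry used by [scale_to_vessel()]; a vessel of
#'   inlet radius r is taken to subtend `myocardial_mass_g * (r/radius_ref_mm)^radius_exp`.
#' @return A list of class `physiology_model`.
#' @export
physiology_model <- function(myocardial_mass_g = 100, q_scale = 0.013,
                             k = 0.75, hyperemia_factor = 0.24,
                             radius_ref_mm = 1.8, radius_exp = 2.6) {
  stopifnot(myocardial_mass_g > 0, q_scale > 0,
            k > 0, k <= 1,
            hyperemia_factor > 0, hyperemia_factor < 1,
            radius_ref_mm > 0)
  structure(list(myocardial_mass_g = myocardial_mass_g, q_scale = q_scale,
                 k = k, hyperemia_factor = hyperemia_factor,
                 radius_ref_mm = radius_ref_mm, radius_exp = radius_exp),
            class = "physiology_model")
}

#' Resting coronary flow from the allometric scaling law
#'
#' `q_rest = q_scale * mass^k`.
#'
#' @param model A [physiology_model()].
#' @return Resting flow, mL/s.
#' @export
resting_flow <- function(model) {
  model$q_scale * model$myocardial_mass_g^model$k
}

#' Hyperemic boundary condition
#'
#' Resting microvascular resistance is sized so the resting flow is delivered
#' across `pa - pv`; maximal hyperemia multiplies it by `hyperemia_factor`.
#'
#' @param model A [physiology_model()].
#' @param pa,pv Aortic and venous pressures, mmHg.
#' @return A [boundary_condition()].
#' @export
hyperemic_bc <- function(model, pa = 90, pv = 0) {
  stopifnot(pa > pv)
  q_rest <- resting_flow(model)
  r_rest <- (pa - pv) / q_rest
  boundary_condition(pa = pa, pv = pv,
                     r_micro = model$hyperemia_factor * r_rest)
}

#' Scale the physiological model to a vessel's caliber
#'
#' Larger vessels subtend more myocardium and therefore carry more flow.
#' Returns a copy of `model` with `myocardial_mass_g` rescaled by
#' `(inlet radius / radius_ref_mm) ^ radius_exp`.
#'
#' @param model A [physiology_model()].
#' @param geom A [vessel_geometry()]; the inlet radius is the first sample.
#' @return A `physiology_model` for this vessel.
#' @export
scale_to_vessel <- function(model, geom) {
  geom <- as_vessel_geometry(geom)
  r_inlet <- geom$r_mm[1]
  model$myocardial_mass_g <-
    model$myocardial_mass_g * (r_inlet / model$radius_ref_mm)^model$radius_exp
  model
}
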