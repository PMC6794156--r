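# Flow-dependent epicardial resistance model, R(Q) = R_in + R_sl * Q per
# vessel segment, calibrated from two fine-grid solutions at different
# microvascular states (hyperemia and 40% lower resistance), with an analytic
# viscous/expansion fallback when the two flow states are too close.

#' Tile a vessel into reduced-order segments
#'
#' One segment per lesion plus one per healthy stretch between (and flanking)
#' lesions: the granularity at which serial-stenosis interplay is
#' representable.
#'
#' @param geom A [vessel_geometry()].
#' @param lesions Lesion tibble; may have zero rows.
#' @return A tibble with `start_mm`, `end_mm`, `type` ("lesion"/"healthy").
#' @export
segment_tiling <- function(geom, lesions) {
  geom <- as_vessel_geometry(geom)
  s0 <- min(geom$s_mm); s1 <- max(geom$s_mm)
  if (is.null(lesions) || nrow(lesions) == 0) {
    return(tibble::tibble(start_mm = s0, end_mm = s1, type = "healthy"))
  }
  lesions <- lesions[order(lesions$start_mm), , drop = FALSE]
  bounds <- sort(unique(pmin(pmax(
    c(s0, rbind(lesions$start_mm, lesions$end_mm), s1), s0), s1)))
  seg <- tibble::tibble(start_mm = utils::head(bounds, -1),
                        end_mm = utils::tail(bounds, -1))
  seg$type <- purrr::map2_chr(seg$start_mm, seg$end_mm, function(a, b) {
    mid <- (a + b) / 2
    hit <- any(lesions$start_mm <= mid & mid < lesions$end_mm)
    if (hit) "lesion" else "healthy"
  })
  seg[seg$end_mm - seg$start_mm > 1e-9, , drop = FALSE]
}

#' Epicardial resistance of a segment at a given flow
#'
#' `R = dP / Q`, the resistance the segment poses to blood flow.
#'
#' @param geom A [vessel_geometry()].
#' @param extent `c(start_mm, end_mm)`.
#' @param q Flow, mL/s; must be positive (the ratio is undefined at 0).
#' @param fluid A [fluid_properties()].
#' @return Resistance, mmHg s/mL.
#' @export
segment_resistance <- function(geom, extent, q, fluid = fluid_properties()) {
  if (any(q <= 0)) stop("segment resistance is undefined for q <= 0", call. = FALSE)
  segment_dp(geom, extent, q, fluid) / q
}

segment_dp_from_solution <- function(sol, extent) {
  prof <- sol$profile
  p <- stats::approx(prof$s_mm, prof$p_mmHg, xout = extent, rule = 2)$y
  p[1] - p[2]
}

#' Calibrate reduced-order segments against the fine-grid solver
#'
#' The whole vessel is solved under the hyperemic boundary condition and
#' again with the microvascular resistance lowered by 40%
#' (`r_micro <- 0.6 * r_micro`), giving flows `Q` and `Q*` and, per segment,
#' resistances `R = dP/Q` and `R* = dP*/Q*`. The two-point fit
#' `r_sl = (R* - R)/(Q* - Q)`, `r_in = R - r_sl * Q` reproduces both states
#' exactly. When the achieved flow difference `Q* - Q` falls below
#' `flow_tol`, the fit is ill-conditioned and the coefficients are replaced
#' by the analytic 1D law: `r_in` the Poiseuille integral over the extent and
#' `r_sl` its expansion-loss coefficient (source `"fallback"`).
#'
#' @param geom A [vessel_geometry()].
#' @param lesions Lesion tibble used for the segment tiling.
#' @param bc Hyperemic [boundary_condition()].
#' @param fluid A [fluid_properties()].
#' @param flow_tol Minimum usable flow separation, mL/s (default 0.05).
#' @param ds Fine-grid spacing for the calibration solves, mm.
#' @return A tibble of class `ffr_segments`: one row per segment with
#'   `start_mm`, `end_mm`, `type`, `r_in`, `r_sl`, `source`, and the
#'   calibration states `q`, `q_star`, `r`, `r_star`.
#' @export
calibrate_segments <- function(geom, lesions, bc, fluid = fluid_properties(),
                               flow_tol = 0.05, ds = 0.05) {
  geom <- as_vessel_geometry(geom)
  tiling <- segment_tiling(geom, lesions)
  sol <- oracle_solve(geom, bc, fluid, ds = ds)
  bc_star <- boundary_condition(bc$pa, bc$pv, 0.6 * bc$r_micro)
  sol_star <- oracle_solve(geom, bc_star, fluid, ds = ds)
  q <- sol$q_ml_s; q_star <- sol_star$q_ml_s
  if (q_star <= q) {
    stop(sprintf(
      "lower microvascular resistance produced no extra flow (Q=%.4f, Q*=%.4f); solver failure",
      q, q_star), call. = FALSE)
  }
  out <- purrr::map_dfr(seq_len(nrow(tiling)), function(i) {
    ext <- c(tiling$start_mm[i], tiling$end_mm[i])
    r <- segment_dp_from_solution(sol, ext) / q
    r_star <- segment_dp_from_solution(sol_star, ext) / q_star
    if (q_star - q < flow_tol) {
      coef <- segment_coefficients(geom, ext, fluid)
      tibble::tibble(r_in = coef$rv, r_sl = coef$s, source = "fallback",
                     q = q, q_star = q_star, r = r, r_star = r_star)
    } else {
      r_sl <- (r_star - r) / (q_star - q)
      tibble::tibble(r_in = r - r_sl * q, r_sl = r_sl, source = "calibrated",
                     q = q, q_star = q_star, r = r, r_star = r_star)
    }
  })
  out <- dplyr::bind_cols(tiling, out)
  out$r_in <- pmax(out$r_in, 0)
  out$r_sl <- pmax(out$r_sl, 0)
  structure(out, class = c("ffr_segments", class(tibble::tibble())))
}

#' Calibrate a single extent
#'
#' Convenience wrapper around [calibrate_segments()] for one extent.
#'
#' @inheritParams calibrate_segments
#' @param extent `c(start_mm, end_mm)`.
#' @return A one-row `ffr_segments` tibble.
#' @export
calibrate_segment <- function(geom, extent, bc, fluid = fluid_properties(),
                              flow_tol = 0.05, ds = 0.05) {
  geom <- as_vessel_geometry(geom)
  extent <- check_extent(geom, extent)
  seg <- calibrate_segments(
    geom,
    lesion_tibble(extent[1], extent[2], NA_real_, NA_real_, NA_real_),
    bc, fluid, flow_tol = flow_tol, ds = ds)
  seg[seg$start_mm == extent[1] & seg$end_mm == extent[2], , drop = FALSE]
}

# Analytic reduced-order coefficients of an extent (exact for the 1D law);
# used to refresh segments whose lumen a virtual stent has changed.
analytic_segment <- function(geom, extent, fluid) {
  coef <- segment_coefficients(geom, extent, fluid)
  tibble::tibble(r_in = coef$rv, r_sl = coef$s, source = "fallback",
                 q = NA_real_, q_star = NA_real_,
                 r = NA_real_, r_star = NA_real_)
}

#' Solve the reduced-order resistance network
#'
#' With segments tiling the vessel, the flow solves
#' `pa - pv = sum_i (r_in_i q + r_sl_i q^2) + r_micro q`, the positive root
#' of a quadratic. Pressures are accumulated segment by segment; the FFR
#' profile is piecewise linear between segment boundaries.
#'
#' @param segments An `ffr_segments` tibble tiling the vessel contiguously.
#' @param bc A [boundary_condition()].
#' @return An `ffr_solution` sampled at the segment boundaries.
#' @export
assemble_network <- function(segments, bc) {
  if (nrow(segments) == 0) stop("no segments", call. = FALSE)
  segments <- segments[order(segments$start_mm), , drop = FALSE]
  gaps <- utils::head(segments$end_mm, -1) - segments$start_mm[-1]
  if (any(abs(gaps) > 1e-6)) {
    stop("segments must tile the vessel without gaps or overlap", call. = FALSE)
  }
  a <- sum(segments$r_sl)
  b <- sum(segments$r_in) + bc$r_micro
  c0 <- -(bc$pa - bc$pv)
  disc <- b^2 - 4 * a * c0
  if (disc < 0 || b <= 0) stop("network has no positive flow root", call. = FALSE)
  q <- if (a > 0) (-b + sqrt(disc)) / (2 * a) else -c0 / b
  if (q <= 0) stop("network has no positive flow root", call. = FALSE)

  drops <- segments$r_in * q + segments$r_sl * q^2
  p_bounds <- bc$pa - c(0, cumsum(drops))
  s_bounds <- c(segments$start_mm[1], segments$end_mm)
  new_ffr_solution(
    q = q,
    profile = tibble::tibble(s_mm = s_bounds, p_mmHg = p_bounds,
                             ffr = p_bounds / bc$pa),
    bc = bc, fluid = NULL,
    meta = list(method = "reduced-order network",
                n_segments = nrow(segments),
                sources = table(segments$source))
  )
}
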