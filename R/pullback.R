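# In-silico hyperemic pressure-wire pullback and per-lesion FFR gradients:
# the apparent gradient read off the pre-PCI trace, and the "true" gradient
# of a lesion in isolation, obtained after virtually removing its companions.

#' Simulate a pressure-wire pullback
#'
#' Under the steady hyperemic model the pullback recording is the FFR profile
#' itself, traversed distal to proximal (the wire is withdrawn from beyond
#' the distal stenosis back to the guide catheter).
#'
#' @param sol An `ffr_solution`.
#' @return A tibble of class `ffr_pullback` (`s_mm`, `ffr`), rows ordered
#'   distal to proximal.
#' @export
simulate_pullback <- function(sol) {
  trace <- dplyr::arrange(sol$profile[, c("s_mm", "ffr")],
                          dplyr::desc(.data$s_mm))
  structure(trace, direction = "distal-to-proximal",
            class = c("ffr_pullback", class(tibble::tibble())))
}

trace_ffr_at <- function(trace, pos_mm) {
  if (inherits(trace, "ffr_solution")) trace <- trace$profile
  stats::approx(trace$s_mm, trace$ffr, xout = pos_mm, rule = 2)$y
}

#' Apparent FFR gradient across a lesion
#'
#' FFR read `margin` mm proximal to the lesion start minus FFR read `margin`
#' mm distal to its end (read points clipped to the vessel). When the margins
#' of adjacent lesions would overlap, they are shrunk to half the inter-lesion
#' gap with a warning, so each lesion's reading stays on its own side.
#'
#' @param trace An `ffr_pullback` trace or an `ffr_solution`.
#' @param lesion One-row lesion tibble (columns `start_mm`, `end_mm`).
#' @param margin Read margin beyond the lesion shoulders, mm (default 2,
#'   enough to sit clear of post-stenotic flow disturbance).
#' @param lesions Optional full lesion tibble used to detect overlapping
#'   margins with neighbours.
#' @return The apparent FFR gradient (non-negative).
#' @export
apparent_gradient <- function(trace, lesion, margin = 2, lesions = NULL) {
  if (inherits(trace, "ffr_solution")) {
    s_range <- range(trace$profile$s_mm)
  } else {
    s_range <- range(trace$s_mm)
  }
  m_prox <- m_dist <- margin
  if (!is.null(lesions) && nrow(lesions) > 1) {
    others <- lesions[abs(lesions$start_mm - lesion$start_mm) > 1e-9 |
                        abs(lesions$end_mm - lesion$end_mm) > 1e-9, ,
                      drop = FALSE]
    up <- others[others$end_mm <= lesion$start_mm + 1e-9, , drop = FALSE]
    if (nrow(up) > 0) {
      gap <- lesion$start_mm - max(up$end_mm)
      if (2 * margin > gap) {
        m_prox <- gap / 2
        warning(sprintf("proximal margin shrunk to %.2f mm (half the %.2f mm gap)",
                        m_prox, gap), call. = FALSE)
      }
    }
    down <- others[others$start_mm >= lesion$end_mm - 1e-9, , drop = FALSE]
    if (nrow(down) > 0) {
      gap <- min(down$start_mm) - lesion$end_mm
      if (2 * margin > gap) {
        m_dist <- gap / 2
        warning(sprintf("distal margin shrunk to %.2f mm (half the %.2f mm gap)",
                        m_dist, gap), call. = FALSE)
      }
    }
  }
  p_prox <- max(lesion$start_mm - m_prox, s_range[1])
  p_dist <- min(lesion$end_mm + m_dist, s_range[2])
  max(0, trace_ffr_at(trace, p_prox) - trace_ffr_at(trace, p_dist))
}

#' True (isolated) FFR gradient of a lesion
#'
#' All companion lesions are virtually removed (their lumen idealized), the
#' vessel is re-solved on the fine grid, and the target lesion's gradient is
#' read with the same margins as the apparent gradient. This is the in-silico
#' analogue of re-measuring a lesion after PCI of its companions.
#'
#' @param geom A [vessel_geometry()].
#' @param lesions Full lesion tibble.
#' @param target One-row lesion tibble identifying the lesion to isolate
#'   (matched to `lesions` by extent).
#' @param bc Hyperemic [boundary_condition()].
#' @param fluid A [fluid_properties()].
#' @param margin Read margin, mm.
#' @param ds Fine-grid spacing, mm.
#' @return The isolated FFR gradient of `target`.
#' @export
true_gradient <- function(geom, lesions, target, bc,
                          fluid = fluid_properties(), margin = 2, ds = 0.05) {
  geom <- as_vessel_geometry(geom)
  is_target <- abs(lesions$start_mm - target$start_mm) < 1e-9 &
    abs(lesions$end_mm - target$end_mm) < 1e-9
  if (!any(is_target)) stop("target lesion not found in `lesions`", call. = FALSE)
  companions <- lesions[!is_target, , drop = FALSE]
  g <- geom
  for (i in seq_len(nrow(companions))) {
    g <- idealize_lumen(g, c(companions$start_mm[i], companions$end_mm[i]),
                        lesions)
  }
  sol <- oracle_solve(g, bc, fluid, ds = ds)
  apparent_gradient(sol, target, margin = margin, lesions = lesions)
}
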