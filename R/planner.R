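# Virtual-PCI planner: idealize the stented extent, refresh the reduced-order
# coefficients of the segments the stent touched, re-solve the network, and
# report the predicted residual FFR and the per-lesion gradients that remain.

overlaps <- function(a0, a1, b0, b1) a0 < b1 & b0 < a1

#' Predict the physiological result of a stent plan
#'
#' Lumen radii inside the stented extent are replaced by their idealized
#' (healthy reference) values; reduced-order segments overlapping the stent
#' are refreshed with analytic coefficients on the updated lumen while
#' unchanged segments keep their calibrated flow-dependent coefficients; the
#' network is re-solved for the post-PCI flow, pressures and FFR.
#'
#' @param geom A [vessel_geometry()].
#' @param lesions Lesion tibble for the vessel (pre-PCI ground truth).
#' @param stent A [stent_plan()].
#' @param bc Hyperemic [boundary_condition()].
#' @param fluid A [fluid_properties()].
#' @param segments Optional pre-calibrated `ffr_segments` from
#'   [calibrate_segments()] on the *unstented* vessel; calibrated on the fly
#'   when omitted. Reusing them is what makes repeated planning real-time.
#' @param margin Read margin beyond lesion shoulders for residual gradients,
#'   mm (default 2).
#' @param flow_tol,ds Passed to [calibrate_segments()] when calibrating.
#' @return An object of class `ffr_plan`: the stent, `ffr_profile_post`
#'   (tibble `s_mm`, `ffr` at every geometry sample), `predicted_ffr_distal`,
#'   `gradients` (one row per untreated lesion), the post-PCI network
#'   solution, and the elapsed wall time in seconds.
#' @export
plan_pci <- function(geom, lesions, stent, bc, fluid = fluid_properties(),
                     segments = NULL, margin = 2, flow_tol = 0.05, ds = 0.05) {
  t0 <- proc.time()[["elapsed"]]
  geom <- as_vessel_geometry(geom)
  ext <- check_extent(geom, c(stent$start_mm, stent$end_mm))

  if (is.null(segments)) {
    segments <- calibrate_segments(geom, lesions, bc, fluid,
                                   flow_tol = flow_tol, ds = ds)
  }
  g_post <- idealize_lumen(geom, ext, lesions)

  touched <- overlaps(segments$start_mm, segments$end_mm, ext[1], ext[2])
  seg_post <- segments
  for (i in which(touched)) {
    seg_post[i, c("r_in", "r_sl", "source", "q", "q_star", "r", "r_star")] <-
      analytic_segment(g_post, c(seg_post$start_mm[i], seg_post$end_mm[i]), fluid)
  }
  sol_net <- assemble_network(seg_post, bc)

  ffr_post <- stats::approx(sol_net$profile$s_mm, sol_net$profile$ffr,
                            xout = geom$s_mm, rule = 2)$y
  untreated <- lesions[!overlaps(lesions$start_mm, lesions$end_mm,
                                 ext[1], ext[2]), , drop = FALSE]
  gradients <- if (nrow(untreated) > 0) {
    grads <- purrr::map_dbl(seq_len(nrow(untreated)), function(i) {
      apparent_gradient(sol_net, untreated[i, ], margin = margin,
                        lesions = lesions)
    })
    dplyr::mutate(untreated, gradient = grads)
  } else {
    dplyr::mutate(lesions[0, ], gradient = numeric(0))
  }

  structure(list(
    stent = stent,
    ffr_profile_post = tibble::tibble(s_mm = geom$s_mm, ffr = ffr_post),
    predicted_ffr_distal = distal_ffr(sol_net),
    gradients = gradients,
    solution = sol_net,
    segments = seg_post,
    elapsed = proc.time()[["elapsed"]] - t0
  ), class = "ffr_plan")
}

#' @export
print.ffr_plan <- function(x, ...) {
  cat(sprintf(
    "<ffr_plan> stent [%.1f, %.1f) mm: predicted distal FFR %.3f (%d residual lesion%s, %.1f ms)\n",
    x$stent$start_mm, x$stent$end_mm, x$predicted_ffr_distal,
    nrow(x$gradients), if (nrow(x$gradients) == 1) "" else "s",
    1000 * x$elapsed))
  invisible(x)
}

#' Tidy the residual-lesion gradients of a plan
#'
#' @param x An `ffr_plan`.
#' @param ... Unused.
#' @return A tibble with one row per untreated lesion and its predicted
#'   residual FFR gradient.
#' @export
tidy.ffr_plan <- function(x, ...) tibble::as_tibble(x$gradients)

#' One-row summary of a plan
#'
#' @param x An `ffr_plan`.
#' @param ... Unused.
#' @return A one-row tibble: stent extent, predicted distal FFR, flow and
#'   elapsed time.
#' @export
glance.ffr_plan <- function(x, ...) {
  tibble::tibble(stent_start_mm = x$stent$start_mm,
                 stent_end_mm = x$stent$end_mm,
                 predicted_ffr_distal = x$predicted_ffr_distal,
                 q_ml_s = x$solution$q_ml_s,
                 n_residual_lesions = nrow(x$gradients),
                 elapsed_s = x$elapsed)
}

#' Plot a plan's post-PCI FFR profile
#'
#' @param object An `ffr_plan`.
#' @param ... Unused.
#' @return A ggplot of the predicted post-PCI FFR profile with the stented
#'   extent shaded.
#' @export
autoplot.ffr_plan <- function(object, ...) {
  ggplot2::ggplot(object$ffr_profile_post,
                  ggplot2::aes(x = .data$s_mm, y = .data$ffr)) +
    ggplot2::annotate("rect", xmin = object$stent$start_mm,
                      xmax = object$stent$end_mm, ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "arc length from ostium (mm)", y = "predicted FFR",
                  title = sprintf("Post-PCI prediction: distal FFR %.3f",
                                  object$predicted_ffr_distal))
}

#' Rank alternative stent plans
#'
#' Each plan is evaluated with [plan_pci()] (one shared base calibration) and
#' the results are ranked by predicted distal FFR, best first; ties are
#' broken by shorter stent, then more proximal start.
#'
#' @inheritParams plan_pci
#' @param plans A list of [stent_plan()]s (at least one).
#' @return A tibble with one row per plan (rank order), the glance columns of
#'   each result, and the full `ffr_plan` objects in a list-column `result`.
#' @export
compare_plans <- function(geom, lesions, plans, bc, fluid = fluid_properties(),
                          margin = 2, flow_tol = 0.05, ds = 0.05) {
  if (length(plans) == 0) stop("at least one stent plan is required", call. = FALSE)
  geom <- as_vessel_geometry(geom)
  base <- calibrate_segments(geom, lesions, bc, fluid,
                             flow_tol = flow_tol, ds = ds)
  results <- purrr::map(plans, function(p) {
    plan_pci(geom, lesions, p, bc, fluid, segments = base, margin = margin)
  })
  out <- purrr::map_dfr(results, glance)
  out$result <- results
  out <- dplyr::arrange(out,
                        dplyr::desc(.data$predicted_ffr_distal),
                        .data$stent_end_mm - .data$stent_start_mm,
                        .data$stent_start_mm)
  dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
}
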