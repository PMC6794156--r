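# End-to-end in-silico experiment: on a synthetic cohort, compare the
# apparent pullback gradient and the planner's predicted gradient of each
# lesion against its true (isolated) gradient, and summarise the agreement
# per method.

vessel_bc <- function(config, geom) {
  phys <- scale_to_vessel(config_physiology(config), geom)
  hyperemic_bc(phys, pa = config$pa_mmHg, pv = config$pv_mmHg)
}

pick_targets <- function(lesions, policy) {
  # Returns the indices of lesions to assess as targets (companion stented).
  switch(policy,
         both = seq_len(nrow(lesions)),
         most_severe = which.min(lesions$pct_ds),  # stent the most severe -> assess the other
         proximal = nrow(lesions),                  # stent the proximal lesion
         distal = 1L,                               # stent the distal lesion
         stop("unknown stent policy", call. = FALSE))
}

#' Run the cohort experiment
#'
#' For every synthetic vessel: solve the pre-PCI hyperemic state and read
#' each lesion's apparent pullback gradient; for each target lesion, stent
#' its companion (per the stent policy), obtain the target's true gradient
#' from the fine-grid re-solve and the planner's predicted gradient from the
#' reduced-order re-solve; then assess pullback-vs-true and planner-vs-true
#' agreement over the cohort.
#'
#' With the default policy `"both"` every lesion of every vessel is assessed
#' once as the remaining lesion. Policies `most_severe`, `proximal` and
#' `distal` stent that lesion and assess only its companion, mirroring a
#' single-PCI clinical protocol.
#'
#' @param config An `ffr_config` (see [default_config()]).
#' @param progress Print one line per vessel (flow, distal FFR, calibration
#'   sources)?
#' @return An object of class `ffr_experiment`: `per_lesion` tibble,
#'   `per_vessel` tibble, `agreement_pullback`, `agreement_planner`, and a
#'   Figure-style `summary` tibble (mean error +/- SD and percent error per
#'   method).
#' @export
run_experiment <- function(config = default_config(), progress = FALSE) {
  validate_config(config)
  if (config$cohort$n_lesions != 2) {
    stop("the experiment protocol assumes serial pairs (n_lesions = 2)",
         call. = FALSE)
  }
  fluid <- config_fluid(config)
  spec <- config_cohort_spec(config)
  cohort <- generate_cohort(spec)
  ds <- config$solver$ds_oracle_mm
  margin <- config$solver$margin_mm
  flow_tol <- config$solver$flow_tol_ml_s

  per_vessel <- list()
  per_lesion <- list()
  for (i in seq_along(cohort$vessels)) {
    v <- cohort$vessels[[i]]
    bc <- vessel_bc(config, v$geom)
    sol_pre <- oracle_solve(v$geom, bc, fluid, ds = ds)
    trace <- simulate_pullback(sol_pre)
    base_seg <- calibrate_segments(v$geom, v$lesions, bc, fluid,
                                   flow_tol = flow_tol, ds = ds)

    targets <- pick_targets(v$lesions, config$stent_policy)
    rows <- purrr::map_dfr(targets, function(j) {
      target <- v$lesions[j, ]
      companions <- v$lesions[-j, , drop = FALSE]
      grad_pb <- apparent_gradient(trace, target, margin = margin,
                                   lesions = v$lesions)
      g_true <- v$geom
      for (k in seq_len(nrow(companions))) {
        g_true <- idealize_lumen(g_true, c(companions$start_mm[k],
                                           companions$end_mm[k]), v$lesions)
      }
      sol_true <- oracle_solve(g_true, bc, fluid, ds = ds)
      grad_true <- apparent_gradient(sol_true, target, margin = margin,
                                     lesions = v$lesions)
      # plan: stent every companion (serial default has exactly one)
      grad_plan <- NA_real_
      plan_distal <- NA_real_
      if (nrow(companions) > 0) {
        stent <- stent_plan(min(companions$start_mm), max(companions$end_mm))
        plan <- plan_pci(v$geom, v$lesions, stent, bc, fluid,
                         segments = base_seg, margin = margin)
        hit <- abs(plan$gradients$start_mm - target$start_mm) < 1e-9
        grad_plan <- plan$gradients$gradient[hit][1]
        plan_distal <- plan$predicted_ffr_distal
      }
      tibble::tibble(vessel_id = i, lesion_idx = j, pct_ds = target$pct_ds,
                     grad_pullback = grad_pb, grad_planner = grad_plan,
                     grad_true = grad_true,
                     planner_ffr_distal_post = plan_distal,
                     oracle_ffr_distal_post = distal_ffr(sol_true))
    })
    per_lesion[[i]] <- rows
    per_vessel[[i]] <- tibble::tibble(
      vessel_id = i, q_ml_s = sol_pre$q_ml_s,
      ffr_distal_pre = distal_ffr(sol_pre),
      n_fallback = sum(base_seg$source == "fallback"),
      n_calibrated = sum(base_seg$source == "calibrated"))
    if (progress) {
      cat(sprintf("vessel %3d: q = %.2f mL/s, distal FFR = %.3f, segments %d calibrated / %d fallback\n",
                  i, sol_pre$q_ml_s, distal_ffr(sol_pre),
                  sum(base_seg$source == "calibrated"),
                  sum(base_seg$source == "fallback")))
    }
  }
  per_lesion <- dplyr::bind_rows(per_lesion)
  per_vessel <- dplyr::bind_rows(per_vessel)
  per_lesion <- dplyr::mutate(
    per_lesion,
    rel_err_pullback_pct = 100 * abs(.data$grad_true - .data$grad_pullback) /
      .data$grad_true,
    rel_err_planner_pct = 100 * abs(.data$grad_true - .data$grad_planner) /
      .data$grad_true)

  ag_pb <- assess_cohort(
    tibble::tibble(estimate = per_lesion$grad_pullback,
                   truth = per_lesion$grad_true),
    tost_margin = config$tost_margin)
  ag_pl <- assess_cohort(
    tibble::tibble(estimate = per_lesion$grad_planner,
                   truth = per_lesion$grad_true),
    tost_margin = config$tost_margin)

  summary <- purrr::map2_dfr(
    list(ag_pb, ag_pl), c("pullback", "planner"),
    function(ag, method) {
      tibble::tibble(method = method, n = ag$n,
                     mean_error = ag$mean_diff, sd_error = ag$sd_diff,
                     mean_abs_error = mean(abs(ag$data$truth - ag$data$estimate)),
                     pct_error = ag$mean_relative_error_pct,
                     pearson_r = ag$pearson_r)
    })

  structure(list(per_lesion = per_lesion, per_vessel = per_vessel,
                 agreement_pullback = ag_pb, agreement_planner = ag_pl,
                 summary = summary, config = config),
            class = "ffr_experiment")
}

#' @export
print.ffr_experiment <- function(x, ...) {
  cat(sprintf("<ffr_experiment> %d vessels, %d lesion assessments\n",
              nrow(x$per_vessel), nrow(x$per_lesion)))
  cat(sprintf("  pre-PCI distal FFR: %.2f +/- %.2f\n",
              mean(x$per_vessel$ffr_distal_pre),
              stats::sd(x$per_vessel$ffr_distal_pre)))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write experiment reports
#'
#' `per_lesion.csv`, `per_vessel.csv`, `summary.csv` and
#' `agreement_<method>.json` under `dir`.
#'
#' @param exp An `ffr_experiment`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(exp$per_lesion, file.path(dir, "per_lesion.csv"),
                   progress = FALSE)
  readr::write_csv(exp$per_vessel, file.path(dir, "per_vessel.csv"),
                   progress = FALSE)
  readr::write_csv(exp$summary, file.path(dir, "summary.csv"),
                   progress = FALSE)
  for (m in c("pullback", "planner")) {
    ag <- exp[[paste0("agreement_", m)]]
    jsonlite::write_json(as.list(glance(ag)),
                         file.path(dir, sprintf("agreement_%s.json", m)),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}
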