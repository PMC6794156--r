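# Plain-text interchange: vessel profile CSV (header `s_mm,r_mm`, optional
# `# label=` comment), lesion list JSON, solution JSON, cohort directories.

#' Read a vessel profile CSV
#'
#' Expects header `s_mm,r_mm`; an optional leading comment line
#' `# label=<name>` sets the vessel label.
#'
#' @param path CSV file path.
#' @return A [vessel_geometry()].
#' @export
read_vessel_csv <- function(path) {
  lines <- readLines(path, n = 5)
  label <- "vessel"
  lab_line <- grep("^#\\s*label=", lines, value = TRUE)
  if (length(lab_line) > 0) {
    label <- sub("^#\\s*label=\\s*", "", lab_line[1])
  }
  # base read.csv: strtod parsing is correctly rounded, so 17-digit output
  # round-trips bit-exactly
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("s_mm", "r_mm") %in% names(df))) {
    stop(sprintf("malformed vessel CSV %s: header must contain s_mm,r_mm", path),
         call. = FALSE)
  }
  vessel_geometry(df$s_mm, df$r_mm, label = label)
}

#' Write a vessel profile CSV
#'
#' Values are written with 17 significant digits so read/write round-trips
#' are exact.
#'
#' @param geom A [vessel_geometry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vessel_csv <- function(geom, path) {
  geom <- as_vessel_geometry(geom)
  rows <- sprintf("%.17g,%.17g", geom$s_mm, geom$r_mm)
  writeLines(c(sprintf("# label=%s", vessel_label(geom)), "s_mm,r_mm", rows),
             path)
  invisible(path)
}

#' Write a lesion list as JSON
#'
#' @param lesions Lesion tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lesions_json <- function(lesions, path) {
  jsonlite::write_json(lesions, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a lesion list from JSON
#'
#' @param path JSON file path.
#' @return A lesion tibble.
#' @export
read_lesions_json <- function(path) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}

#' Export a hemodynamic solution as JSON
#'
#' Schema: `{q_ml_s, samples: [{s_mm, p_mmHg, ffr}]}`.
#'
#' @param sol An `ffr_solution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_solution_json <- function(sol, path) {
  jsonlite::write_json(list(q_ml_s = sol$q_ml_s, samples = sol$profile),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write a cohort to a directory
#'
#' One `vessel_<i>.csv` per vessel plus `manifest.csv` with the planted
#' ground truth.
#'
#' @param cohort An `ffr_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  purrr::iwalk(cohort$vessels, function(v, i) {
    write_vessel_csv(v$geom, file.path(dir, sprintf("vessel_%03d.csv", i)))
  })
  readr::write_csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   progress = FALSE)
  invisible(dir)
}
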