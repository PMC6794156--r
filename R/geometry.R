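# Vessel lumen geometry: construction, resampling, reference (healthy) lumen
# estimation, percent diameter stenosis, lesion detection and idealization.
#
# Conventions: arc length s in mm from the ostium, lumen radius r in mm,
# extents are half-open intervals [start_mm, end_mm).

#' Construct a vessel lumen profile
#'
#' A vessel is a tibble of arc-length / lumen-radius samples with class
#' `vessel_geometry`. Arc length `s_mm` runs from the coronary ostium; the
#' lumen is assumed circular, so area is `pi * r_mm^2`.
#'
#' @param s_mm Numeric vector of arc-length samples (mm), strictly increasing.
#' @param r_mm Numeric vector of lumen radii (mm), same length, all positive.
#' @param label Free-text identifier carried through analyses.
#'
#' @return A tibble with columns `s_mm`, `r_mm` and class `vessel_geometry`.
#' @export
#' @examples
#' tube <- vessel_geometry(seq(0, 50, by = 0.5), rep(2, 101), "straight tube")
#' tube
vessel_geometry <- function(s_mm, r_mm, label = "vessel") {
  s_mm <- as.numeric(s_mm)
  r_mm <- as.numeric(r_mm)
  g <- tibble::tibble(s_mm = s_mm, r_mm = r_mm)
  g <- structure(g, label = as.character(label)[1],
                 class = c("vessel_geometry", class(tibble::tibble())))
  validate_vessel(g)
  g
}

#' Coerce a data frame to a vessel geometry
#'
#' @param x A data frame with numeric columns `s_mm` and `r_mm`.
#' @param label Identifier; defaults to an existing label attribute or
#'   `"vessel"`.
#' @return A validated `vessel_geometry`.
#' @export
as_vessel_geometry <- function(x, label = NULL) {
  if (inherits(x, "vessel_geometry") && is.null(label)) {
    validate_vessel(x)
    return(x)
  }
  if (!all(c("s_mm", "r_mm") %in% names(x))) {
    stop("vessel geometry needs columns `s_mm` and `r_mm`", call. = FALSE)
  }
  if (is.null(label)) label <- attr(x, "label") %||% "vessel"
  vessel_geometry(x$s_mm, x$r_mm, label = label)
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("<vessel_geometry> %s: %d samples, %.1f mm, radius %.2f-%.2f mm\n",
              vessel_label(x), nrow(x), diff(range(x$s_mm)),
              min(x$r_mm), max(x$r_mm)))
  NextMethod()
}

vessel_label <- function(geom) attr(geom, "label") %||% "vessel"

validate_vessel <- function(geom) {
  if (nrow(geom) < 10) {
    stop("vessel geometry needs at least 10 samples", call. = FALSE)
  }
  if (anyNA(geom$s_mm) || anyNA(geom$r_mm)) {
    stop("vessel geometry contains missing values", call. = FALSE)
  }
  if (any(diff(geom$s_mm) <= 0)) {
    stop("arc-length samples `s_mm` must be strictly increasing", call. = FALSE)
  }
  if (any(geom$r_mm <= 0)) {
    stop("lumen radii `r_mm` must all be positive", call. = FALSE)
  }
  invisible(geom)
}

vessel_length <- function(geom) max(geom$s_mm) - min(geom$s_mm)

#' Resample a vessel profile to uniform spacing
#'
#' Radii are linearly interpolated onto a uniform arc-length grid; both
#' endpoints are preserved exactly. Resampling twice at the same spacing is
#' idempotent.
#'
#' @param geom A [vessel_geometry()].
#' @param ds Target sample spacing (mm), default 0.25.
#' @return A `vessel_geometry` on the uniform grid.
#' @export
resample_vessel <- function(geom, ds = 0.25) {
  geom <- as_vessel_geometry(geom)
  stopifnot(ds > 0)
  s0 <- min(geom$s_mm)
  s1 <- max(geom$s_mm)
  grid <- seq(s0, s1, by = ds)
  if (grid[length(grid)] < s1 - 1e-12) grid <- c(grid, s1)
  r <- stats::approx(geom$s_mm, geom$r_mm, xout = grid)$y
  vessel_geometry(grid, r, label = vessel_label(geom))
}

# Radius at arbitrary positions by linear interpolation (positions clamped
# to the sampled range must be checked by callers where that matters).
radius_at <- function(geom, pos_mm) {
  stats::approx(geom$s_mm, geom$r_mm, xout = pos_mm, rule = 2)$y
}

# Least concave majorant (upper hull) of the sampled profile, evaluated at
# every sample. For a linear-taper healthy baseline with narrowings below it,
# this recovers the healthy envelope exactly at healthy samples.
concave_majorant <- function(s, r) {
  n <- length(s)
  hull <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      a <- hull[m - 1L]; b <- hull[m]
      # drop b if it lies on or below chord a--i (keeps upper hull)
      cross <- (s[b] - s[a]) * (r[i] - r[a]) - (r[b] - r[a]) * (s[i] - s[a])
      if (cross >= 0) m <- m - 1L else break
    }
    m <- m + 1L
    hull[m] <- i
  }
  idx <- hull[seq_len(m)]
  stats::approx(s[idx], r[idx], xout = s)$y
}

check_extent <- function(geom, extent) {
  extent <- as.numeric(extent)
  if (length(extent) != 2 || !all(is.finite(extent)) || extent[2] <= extent[1]) {
    stop("extent must be a finite interval c(start_mm, end_mm) with end > start",
         call. = FALSE)
  }
  if (extent[1] < min(geom$s_mm) - 1e-9 || extent[2] > max(geom$s_mm) + 1e-9) {
    stop(sprintf("extent [%.2f, %.2f) lies outside the vessel [%.2f, %.2f]",
                 extent[1], extent[2], min(geom$s_mm), max(geom$s_mm)),
         call. = FALSE)
  }
  extent
}

lesion_tibble <- function(start_mm = numeric(), end_mm = numeric(),
                          r_min_mm = numeric(), r_ref_mm = numeric(),
                          pct_ds = numeric()) {
  tibble::tibble(start_mm = start_mm, end_mm = end_mm,
                 r_min_mm = r_min_mm, r_ref_mm = r_ref_mm, pct_ds = pct_ds)
}

#' Healthy (disease-free) reference radius profile
#'
#' Outside lesions the reference equals the measured radius; inside each
#' lesion it is the chord between the radii at the lesion flanks, the same
#' rule quantitative coronary angiography uses to interpolate a reference
#' diameter from adjacent normal segments.
#'
#' @param geom A [vessel_geometry()].
#' @param lesions Lesion tibble (as from [detect_lesions()]) with columns
#'   `start_mm`, `end_mm`; may have zero rows.
#' @return A `vessel_geometry` holding the reference radii.
#' @export
reference_profile <- function(geom, lesions) {
  geom <- as_vessel_geometry(geom)
  ref <- geom$r_mm
  if (is.null(lesions) || nrow(lesions) == 0) {
    return(vessel_geometry(geom$s_mm, ref, label = vessel_label(geom)))
  }
  lesions <- lesions[order(lesions$start_mm), , drop = FALSE]
  if (nrow(lesions) > 1 &&
      any(lesions$start_mm[-1] < lesions$end_mm[-nrow(lesions)] - 1e-9)) {
    stop("lesion extents overlap", call. = FALSE)
  }
  s0 <- min(geom$s_mm); s1 <- max(geom$s_mm)
  for (i in seq_len(nrow(lesions))) {
    a <- lesions$start_mm[i]; b <- lesions$end_mm[i]
    check_extent(geom, c(a, b))
    if (a <= s0 + 1e-9 || b >= s1 - 1e-9) {
      stop("lesion touches a vessel endpoint; no healthy flank to anchor the reference",
           call. = FALSE)
    }
    inside <- geom$s_mm >= a & geom$s_mm < b
    if (!any(inside)) next
    ra <- radius_at(geom, a)
    rb <- radius_at(geom, b)
    ref[inside] <- ra + (rb - ra) * (geom$s_mm[inside] - a) / (b - a)
  }
  vessel_geometry(geom$s_mm, ref, label = vessel_label(geom))
}

#' Percent diameter stenosis over an extent
#'
#' `100 * (1 - r_min / r_ref)` with `r_min` the minimum sampled radius in the
#' extent and `r_ref` the reference radius there, taken from the chord between
#' the measured radii at the extent boundaries. Negative values (local
#' bulging) are clamped to zero.
#'
#' @param geom A [vessel_geometry()].
#' @param extent `c(start_mm, end_mm)`, half-open, within the vessel.
#' @return Percent diameter stenosis (scalar, in `[0, 100)`).
#' @export
percent_stenosis <- function(geom, extent) {
  geom <- as_vessel_geometry(geom)
  extent <- check_extent(geom, extent)
  inside <- geom$s_mm >= extent[1] & geom$s_mm < extent[2]
  if (!any(inside)) stop("extent contains no samples", call. = FALSE)
  r_in <- geom$r_mm[inside]
  s_in <- geom$s_mm[inside]
  i_min <- which.min(r_in)
  ra <- radius_at(geom, extent[1])
  rb <- radius_at(geom, extent[2])
  r_ref <- ra + (rb - ra) * (s_in[i_min] - extent[1]) / (extent[2] - extent[1])
  max(0, 100 * (1 - r_in[i_min] / r_ref))
}

#' Detect lesions in a lumen profile
#'
#' Narrowing is measured against the least concave majorant of the profile
#' (the healthy envelope). Contiguous runs where the narrowing fraction
#' exceeds `edge_frac` delimit candidate extents; extents separated by less
#' than `min_gap` are merged into one lesion; lesions whose peak percent
#' diameter stenosis falls below `min_pct` are discarded. This mirrors lesion
#' inclusion by peak severity while keeping the full anatomical extent of
#' each smooth-shouldered narrowing.
#'
#' @param geom A [vessel_geometry()].
#' @param min_pct Minimum peak percent diameter stenosis for a narrowing to
#'   count as a lesion (default 30, the usual angiographic threshold).
#' @param min_gap Narrowings separated by less than this many mm of normal
#'   lumen are merged (default 10).
#' @param edge_frac Narrowing fraction (vs the healthy envelope) delimiting a
#'   lesion's extent. The default `1e-8` recovers the full anatomical extent
#'   of smooth-shouldered lesions on noise-free profiles; raise it (to, say,
#'   `0.01`-`0.05`) for measured lumen data with segmentation noise.
#' @return A lesion tibble with columns `start_mm`, `end_mm`, `r_min_mm`,
#'   `r_ref_mm`, `pct_ds`, ordered proximal to distal (possibly zero rows).
#' @export
detect_lesions <- function(geom, min_pct = 30, min_gap = 10, edge_frac = 1e-8) {
  geom <- as_vessel_geometry(geom)
  stopifnot(min_pct > 0, min_pct < 100, min_gap >= 0)
  env <- concave_majorant(geom$s_mm, geom$r_mm)
  narrowing <- 1 - geom$r_mm / env
  inside <- narrowing > edge_frac
  if (!any(inside)) return(lesion_tibble())

  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  idx <- which(runs$values)
  n <- nrow(geom)
  spacing <- stats::median(diff(geom$s_mm))
  # raw runs of narrowed samples (closed, first to last flagged sample)
  ext <- lapply(idx, function(k) c(geom$s_mm[starts[k]], geom$s_mm[ends[k]]))
  # merge runs separated by < min_gap of normal lumen
  merged <- list(ext[[1]])
  for (e in ext[-1]) {
    last <- merged[[length(merged)]]
    if (e[1] - last[2] < min_gap) {
      merged[[length(merged)]] <- c(last[1], e[2])
    } else {
      merged[[length(merged) + 1L]] <- e
    }
  }
  # half-open extents: extend past the last flagged sample
  merged <- lapply(merged, function(e) {
    c(e[1], min(e[2] + spacing, geom$s_mm[n]))
  })
  out <- purrr::map_dfr(merged, function(e) {
    if (e[1] <= min(geom$s_mm) + 1e-9 || e[2] >= max(geom$s_mm) - 1e-9) {
      stop("detected narrowing touches a vessel endpoint; cannot anchor a reference",
           call. = FALSE)
    }
    inside_e <- geom$s_mm >= e[1] & geom$s_mm < e[2]
    r_in <- geom$r_mm[inside_e]
    s_in <- geom$s_mm[inside_e]
    i_min <- which.min(r_in)
    ra <- radius_at(geom, e[1]); rb <- radius_at(geom, e[2])
    r_ref <- ra + (rb - ra) * (s_in[i_min] - e[1]) / (e[2] - e[1])
    lesion_tibble(e[1], e[2], r_in[i_min], r_ref,
                  max(0, 100 * (1 - r_in[i_min] / r_ref)))
  })
  out <- out[out$pct_ds >= min_pct, , drop = FALSE]
  out[order(out$start_mm), , drop = FALSE]
}

#' Idealize (virtually revascularize) part of a vessel
#'
#' Radii inside `extent` are replaced by the healthy reference profile, i.e.
#' the lumen a perfectly deployed stent (or the disease-free vessel) would
#' present; radii outside are untouched. Idempotent.
#'
#' @param geom A [vessel_geometry()].
#' @param extent `c(start_mm, end_mm)` to idealize, half-open.
#' @param lesions Lesion tibble anchoring the reference profile.
#' @return A `vessel_geometry` with the idealized lumen.
#' @export
idealize_lumen <- function(geom, extent, lesions) {
  geom <- as_vessel_geometry(geom)
  extent <- check_extent(geom, extent)
  ref <- reference_profile(geom, lesions)
  inside <- geom$s_mm >= extent[1] & geom$s_mm < extent[2]
  r <- geom$r_mm
  r[inside] <- ref$r_mm[inside]
  vessel_geometry(geom$s_mm, r, label = vessel_label(geom))
}

#' Describe a planned stent
#'
#' @param start_mm,end_mm Stented extent along the vessel, half-open, mm.
#' @return A one-row tibble of class `stent_plan`.
#' @export
stent_plan <- function(start_mm, end_mm) {
  if (end_mm <= start_mm) stop("stent end must exceed its start", call. = FALSE)
  structure(tibble::tibble(start_mm = start_mm, end_mm = end_mm),
            class = c("stent_plan", class(tibble::tibble())))
}
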