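# Seeded generator of synthetic serially diseased vessels: a linear-taper
# healthy baseline with raised-cosine narrowings, placed under the study-style
# inclusion constraints (two lesions, each past the severity threshold,
# separated by >= 10 mm of normal lumen). Per-vessel RNG substreams make
# cohorts order-independent and bit-reproducible.

#' Specification of a synthetic cohort
#'
#' Defaults emulate vessels eligible for serial-stenosis assessment: two
#' raised-cosine lesions of 40-85% diameter stenosis on an 80-140 mm vessel
#' with 10-30% linear taper, separated by at least 10 mm of normal lumen.
#'
#' @param n_vessels Number of vessels.
#' @param seed Integer seed; with `index`, fully determines each vessel.
#' @param length_range Vessel length range, mm.
#' @param inlet_radius_range Inlet (ostial) radius range, mm.
#' @param taper_pct_range Total healthy taper over the vessel, percent.
#' @param n_lesions Lesions per vessel (default 2, serial disease).
#' @param ds_range Percent-diameter-stenosis sampling range, within (30, 95).
#' @param lesion_len_range Lesion length range, mm.
#' @param min_gap Minimum normal-lumen gap between lesions, mm (>= 10).
#' @param edge_margin_mm Healthy margin kept at both vessel ends, mm.
#' @param ds Sample spacing of generated profiles, mm.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_vessels = 100, seed = 20260101,
                        length_range = c(80, 140),
                        inlet_radius_range = c(1.4, 2.2),
                        taper_pct_range = c(10, 30),
                        n_lesions = 2,
                        ds_range = c(40, 85),
                        lesion_len_range = c(8, 25),
                        min_gap = 10,
                        edge_margin_mm = 5,
                        ds = 0.25) {
  stopifnot(n_vessels >= 1, min_gap >= 10,
            ds_range[1] > 30, ds_range[2] < 95, ds_range[1] < ds_range[2],
            n_lesions >= 1, lesion_len_range[1] > 0, ds > 0)
  structure(list(n_vessels = as.integer(n_vessels), seed = as.integer(seed),
                 length_range = length_range,
                 inlet_radius_range = inlet_radius_range,
                 taper_pct_range = taper_pct_range,
                 n_lesions = as.integer(n_lesions),
                 ds_range = ds_range, lesion_len_range = lesion_len_range,
                 min_gap = min_gap, edge_margin_mm = edge_margin_mm, ds = ds),
            class = "cohort_spec")
}

# Substream seed for vessel `index`: a fixed LCG step keeps it < 2^31 and
# collision-free for any (seed, index) pair used in practice.
vessel_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(index)) %% 2147483647)
}

#' Generate one synthetic vessel
#'
#' Deterministic in `(spec$seed, index)`. The healthy baseline is a linear
#' taper; each lesion multiplies it by `1 - depth * w(s)` with `w` a raised
#' cosine over the lesion extent, so percent diameter stenosis at the throat
#' equals the sampled depth. Placement is by rejection sampling under the
#' gap and margin constraints.
#'
#' @param spec A [cohort_spec()].
#' @param index Vessel index (1-based) selecting the RNG substream.
#' @return A list: `geom` (the [vessel_geometry()]) and `lesions` (ground
#'   truth lesion tibble with planted extents and severities).
#' @export
generate_vessel <- function(spec, index = 1) {
  runif2 <- function(rng) stats::runif(1, rng[1], rng[2])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(vessel_seed(spec$seed, index), kind = "Mersenne-Twister")

  L <- round(runif2(spec$length_range) / spec$ds) * spec$ds
  r_inlet <- runif2(spec$inlet_radius_range)
  taper <- runif2(spec$taper_pct_range) / 100
  n_les <- spec$n_lesions
  m <- spec$edge_margin_mm

  placed <- NULL
  for (try in seq_len(100)) {
    lens <- stats::runif(n_les, spec$lesion_len_range[1], spec$lesion_len_range[2])
    free <- L - 2 * m - sum(lens) - (n_les - 1) * spec$min_gap
    if (free < 0) next
    w <- stats::runif(n_les + 1)
    slack <- free * w / sum(w)
    starts <- numeric(n_les)
    pos <- m + slack[1]
    for (i in seq_len(n_les)) {
      starts[i] <- pos
      pos <- pos + lens[i] + spec$min_gap + slack[i + 1]
    }
    placed <- list(starts = starts, lens = lens)
    break
  }
  if (is.null(placed)) {
    stop("could not place lesions under the gap/margin constraints; vessel too short",
         call. = FALSE)
  }
  depths <- stats::runif(n_les, spec$ds_range[1], spec$ds_range[2]) / 100

  s <- seq(0, L, by = spec$ds)
  r0 <- r_inlet * (1 - taper * s / L)
  shrink <- rep(1, length(s))
  for (i in seq_len(n_les)) {
    a <- placed$starts[i]; b <- a + placed$lens[i]
    w_s <- ifelse(s > a & s < b,
                  0.5 * (1 - cos(2 * pi * (s - a) / (b - a))), 0)
    shrink <- shrink * (1 - depths[i] * w_s)
  }
  geom <- vessel_geometry(s, r0 * shrink,
                          label = sprintf("synthetic-%d-%d", spec$seed, index))

  lesions <- purrr::map_dfr(seq_len(n_les), function(i) {
    a <- placed$starts[i]; b <- a + placed$lens[i]
    inside <- s >= a & s < b
    i_min <- which.min(geom$r_mm[inside])
    r_min <- geom$r_mm[inside][i_min]
    r_ref <- r0[inside][i_min]
    lesion_tibble(a, b, r_min, r_ref, 100 * (1 - r_min / r_ref))
  })
  list(geom = geom, lesions = lesions)
}

#' Generate a cohort of synthetic vessels
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `ffr_cohort`: `vessels` (list of
#'   [generate_vessel()] outputs) and `manifest`, a tibble of ground truth
#'   (one row per lesion: vessel id, geometry summary, planted extents and
#'   severities).
#' @export
generate_cohort <- function(spec) {
  vessels <- purrr::map(seq_len(spec$n_vessels), function(i) {
    generate_vessel(spec, i)
  })
  manifest <- purrr::imap_dfr(vessels, function(v, i) {
    dplyr::mutate(v$lesions,
                  vessel_id = i,
                  lesion_idx = dplyr::row_number(),
                  length_mm = vessel_length(v$geom),
                  inlet_radius_mm = v$geom$r_mm[1],
                  .before = 1)
  })
  structure(list(vessels = vessels, manifest = manifest, spec = spec),
            class = "ffr_cohort")
}

#' @export
print.ffr_cohort <- function(x, ...) {
  cat(sprintf("<ffr_cohort> %d vessels (seed %d), %d lesions, DS %.0f-%.0f%%\n",
              length(x$vessels), x$spec$seed, nrow(x$manifest),
              min(x$manifest$pct_ds), max(x$manifest$pct_ds)))
  invisible(x)
}
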