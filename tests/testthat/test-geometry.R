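test_that("vessel construction enforces the profile invariants", {
  expect_error(vessel_geometry(c(0, 1, 1, 2:10), rep(2, 12)), "increasing")
  expect_error(vessel_geometry(0:10, c(rep(2, 10), -1)), "positive")
  expect_error(vessel_geometry(0:5, rep(2, 6)), "at least 10 samples")
  g <- make_tube()
  expect_s3_class(g, "vessel_geometry")
  expect_identical(nrow(g), 201L)
})

test_that("resampling interpolates linearly, preserves endpoints and is idempotent", {
  tube <- make_tube(r = 2, L = 50, ds = 1)
  for (ds in c(0.1, 0.25, 0.7)) {
    rs <- resample_vessel(tube, ds)
    expect_true(all(rs$r_mm == 2))
    expect_equal(range(rs$s_mm), c(0, 50))
  }
  taper <- make_taper(r0 = 2.0, r1 = 1.5, L = 50, ds = 1)
  rs <- resample_vessel(taper, 0.5)
  expect_equal(rs$r_mm[rs$s_mm == 25], 1.75)
  expect_identical(resample_vessel(rs, 0.5), rs)
})

test_that("reference profile is identity on healthy vessels and interpolates flanks in lesions", {
  tube <- make_tube()
  expect_equal(reference_profile(tube, NULL)$r_mm, tube$r_mm)

  les <- data.frame(a = 20, b = 30, depth = 0.5)
  v <- make_lesion_vessel(les, r0 = 2, L = 60)
  ref <- reference_profile(v, lesion_extents(les))
  expect_equal(ref$r_mm, rep(2, nrow(v)), tolerance = 1e-12)

  # independent interpolation oracle on a tapered vessel
  vt <- make_lesion_vessel(data.frame(a = 40, b = 60, depth = 0.4),
                           r0 = 2.5, r1 = 1.5, L = 100)
  ref_t <- reference_profile(vt, lesion_extents(data.frame(a = 40, b = 60)))
  inside <- vt$s_mm >= 40 & vt$s_mm < 60
  r40 <- 2.5 - 1 * 40 / 100
  r60 <- 2.5 - 1 * 60 / 100
  expected <- r40 + (r60 - r40) * (vt$s_mm[inside] - 40) / 20
  expect_equal(ref_t$r_mm[inside], expected, tolerance = 1e-10)
  expect_equal(ref_t$r_mm[!inside], vt$r_mm[!inside])
})

test_that("reference profile rejects lesions touching a vessel endpoint", {
  v <- make_lesion_vessel(data.frame(a = 0, b = 10, depth = 0.5), L = 60)
  expect_error(reference_profile(v, lesion_extents(data.frame(a = 0, b = 10))),
               "endpoint")
})

test_that("percent stenosis matches its definition and a brute-force scan", {
  expect_equal(percent_stenosis(make_tube(), c(10, 40)), 0)

  # forced 50%: narrow a 2 mm tube to exactly 1 mm with a sampled plateau
  s <- seq(0, 60, 0.25)
  r <- rep(2, length(s)); r[s >= 28 & s <= 32] <- 1
  v50 <- vessel_geometry(s, r)
  expect_equal(percent_stenosis(v50, c(25, 35)), 50)

  # cosine lesion, nominal depth 0.6: expected value from an independent
  # scan of the generator's closed form at the sampled grid
  les <- data.frame(a = 20, b = 35, depth = 0.6)
  v <- make_lesion_vessel(les, r0 = 2, L = 60, ds = 0.25)
  r_scan <- 2 * (1 - cosine_dip(seq(20, 35 - 0.25, 0.25), 20, 35, 0.6))
  expected <- 100 * (1 - min(r_scan) / 2)
  expect_equal(percent_stenosis(v, c(20, 35)), expected, tolerance = 1e-10)

  expect_error(percent_stenosis(make_tube(), c(40, 30)), "end > start")
})

test_that("lesion detection finds, separates and merges narrowings", {
  expect_identical(nrow(detect_lesions(make_tube())), 0L)

  two_far <- make_lesion_vessel(
    data.frame(a = c(15, 55), b = c(25, 65), depth = 0.5), r0 = 2, L = 90)
  det <- detect_lesions(two_far, min_pct = 30, min_gap = 10)
  expect_identical(nrow(det), 2L)
  expect_lt(max(abs(det$pct_ds - 50)), 1)

  # 5 mm apart with min_gap = 10: merged into one lesion spanning both
  two_close <- make_lesion_vessel(
    data.frame(a = c(15, 30), b = c(25, 40), depth = 0.5), r0 = 2, L = 60)
  det_m <- detect_lesions(two_close, min_pct = 30, min_gap = 10)
  expect_identical(nrow(det_m), 1L)
  expect_lt(abs(det_m$start_mm - 15), 0.5)
  expect_lt(abs(det_m$end_mm - 40), 0.5)

  # sub-threshold narrowing is not a lesion
  mild <- make_lesion_vessel(data.frame(a = 20, b = 30, depth = 0.2), L = 60)
  expect_identical(nrow(detect_lesions(mild, min_pct = 30)), 0L)
})

test_that("idealization restores the reference lumen only inside the extent", {
  tube <- make_tube()
  expect_equal(idealize_lumen(tube, c(10, 40), NULL)$r_mm, tube$r_mm)

  les <- data.frame(a = c(15, 45), b = c(25, 55), depth = c(0.5, 0.6))
  v <- make_lesion_vessel(les, r0 = 2.2, r1 = 1.8, L = 80)
  lt <- lesion_extents(les)

  g1 <- idealize_lumen(v, c(15, 25), lt)
  expect_equal(percent_stenosis(g1, c(14, 26)), 0, tolerance = 1e-6)
  outside <- v$s_mm < 15 | v$s_mm >= 25
  expect_identical(g1$r_mm[outside], v$r_mm[outside])  # lesion 2 untouched

  # idempotence, sample-wise
  expect_identical(idealize_lumen(g1, c(15, 25), lt)$r_mm, g1$r_mm)
})

test_that("reference never falls below the measured radius inside lesions", {
  spec <- cohort_spec(n_vessels = 8, seed = 11)
  for (i in 1:8) {
    v <- generate_vessel(spec, i)
    ref <- reference_profile(v$geom, v$lesions)
    expect_true(all(ref$r_mm >= v$geom$r_mm - 1e-9))
  }
})

test_that("percent stenosis is stable under finer resampling", {
  les <- data.frame(a = 22, b = 38, depth = 0.55)
  v <- make_lesion_vessel(les, r0 = 2.1, r1 = 1.7, L = 70, ds = 0.25)
  p_coarse <- percent_stenosis(v, c(22, 38))
  p_fine <- percent_stenosis(resample_vessel(v, 0.05), c(22, 38))
  expect_lt(abs(p_coarse - p_fine), 1)
})
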