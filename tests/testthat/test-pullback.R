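test_that("pullback of a healthy vessel is flat and starts at 1 proximally", {
  sol <- oracle_solve(make_tube(r = 2.4, L = 70), test_bc(r_micro = 25))
  trace <- simulate_pullback(sol)
  expect_s3_class(trace, "ffr_pullback")
  expect_true(all(diff(trace$s_mm) < 0))  # distal to proximal
  expect_gte(min(trace$ffr), 0.97)
  expect_equal(trace$ffr[nrow(trace)], 1, tolerance = 1e-6)
  expect_equal(range(trace$s_mm), c(0, 70))
})

test_that("pullback step-downs co-locate with the planted lesions", {
  spec <- cohort_spec(n_vessels = 1, seed = 3)
  v <- generate_vessel(spec, 1)
  sol <- oracle_solve(v$geom, test_bc(r_micro = 18))
  prof <- sol$profile
  drop_per_sample <- -diff(prof$ffr)
  # the two largest local drops must fall inside the two planted extents
  top <- order(drop_per_sample, decreasing = TRUE)[1:2]
  s_top <- prof$s_mm[top]
  ds <- median(diff(v$geom$s_mm))
  hits <- sapply(s_top, function(s) {
    any(s >= v$lesions$start_mm - ds & s <= v$lesions$end_mm + ds)
  })
  expect_true(all(hits))
})

test_that("apparent gradients read margins, telescope, and clamp at zero", {
  les <- data.frame(a = c(20, 50), b = c(32, 62), depth = c(0.5, 0.6))
  v <- make_lesion_vessel(les, r0 = 2, r1 = 1.75, L = 85)
  lesions <- detect_lesions(v)
  sol <- oracle_solve(v, test_bc(r_micro = 18))
  trace <- simulate_pullback(sol)

  g1 <- apparent_gradient(trace, lesions[1, ], margin = 2, lesions = lesions)
  g2 <- apparent_gradient(trace, lesions[2, ], margin = 2, lesions = lesions)
  # manual read at the same points
  ffr_t <- function(p) approx(trace$s_mm, trace$ffr, xout = p)$y
  expect_equal(g1, ffr_t(lesions$start_mm[1] - 2) - ffr_t(lesions$end_mm[1] + 2),
               tolerance = 1e-12)

  # telescoping: lesion gradients plus healthy losses equal 1 - distal FFR
  pts <- c(0, lesions$start_mm[1] - 2, lesions$end_mm[1] + 2,
           lesions$start_mm[2] - 2, lesions$end_mm[2] + 2, 85)
  healthy_losses <- (ffr_t(pts[1]) - ffr_t(pts[2])) +
    (ffr_t(pts[3]) - ffr_t(pts[4])) + (ffr_t(pts[5]) - ffr_t(pts[6]))
  expect_equal(g1 + g2 + healthy_losses, 1 - distal_ffr(sol),
               tolerance = 1e-10)

  # healthy stretch far from lesions shows only viscous losses
  healthy_ext <- lesion_extents(data.frame(a = 66, b = 80))
  g_h <- apparent_gradient(trace, healthy_ext[1, ], margin = 2)
  expect_lt(g_h, 0.005)
  expect_gte(g_h, 0)
})

test_that("overlapping read margins of close lesions are shrunk with a warning", {
  les <- data.frame(a = c(20, 35), b = c(32, 47), depth = c(0.5, 0.5))
  v <- make_lesion_vessel(les, r0 = 2, L = 70)
  lesions <- lesion_extents(les)  # 3 mm gap < 2 * margin
  sol <- oracle_solve(v, test_bc(r_micro = 20))
  expect_warning(
    g <- apparent_gradient(simulate_pullback(sol), lesions[1, ],
                           margin = 2, lesions = lesions),
    "shrunk")
  expect_gte(g, 0)
})

test_that("the true gradient equals the apparent one when there is no companion", {
  les <- data.frame(a = 30, b = 45, depth = 0.6)
  v <- make_lesion_vessel(les, r0 = 2, L = 80)
  lesions <- detect_lesions(v)
  bc <- test_bc(r_micro = 20)
  sol <- oracle_solve(v, bc)
  g_apparent <- apparent_gradient(simulate_pullback(sol), lesions[1, ],
                                  lesions = lesions)
  g_true <- true_gradient(v, lesions, lesions[1, ], bc)
  expect_equal(g_true, g_apparent, tolerance = 1e-9)
})

test_that("serial companions mask each lesion's true gradient", {
  les <- data.frame(a = c(20, 52), b = c(34, 66), depth = c(0.55, 0.6))
  v <- make_lesion_vessel(les, r0 = 2, r1 = 1.75, L = 90)
  lesions <- detect_lesions(v)
  bc <- test_bc(r_micro = 18)
  trace <- simulate_pullback(oracle_solve(v, bc))
  for (i in 1:2) {
    g_app <- apparent_gradient(trace, lesions[i, ], lesions = lesions)
    g_true <- true_gradient(v, lesions, lesions[i, ], bc)
    expect_gt(g_true, g_app)
  }
})

test_that("the masking vanishes continuously as the companion disappears", {
  gaps <- sapply(c(0.5, 0.35, 0.2, 0.1, 0.04), function(depth_companion) {
    les <- data.frame(a = c(20, 52), b = c(34, 66),
                      depth = c(depth_companion, 0.6))
    v <- make_lesion_vessel(les, r0 = 2, L = 90)
    lesions <- lesion_extents(les)
    bc <- test_bc(r_micro = 18)
    g_app <- apparent_gradient(simulate_pullback(oracle_solve(v, bc)),
                               lesions[2, ], lesions = lesions)
    g_true <- true_gradient(v, lesions, lesions[2, ], bc)
    g_true - g_app
  })
  expect_true(all(diff(gaps) < 1e-9))   # shrinking companion shrinks the gap
  expect_lt(gaps[length(gaps)], 0.005)  # and it vanishes in the limit
})
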