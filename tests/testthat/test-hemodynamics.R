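test_that("segment pressure drop matches closed-form Poiseuille on a straight tube", {
  tube <- make_tube(r = 1.5, L = 30)
  expect_identical(segment_dp(tube, c(0, 30), 0), 0)
  dp <- segment_dp(tube, c(0, 30), q = 2)
  dp_cf <- 2 * tube_rv(1.5, 30)
  expect_equal(dp, dp_cf, tolerance = 1e-10)
  expect_equal(segment_resistance(tube, c(0, 30), 1),
               segment_resistance(tube, c(0, 30), 3), tolerance = 1e-10)
})

test_that("segment pressure drop converges under grid refinement", {
  les <- data.frame(a = 20, b = 32, depth = 0.6)
  v <- make_lesion_vessel(les, r0 = 2, L = 60, ds = 0.25)
  v_fine <- make_lesion_vessel(les, r0 = 2, L = 60, ds = 0.025)
  dp <- segment_dp(v, c(10, 50), q = 2)
  dp_fine <- segment_dp(v_fine, c(10, 50), q = 2)
  expect_lt(abs(dp - dp_fine) / dp_fine, 0.01)
})

test_that("flow solve is exact in the linear and quadratic limits", {
  # straight tube: no constriction, so the law is linear in q
  tube <- make_tube(r = 1.8, L = 80, ds = 0.05)
  bc <- test_bc(r_micro = 25)
  sol <- oracle_solve(tube, bc, ds = 0.05)
  rv <- segment_dp(tube, c(0, 80), 1)
  expect_equal(sol$q_ml_s, 90 / (rv + 25), tolerance = 1e-9)

  # lesioned vessel: q must equal the positive quadratic root of
  # S q^2 + (Rv + r_micro) q - (pa - pv) = 0, with Rv and S extracted
  # independently from two pressure-drop evaluations
  les <- data.frame(a = 25, b = 40, depth = 0.6)
  v <- make_lesion_vessel(les, r0 = 1.9, L = 80, ds = 0.05)
  dp1 <- segment_dp(v, c(0, 80), 1)
  dp2 <- segment_dp(v, c(0, 80), 2)
  s_coef <- dp2 / 2 - dp1          # (2Rv + 4S)/2 - (Rv + S) = S
  rv_coef <- dp1 - s_coef
  b_tot <- rv_coef + 25
  q_expected <- (-b_tot + sqrt(b_tot^2 + 4 * s_coef * 90)) / (2 * s_coef)
  sol2 <- oracle_solve(v, bc, ds = 0.05)
  expect_equal(sol2$q_ml_s, q_expected, tolerance = 1e-7)
})

test_that("a disease-free wide vessel keeps distal FFR near 1 under hyperemic flow", {
  wide <- make_tube(r = 2.5, L = 80)
  bc <- test_bc(r_micro = 30)  # gives q near 3 mL/s
  sol <- oracle_solve(wide, bc)
  expect_gt(sol$q_ml_s, 2.5)
  expect_gte(distal_ffr(sol), 0.97)
  expect_equal(sol$profile$ffr[1], 1, tolerance = 1e-9)
  expect_true(all(diff(sol$profile$p_mmHg) <= 1e-12))
})

test_that("ffr_at interpolates the profile and rejects outside positions", {
  sol <- structure(list(
    q_ml_s = 1,
    profile = tibble::tibble(s_mm = c(0, 30, 35, 70, 75),
                             p_mmHg = c(90, 90 * 0.93, 90 * 0.93,
                                        90 * 0.80, 90 * 0.80),
                             ffr = c(1, 0.93, 0.93, 0.80, 0.80)),
    bc = test_bc(), fluid = NULL, meta = list()), class = "ffr_solution")
  expect_equal(ffr_at(sol, 0), 1, tolerance = 1e-6)
  expect_equal(ffr_at(sol, 32), 0.93)
  expect_equal(ffr_at(sol, 75), 0.80)
  expect_lte(ffr_at(sol, 70), ffr_at(sol, 30))
  expect_error(ffr_at(sol, 80), "outside")
})

test_that("pressure drops over a partition telescope to the total drop", {
  les <- data.frame(a = c(18, 50), b = c(30, 62), depth = c(0.5, 0.65))
  v <- make_lesion_vessel(les, r0 = 2, r1 = 1.7, L = 90)
  sol <- oracle_solve(v, test_bc(r_micro = 18))
  prof <- sol$profile
  cuts <- c(0, 30, 45, 62, 90)
  drops <- sapply(seq_len(length(cuts) - 1), function(i) {
    p <- approx(prof$s_mm, prof$p_mmHg, xout = cuts[i:(i + 1)])$y
    p[1] - p[2]
  })
  expect_equal(sum(drops), prof$p_mmHg[1] - prof$p_mmHg[nrow(prof)],
               tolerance = 1e-10)
})

test_that("deepening a lesion strictly decreases distal FFR", {
  ffrs <- sapply(c(0.3, 0.45, 0.6, 0.75), function(d) {
    v <- make_lesion_vessel(data.frame(a = 25, b = 40, depth = d),
                            r0 = 2, L = 80)
    distal_ffr(oracle_solve(v, test_bc(r_micro = 18)))
  })
  expect_true(all(diff(ffrs) < 0))
})

test_that("the solver approaches the analytic Poiseuille limit for vanishing disease", {
  v <- make_lesion_vessel(data.frame(a = 25, b = 40, depth = 0.005),
                          r0 = 2, L = 80, ds = 0.05)
  bc <- test_bc(r_micro = 400)  # small flow keeps losses viscous
  sol <- oracle_solve(v, bc, ds = 0.05)
  dp_total <- sol$profile$p_mmHg[1] - utils::tail(sol$profile$p_mmHg, 1)
  dp_poiseuille <- segment_dp(make_tube(r = 2, L = 80, ds = 0.05),
                              c(0, 80), sol$q_ml_s)
  expect_lt(abs(dp_total - dp_poiseuille) / dp_poiseuille, 0.005)
})

test_that("halving the oracle grid changes distal FFR by less than 0.002", {
  les <- data.frame(a = c(20, 55), b = c(32, 68), depth = c(0.55, 0.6))
  v <- make_lesion_vessel(les, r0 = 1.9, r1 = 1.6, L = 90)
  bc <- test_bc(r_micro = 18)
  f1 <- distal_ffr(oracle_solve(v, bc, ds = 0.05))
  f2 <- distal_ffr(oracle_solve(v, bc, ds = 0.025))
  expect_lt(abs(f1 - f2), 0.002)
})
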