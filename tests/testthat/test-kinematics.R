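test_that("growth zone end follows the mature-fraction rule", {
  prof <- step_profile()
  gz <- growth_zone_end(prof)
  expect_equal(gz$x_gz, 0.5)
  expect_equal(gz$l_mat, 100)

  # strictly increasing profile ending at its maximum
  g <- seq(0, 2, by = 0.1)
  inc <- cell_profile(g, 20 + 50 * g)
  gz2 <- growth_zone_end(inc)
  expect_equal(gz2$x_gz, g[which(inc$fitted >= 0.95 * 120)[1]])

  flat <- cell_profile(g, rep(80, length(g)))
  expect_error(growth_zone_end(flat), "degenerate")
})

test_that("cell numbers integrate the reciprocal profile with unit conversion", {
  g <- seq(0, 1, by = 0.1)
  const50 <- cell_profile(g, rep(50, length(g)))
  # growth_zone_end not involved: 0.2 cm = 2000 um of 50 um cells
  expect_equal(cell_number(const50, 0, 0.2), 40)
  const20 <- cell_profile(g, rep(20, length(g)))
  expect_equal(cell_number(const20, 0, 0.2), 100)
  # non-grid endpoints are interpolated
  expect_equal(cell_number(const50, 0.03, 0.17), 0.14 * 1e4 / 50)
  expect_error(cell_number(const50, 0.5, 0.2), "a < b")
})

test_that("grid quadrature matches brute-force integration of the interpolant", {
  set.seed(12)
  g <- seq(0, 6, by = 0.1)
  prof <- cell_profile(g, sigmoid_profile(g))
  fine <- seq(0.2, 5.7, by = 1e-4)
  lf <- approx(g, prof$fitted, fine)$y
  oracle <- sum(1 / lf) * 1e-4 * 1e4
  for (rule in c("trapezoid", "midpoint")) {
    n <- cell_number(prof, 0.2, 5.7, rule)
    expect_equal(n, oracle, tolerance = 1e-3)
  }
})

test_that("the step-profile worked example reproduces the hand-derived chain", {
  hand <- c(LER_mm_h = 2, L_mer_mm = 2, L_el_mm = 3, L_gz_mm = 5,
            l_div_um = 20, l_mat_um = 100, N_mer = 100, N_el = 150,
            N_gz = 250, P_cells_h = 20, D_cells_cell_h = 0.2,
            R_el_um_um_h = log(5) / 7.5, T_c_h = log(2) / 0.2,
            T_mer_h = log(2) / 0.2 * log2(100), T_el_h = 7.5)
  prof <- step_profile(dx = 1e-7)   # fine grid: quadrature error < 1e-6
  res <- analyze_plant(2, prof, 2000, plant_id = "X")
  expect_equal(unlist(res[-1]), hand, tolerance = 1e-6)
  expect_identity_suite(res)
})

test_that("kinematic outputs are homogeneous in the elongation rate", {
  prof <- step_profile(dx = 0.01)
  a <- analyze_plant(2, prof, 2000, plant_id = "X")
  b <- analyze_plant(4, prof, 2000, plant_id = "X")
  for (p in c("P_cells_h", "D_cells_cell_h", "R_el_um_um_h"))
    expect_equal(b[[p]], 2 * a[[p]])
  for (p in c("T_c_h", "T_mer_h", "T_el_h"))
    expect_equal(b[[p]], a[[p]] / 2)
  for (p in c("L_mer_mm", "L_el_mm", "L_gz_mm", "l_div_um", "l_mat_um",
              "N_mer", "N_el", "N_gz"))
    expect_equal(b[[p]], a[[p]])
})

test_that("a one-cell meristem spends no time in it and guards trip on N_mer < 1", {
  g <- seq(0, 1, by = 0.1)
  prof <- cell_profile(g, ifelse(g < 0.5, 50, 100))
  # 0.005 cm of 50 um cells = exactly one cell
  res <- analyze_plant(2, prof, 50, plant_id = "X")
  expect_equal(res$N_mer, 1)
  expect_equal(res$T_mer_h, 0)

  expect_warning(res2 <- analyze_plant(2, prof, 25, plant_id = "X"),
                 "N_mer < 1")
  expect_true(is.na(res2$D_cells_cell_h) && is.na(res2$T_c_h))
  expect_false(is.na(res2$T_el_h))
})

test_that("meristem longer than the growth zone is a named error", {
  prof <- step_profile()
  expect_error(analyze_plant(2, prof, 6000, plant_id = "Q7"),
               "Q7.*meristem.*exceeds growth zone")
})

test_that("kinematic_analysis maps plants, reports failures, keeps the rest", {
  scn <- growth_zone_scenario(n_plants = 3, noise_sd = 3, leaf_noise_sd = 1)
  sim <- simulate(scn, seed = 99)
  ml <- calculate_ler(sim$leaf_lengths)
  tidy <- get_all_fitted_cell_lengths(sim$cell_lengths)
  kin <- kinematic_analysis(ml, tidy, sim$meristem_sizes)
  expect_s3_class(kin, "kinematic_result")
  expect_equal(nrow(kin), 3L)
  expect_equal(names(kin)[1], "plant_id")
  expect_equal(ncol(kin), 16L)
  expect_identity_suite(kin)

  mer_missing <- sim$meristem_sizes[-2L, ]
  expect_warning(kin2 <- kinematic_analysis(ml, tidy, mer_missing), "P2")
  expect_equal(nrow(kin2), 2L)
  f <- attr(kin2, "failures")
  expect_equal(f$plant_id, "P2")
  expect_match(f$error, "meristem")
})

test_that("noiseless simulated plants recover the analytic truth closely", {
  scn <- growth_zone_scenario(n_plants = 2, noise_sd = 0, leaf_noise_sd = 0)
  sim <- simulate(scn, seed = 1)
  kin <- kinematic_analysis(calculate_ler(sim$leaf_lengths),
                            get_all_fitted_cell_lengths(sim$cell_lengths),
                            sim$meristem_sizes)
  gt <- ground_truth(scn)[1, ]
  for (p in c("D_cells_cell_h", "T_c_h", "l_mat_um", "P_cells_h"))
    expect_equal(kin[[p]], rep(gt[[p]], 2), tolerance = 0.02)
})
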