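test_that("scenario construction enforces the profile ordering invariants", {
  expect_error(growth_zone_scenario(l_init = 50, l_div = 45),
               "l_init <= l_div")
  expect_error(growth_zone_scenario(l_div = 130, l_mat = 120))
  scn <- growth_zone_scenario()
  expect_gt(scn$x_gz_true, scn$mer_length_true / 1e4)
  # the logistic passes through l_div exactly at the meristem boundary
  expect_equal(scn$profile$f(scn$mer_length_true / 1e4), scn$l_div_true)
  expect_equal(scn$profile$f(0), scn$l_init)
})

test_that("simulation is deterministic given the seed, down to written bytes", {
  scn <- growth_zone_scenario(n_plants = 3)
  s1 <- simulate(scn, seed = 7)
  s2 <- simulate(scn, seed = 7)
  expect_identical(s1, s2)
  s3 <- simulate(scn, seed = 8)
  expect_false(identical(s1$cell_lengths, s3$cell_lengths))

  d1 <- tempfile(); d2 <- tempfile()
  write_scenario_files(scn, d1, seed = 7)
  write_scenario_files(scn, d2, seed = 7)
  for (f in c("leaf_lengths.txt", "cell_lengths.txt", "meristem_sizes.txt",
              "ground_truth.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("noiseless draws lie exactly on the true profile and growth line", {
  scn <- growth_zone_scenario(n_plants = 2, noise_sd = 0, leaf_noise_sd = 0)
  sim <- simulate(scn, seed = 1)
  expect_equal(sim$cell_lengths$cell_length,
               scn$profile$f(sim$cell_lengths$position))
  lers <- compute_interval_lers(sim$leaf_lengths)
  expect_equal(lers$LER, rep(scn$LER_true, nrow(lers)))
})

test_that("the missing-data mask produces merged intervals downstream", {
  scn <- growth_zone_scenario(n_plants = 2, leaf_noise_sd = 0,
                              missing_pattern = list(P1 = 2L))
  sim <- simulate(scn, seed = 1)
  expect_true(is.na(sim$leaf_lengths$lengths[1, 2]))
  s <- compute_interval_lers(sim$leaf_lengths)
  expect_equal(sum(s$plant_id == "P1"), 3L)  # 5 points, one hidden
  expect_equal(sum(s$plant_id == "P2"), 4L)
  expect_equal(s$delta_t[s$plant_id == "P1"][1], 48)
})

test_that("cell-length noise has the configured dispersion", {
  scn <- growth_zone_scenario(n_plants = 1, noise_sd = 5,
                              cells_per_position = 30)
  sim <- simulate(scn, seed = 42)
  sds <- tapply(sim$cell_lengths$cell_length, sim$cell_lengths$position, sd)
  # mature-region positions: truncation at the 1 um floor is negligible
  # there; with 30 draws the chi-distribution of the sample SD puts
  # P(3 < s < 7 | sigma = 5) above 0.99
  plateau <- as.numeric(names(sds)) > 6
  expect_gt(mean(sds[plateau] > 3 & sds[plateau] < 7), 0.95)
})

test_that("repeated noisy leaf series estimate the true LER without bias", {
  scn <- growth_zone_scenario(n_plants = 5, leaf_noise_sd = 2)
  set.seed(77)
  ests <- replicate(200, {
    leaf <- simulate_leaf_lengths(scn)
    mean(calculate_ler(leaf)$mean_LER)
  })
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - scn$LER_true), 2 * se + 1e-3)
})

test_that("analytic ground truth satisfies the kinematic identity suite", {
  for (shape in c("logistic", "piecewise_exponential", "step")) {
    scn <- growth_zone_scenario(n_plants = 1, profile_shape = shape,
                                l_init = if (shape == "step") 45 else 15)
    gt <- ground_truth(scn)
    expect_identity_suite(gt)
    expect_equal(gt$L_gz_mm, scn$x_gz_true * 10)
  }
})

test_that("scaling every length doubles sizes, keeps counts, halves rates", {
  base <- growth_zone_scenario(n_plants = 1)
  scaled <- growth_zone_scenario(n_plants = 1, mer_length = 30000,
                                 l_init = 30, l_div = 90, l_mat = 240,
                                 x_max = 20,
                                 positions = seq(0.1, 19.9, by = 0.2))
  a <- ground_truth(base); b <- ground_truth(scaled)
  for (p in c("N_mer", "N_el", "N_gz")) expect_equal(b[[p]], a[[p]])
  for (p in c("l_div_um", "l_mat_um", "L_mer_mm", "L_gz_mm"))
    expect_equal(b[[p]], 2 * a[[p]])
  for (p in c("P_cells_h", "D_cells_cell_h", "R_el_um_um_h"))
    expect_equal(b[[p]], a[[p]] / 2)
  for (p in c("T_c_h", "T_mer_h", "T_el_h"))
    expect_equal(b[[p]], 2 * a[[p]])
})

test_that("the step scenario's analytic truth equals the hand-derived chain", {
  scn <- growth_zone_scenario(n_plants = 1, LER = 2, mer_length = 2000,
                              l_init = 20, l_div = 20, l_mat = 100,
                              x_max = 1, profile_shape = "step",
                              x_step = 0.5)
  gt <- ground_truth(scn)
  expect_equal(gt$N_mer, 100, tolerance = 1e-10)
  expect_equal(gt$N_el, 150, tolerance = 1e-10)
  expect_equal(gt$P_cells_h, 20, tolerance = 1e-10)
  expect_equal(gt$T_el_h, 7.5, tolerance = 1e-10)
})
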