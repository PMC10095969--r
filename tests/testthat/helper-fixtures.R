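# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

daily_timepoints <- function(n, start = "2020/01/06 10:00") {
  as.POSIXct(start, format = "%Y/%m/%d %H:%M", tz = "UTC") + 86400 * (0:(n - 1))
}

make_leaf_table <- function(lengths, start = "2020/01/06 10:00") {
  # lengths: matrix (plants x timepoints) or vector (one plant)
  if (is.vector(lengths)) lengths <- matrix(lengths, nrow = 1)
  leaf_length_table(sprintf("C%d", seq_len(nrow(lengths))),
                    daily_timepoints(ncol(lengths), start), lengths)
}

# A smooth sigmoid cell-length generator used across smoothing tests.
sigmoid_profile <- function(x, lo = 20, hi = 120, mid = 4, rate = 1.2) {
  lo + (hi - lo) / (1 + exp(-rate * (x - mid)))
}

random_cells <- function(n = 200, noise = 5, plant = "C1", xmax = 10) {
  x <- sort(runif(n, 0, xmax))
  data.frame(plant_id = plant, position = x,
             cell_length = pmax(1, sigmoid_profile(x) + rnorm(n, 0, noise)),
             stringsAsFactors = FALSE)
}

# Independent brute-force local-linear fit: one lm() per grid point.
bruteforce_loclin <- function(x, y, xout, h) {
  vapply(xout, function(g) {
    w <- dnorm((x - g) / h)
    unname(predict(lm(y ~ x, weights = w), newdata = data.frame(x = g)))
  }, numeric(1))
}

# Step profile on a grid: l_low below x_step, l_high at and above.
step_profile <- function(dx = 0.1, xmax = 1, x_step = 0.5,
                         l_low = 20, l_high = 100) {
  g <- seq(0, xmax, by = dx)
  cell_profile(g, ifelse(g < x_step - 1e-12, l_low, l_high), plant_id = "S")
}

total_variation <- function(v) sum(abs(diff(v[!is.na(v)])))

expect_identity_suite <- function(kin, tol = 1e-9) {
  expect_equal(kin$L_gz_mm, kin$L_mer_mm + kin$L_el_mm, tolerance = tol)
  expect_equal(kin$N_gz, kin$N_mer + kin$N_el, tolerance = tol)
  expect_equal(kin$P_cells_h, kin$D_cells_cell_h * kin$N_mer, tolerance = tol)
  expect_equal(kin$T_c_h * kin$D_cells_cell_h, rep(log(2), nrow(kin)),
               tolerance = tol)
  expect_equal(kin$T_el_h * kin$P_cells_h, kin$N_el, tolerance = tol)
  expect_equal(kin$R_el_um_um_h * kin$T_el_h,
               log(kin$l_mat_um / kin$l_div_um), tolerance = tol)
}
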