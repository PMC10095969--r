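test_that("local-linear fit reproduces straight lines exactly for any bandwidth", {
  set.seed(2)
  x <- sort(runif(40, 0, 10))
  y <- 12 + 7.5 * x
  for (h in c(0.05, 0.4, 3, 50)) {
    prof <- fit_profile(x, y, h, interval_in_cm = 0.5, max_position = 10)
    expect_equal(prof$fitted, 12 + 7.5 * prof$grid, tolerance = 1e-9)
  }
})

test_that("grid-point fits equal an independent per-point weighted least squares", {
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(8:30, 1)
    x <- sort(runif(n, 0, 10))
    y <- sigmoid_profile(x) + rnorm(n, 0, 8)
    h <- runif(1, 0.3, 2)
    prof <- fit_profile(x, y, h, interval_in_cm = 0.5, max_position = 10)
    oracle <- bruteforce_loclin(x, y, prof$grid, prof$h)
    expect_equal(prof$fitted, oracle, tolerance = 1e-8)
  }
})

test_that("very large bandwidths approach the global least-squares line", {
  set.seed(9)
  x <- sort(runif(120, 0, 10))
  y <- sigmoid_profile(x) + rnorm(120, 0, 4)
  prof <- fit_profile(x, y, 1e4, interval_in_cm = 1, max_position = 10)
  ols <- unname(predict(lm(y ~ x), newdata = data.frame(x = prof$grid)))
  expect_equal(prof$fitted, ols, tolerance = 1e-4)
})

test_that("rougher multipliers give more wiggly fits than smoother ones", {
  # total variation orders strict (0.3x) > plug-in (1x) >= loose (3x) fits
  set.seed(16)
  cells <- random_cells(600, noise = 10)
  tv <- vapply(c(0.3, 1, 3), function(m) {
    fit <- fit_cell_profiles(cells, bw_multiplier = m)
    total_variation(fit$profiles[["C1"]]$fitted)
  }, numeric(1))
  expect_gt(tv[1], tv[2])
  expect_gte(tv[2], tv[3] - 1e-8)
})

test_that("fit accuracy on a noisy sigmoid stays within a few noise SDs", {
  set.seed(31)
  noise <- 6
  cells <- random_cells(400, noise = noise)
  fit <- fit_cell_profiles(cells)
  prof <- fit$profiles[["C1"]]
  interior <- !prof$extrapolated & prof$grid > 0.5 & prof$grid < 9.5
  err <- abs(prof$fitted[interior] - sigmoid_profile(prof$grid[interior]))
  expect_lt(max(err), 3 * noise)
})

test_that("multiplier scales computed bandwidths exactly and smooths monotonically", {
  set.seed(4)
  cells <- random_cells(200, noise = 8)
  f1 <- fit_cell_profiles(cells, bw_multiplier = 1)
  f2 <- fit_cell_profiles(cells, bw_multiplier = 2)
  expect_equal(f2$bandwidths$h_used, 2 * f1$bandwidths$h_used)
  expect_equal(f2$bandwidths$h_plugin, f1$bandwidths$h_plugin)
  expect_lte(total_variation(f2$profiles[["C1"]]$fitted),
             total_variation(f1$profiles[["C1"]]$fitted) + 1e-8)
})

test_that("failed selection falls back to alternative_bw without the multiplier", {
  set.seed(6)
  good <- random_cells(120, noise = 5, plant = "A")
  tiny <- data.frame(plant_id = "B", position = c(0.5, 1, 2),
                     cell_length = c(25, 30, 60))
  expect_warning(
    fit <- fit_cell_profiles(rbind(good, tiny), bw_multiplier = 2,
                             alternative_bw = 0.5),
    "bandwidth selection failed for plant B")
  bw <- fit$bandwidths
  expect_equal(bw$source, c("computed", "alternative"))
  expect_equal(bw$h_used[2], 0.5)          # multiplier NOT applied
  expect_true(is.na(bw$h_plugin[2]))
  expect_equal(bw$h_used[1], 2 * bw$h_plugin[1])
  # mean of the successful bandwidths suggests an alternative
  expect_equal(mean_bandwidth(fit), bw$h_plugin[1])
})

test_that("the fitted grid spans 0 to the rounded-down maximum position", {
  cells <- data.frame(plant_id = "A",
                      position = seq(0, 10, length.out = 60),
                      cell_length = sigmoid_profile(seq(0, 10,
                                                        length.out = 60)))
  tidy <- get_all_fitted_cell_lengths(cells, interval_in_cm = 0.1,
                                      alternative_bw = 0.5)
  expect_equal(nrow(tidy), 101L)           # 0.0, 0.1, ..., 10.0
  expect_equal(range(tidy$position), c(0, 10))

  short <- data.frame(plant_id = "A", position = seq(0, 9.57, by = 0.11),
                      cell_length = sigmoid_profile(seq(0, 9.57, by = 0.11)))
  tidy2 <- suppressWarnings(
    get_all_fitted_cell_lengths(short, alternative_bw = 0.5))
  expect_equal(max(tidy2$position), 9.5)   # rounded down to the grid
})

test_that("tidy and wide extractions carry identical values", {
  set.seed(19)
  cells <- rbind(random_cells(150, plant = "A"), random_cells(150, plant = "B"))
  fit <- fit_cell_profiles(cells)
  tidy <- get_all_fitted_cell_lengths(cells, fit = fit, tidy = TRUE)
  wide <- get_all_fitted_cell_lengths(cells, fit = fit, tidy = FALSE)
  expect_equal(names(wide), c("position", "A", "B"))
  for (p in c("A", "B")) {
    tp <- tidy[tidy$plant_id == p, ]
    expect_equal(wide[[p]][match(tp$position, wide$position)],
                 tp$fitted_length)
  }
})

test_that("predict and residuals are consistent with the stored fits", {
  set.seed(23)
  cells <- random_cells(100)
  fit <- fit_cell_profiles(cells)
  pr <- predict(fit, positions = cells$position)
  res <- residuals(fit)
  expect_equal(cells$cell_length - pr$fitted_length, res)
  expect_lt(abs(mean(res)), 2)
})

test_that("extrapolated grid points are flagged", {
  cells <- data.frame(plant_id = "A", position = seq(2, 8, 0.25),
                      cell_length = sigmoid_profile(seq(2, 8, 0.25)))
  fit <- fit_cell_profiles(cells, alternative_bw = 0.5)
  prof <- fit$profiles[["A"]]
  expect_true(all(prof$extrapolated[prof$grid < 2]))
  expect_false(any(prof$extrapolated[prof$grid >= 2 & prof$grid <= 8]))
})

count_pdf_pages <- function(path) {
  lines <- readLines(path, warn = FALSE, skipNul = TRUE)
  count_line <- grep("/Type /Pages", lines, useBytes = TRUE, value = TRUE)[1]
  as.integer(sub(".*?/Count (\\d+).*", "\\1", count_line, useBytes = TRUE))
}

test_that("the diagnostic report has one page per plant plus the bandwidth page", {
  set.seed(27)
  cells <- do.call(rbind, lapply(sprintf("P%d", 1:3), function(p)
    random_cells(120, plant = p)))
  fit <- fit_cell_profiles(cells)
  dir <- tempfile(); dir.create(dir)
  path <- render_fit_report(fit, dir)
  expect_equal(basename(path), "fit_plots_using_bandwidth_multiplier_1.pdf")
  expect_equal(count_pdf_pages(path), 4L)
  expect_error(render_fit_report(fit, file.path(dir, "missing")),
               "directory")
})
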