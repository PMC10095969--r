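test_that("interval LERs follow the definition, including zero growth", {
  leaf <- make_leaf_table(c(100, 148))
  s <- compute_interval_lers(leaf)
  expect_equal(nrow(s), 1L)
  expect_equal(s$delta_t, 24)
  expect_equal(s$LER, 2)

  flat <- make_leaf_table(c(150, 150, 150))
  s2 <- compute_interval_lers(flat)
  expect_equal(s2$LER, c(0, 0))
  expect_equal(s2$interval_index, 1:2)
})

test_that("a missing middle measurement merges its bracketing intervals", {
  leaf <- make_leaf_table(c(100, NA, 196))
  s <- compute_interval_lers(leaf)
  expect_equal(nrow(s), 1L)
  expect_equal(s$delta_t, 48)
  expect_equal(s$LER, 2)

  # merged LER equals the duration-weighted mean of the original two
  set.seed(11)
  for (i in 1:20) {
    y <- cumsum(c(100, runif(2, 0, 60)))
    hours <- cumsum(c(0, runif(2, 5, 40)))
    tp <- daily_timepoints(1)[1] + 3600 * round(hours * 60) / 60
    full <- leaf_length_table("P", tp, matrix(y, 1))
    holed <- leaf_length_table("P", tp, matrix(c(y[1], NA, y[3]), 1))
    sf <- compute_interval_lers(full)
    sh <- compute_interval_lers(holed)
    expect_equal(sh$LER,
                 sum(sf$LER * sf$delta_t) / sum(sf$delta_t),
                 tolerance = 1e-12)
  }
})

test_that("plants with too few measurements warn and yield no intervals", {
  leaf <- make_leaf_table(matrix(c(100, 148, 90, NA), 2, byrow = TRUE))
  expect_warning(s <- compute_interval_lers(leaf), "C2")
  expect_equal(unique(s$plant_id), "C1")
  expect_warning(m <- calculate_ler(leaf), "C2")
  expect_equal(m$mean_LER[m$plant_id == "C2"], NA_real_)
  expect_equal(m$n_intervals_used[m$plant_id == "C2"], 0L)
})

test_that("mean LER uses the first n intervals, capped at availability", {
  # plant with interval LERs 2.0, 2.2, 3.0, 3.4
  y <- 100 + 24 * cumsum(c(0, 2.0, 2.2, 3.0, 3.4))
  leaf <- make_leaf_table(y)
  expect_equal(calculate_ler(leaf, 2)$mean_LER, 2.1)
  expect_equal(calculate_ler(leaf, 4)$mean_LER, 2.65)
  short <- make_leaf_table(100 + 24 * cumsum(c(0, 2.0, 2.2)))
  m <- calculate_ler(short, 4)
  expect_equal(m$mean_LER, 2.1)
  expect_equal(m$n_intervals_used, 2L)

  # mean over all intervals equals the arithmetic mean of the tidy series
  tidy <- calculate_ler(leaf, output = "tidy_LER")
  expect_equal(calculate_ler(leaf, 99)$mean_LER, mean(tidy$LER))
  # time-weighted variant is total growth over total time
  expect_equal(calculate_ler(leaf, 4, time_weighted = TRUE)$mean_LER,
               (y[5] - y[1]) / 96)
})

test_that("output layouts agree and illegal tokens are rejected", {
  set.seed(3)
  L <- t(replicate(3, 100 + cumsum(c(0, runif(3, 10, 80)))))
  L[2, 3] <- NA
  leaf <- make_leaf_table(L)
  tidy <- calculate_ler(leaf, output = "tidy_LER")
  counts <- table(tidy$plant_id)
  expect_equal(sum(counts), nrow(tidy))
  expect_equal(as.integer(counts[c("C1", "C2", "C3")]), c(3L, 2L, 3L))
  wide <- calculate_ler(leaf, output = "wide_LER")
  expect_equal(nrow(wide), 3L)
  expect_equal(wide$LER_1[wide$plant_id == "C1"],
               tidy$LER[tidy$plant_id == "C1" & tidy$interval_index == 1])
  expect_error(calculate_ler(leaf, output = "all"), "tidy_LER")
})

test_that("LER is invariant to time shifts and to fully-missing columns", {
  y <- c(100, 148, 196)
  a <- make_leaf_table(y)
  b <- make_leaf_table(y, start = "2021/06/01 08:30")
  expect_equal(compute_interval_lers(a)$LER, compute_interval_lers(b)$LER)

  tp <- daily_timepoints(4)
  with_na <- leaf_length_table("C1", tp, matrix(c(100, 148, NA, 196), 1))
  without <- leaf_length_table("C1", tp[-3], matrix(c(100, 148, 196), 1))
  expect_equal(compute_interval_lers(with_na)[-(3:4)],
               compute_interval_lers(without)[-(3:4)])
})

test_that("negative elongation is computed but flagged", {
  expect_warning(expect_warning(
    s <- compute_interval_lers(make_leaf_table(c(100, 90))),
    "decreases"), "negative LER")
  expect_equal(s$LER, -10 / 24)
})

test_that("treatment inhibition summarises mean LERs against control", {
  ml <- data.frame(plant_id = c("C1", "C2", "M1", "M2"),
                   mean_LER = c(2, 2.2, 1.5, 1.65))
  inh <- ler_inhibition(ml, c("control", "control", "mild", "mild"), "control")
  expect_equal(inh$inhibition_pct[inh$group == "mild"],
               100 * (1 - 1.575 / 2.1))
  expect_true(is.na(inh$inhibition_pct[inh$group == "control"]))
})
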