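# Growth-zone simulator: generates the three input tables from a
# parameterised steady-state scenario whose kinematic parameters are known
# analytically, so the whole pipeline can be validated without real data.

#' Define a steady-state growth-zone scenario
#'
#' A scenario fixes the true cell-length profile `l*(x)` along the leaf
#' axis, the true leaf elongation rate, the meristem length, and the
#' measurement design (sampling positions, cells measured per position,
#' noise, leaf-length schedule, missing-data pattern). Three profile shapes
#' are available:
#' \itemize{
#'   \item `"logistic"` (default): `l*(x)` rises smoothly from `l_init` at
#'     the base towards the plateau `l_mat`, with the steepness set so that
#'     the profile passes through `l_div` exactly at the meristem boundary;
#'   \item `"piecewise_exponential"`: linear from `l_init` to `l_div` over
#'     the meristem, exponential growth to `l_mat` at `x_mat`, constant
#'     beyond (mimicking exponential cell expansion);
#'   \item `"step"`: `l_div` below `x_step`, `l_mat` at and beyond it -- a
#'     degenerate profile whose kinematic parameters have simple closed
#'     forms, useful for exact checks.
#' }
#' The implied growth-zone end `x_gz_true` (where the profile reaches
#' `mature_fraction` of its maximum over the sampled region) is computed at
#' construction and stored.
#'
#' @param n_plants number of plants (default 7, a typical number of
#'   dissected plants per treatment).
#' @param LER true leaf elongation rate, mm/h.
#' @param mer_length true meristem length, um.
#' @param l_init cell length at the leaf base, um.
#' @param l_div cell length at the meristem boundary (cells leaving the
#'   meristem), um.
#' @param l_mat mature cell length, um.
#' @param x_max extent of the sampled region, cm (default 10, the basal
#'   segment typically dissected).
#' @param profile_shape one of `"logistic"`, `"piecewise_exponential"`,
#'   `"step"`.
#' @param x_mat position where the piecewise-exponential profile reaches
#'   `l_mat` (cm).
#' @param x_step step position of the `"step"` profile (cm).
#' @param positions cell-length sampling positions, cm.
#' @param cells_per_position number of cells measured at each position.
#' @param noise_sd cell-length measurement noise. For `noise_type`
#'   `"additive"` this is an SD in um (draws are floored at 1 um so lengths
#'   stay positive); for `"multiplicative"` it is the SD of log-length
#'   (a coefficient of variation).
#' @param noise_type `"additive"` or `"multiplicative"`.
#' @param timepoints leaf-length measurement times (`POSIXct`); default five
#'   daily measurements.
#' @param leaf_length_start leaf length at the first measurement, mm.
#' @param leaf_noise_sd additive SD of leaf length measurements, mm.
#' @param missing_pattern optional list mapping plant index to the indices
#'   of timepoints whose leaf-length measurement is masked as missing.
#' @param mer_jitter_sd SD of per-plant jitter on the reported meristem
#'   length, um (default 0: the table carries the true value).
#' @param mature_fraction growth-zone-end criterion used when deriving
#'   `x_gz_true`, see [kinematic_config()].
#' @return Object of class `gz_scenario`. Key derived fields: `x_gz_true`
#'   (cm) and `profile` (list with the true profile function `f` and its
#'   breakpoints).
#' @seealso [simulate.gz_scenario()], [ground_truth()],
#'   [write_scenario_files()]
#' @export
growth_zone_scenario <- function(n_plants = 7, LER = 2.5,
                                 mer_length = 15000,
                                 l_init = 15, l_div = 45, l_mat = 120,
                                 x_max = 10,
                                 profile_shape = c("logistic",
                                                   "piecewise_exponential",
                                                   "step"),
                                 x_mat = x_max / 2, x_step = x_max / 2,
                                 positions = seq(0.05, x_max - 0.05,
                                                 by = 0.1),
                                 cells_per_position = 5, noise_sd = 6,
                                 noise_type = c("additive",
                                                "multiplicative"),
                                 timepoints = as.POSIXct(
                                   "2020/01/06 10:00",
                                   format = "%Y/%m/%d %H:%M",
                                   tz = "UTC") + 86400 * 0:4,
                                 leaf_length_start = 100,
                                 leaf_noise_sd = 2,
                                 missing_pattern = NULL,
                                 mer_jitter_sd = 0,
                                 mature_fraction = 0.95) {
  profile_shape <- match.arg(profile_shape)
  noise_type <- match.arg(noise_type)
  mer_cm <- mer_length / 1e4
  stopifnot(0 < l_init, l_init <= l_div, l_div < l_mat,
            mer_cm < x_max, LER > 0, n_plants >= 1)
  profile <- switch(profile_shape,
    logistic = {
      r <- log((l_div * (l_mat - l_init)) /
                 (l_init * (l_mat - l_div))) / mer_cm
      list(f = function(x) l_init * l_mat /
             (l_init + (l_mat - l_init) * exp(-r * x)),
           breaks = numeric(), rate = r)
    },
    piecewise_exponential = {
      stopifnot(x_mat > mer_cm, x_mat <= x_max)
      q <- log(l_mat / l_div) / (x_mat - mer_cm)
      list(f = function(x) ifelse(x <= mer_cm,
                                  l_init + (l_div - l_init) * x / mer_cm,
                                  ifelse(x < x_mat,
                                         l_div * exp(q * (x - mer_cm)),
                                         l_mat)),
           breaks = c(mer_cm, x_mat), rate = q)
    },
    step = {
      stopifnot(x_step > mer_cm, x_step <= x_max)
      list(f = function(x) ifelse(x < x_step, l_div, l_mat),
           breaks = x_step)
    })
  scn <- structure(list(
    n_plants = as.integer(n_plants), plant_id = sprintf("P%d", 1:n_plants),
    LER_true = LER, mer_length_true = mer_length,
    l_init = l_init, l_div_true = l_div, l_mat_true = l_mat,
    x_max = x_max, profile_shape = profile_shape, profile = profile,
    positions = positions, cells_per_position = as.integer(cells_per_position),
    noise_sd = noise_sd, noise_type = noise_type,
    timepoints = timepoints, leaf_length_start = leaf_length_start,
    leaf_noise_sd = leaf_noise_sd, missing_pattern = missing_pattern,
    mer_jitter_sd = mer_jitter_sd, mature_fraction = mature_fraction),
    class = "gz_scenario")
  scn$x_gz_true <- true_growth_zone_end(scn)$x_gz
  stopifnot(mer_cm < scn$x_gz_true)
  scn
}

#' @export
print.gz_scenario <- function(x, ...) {
  cat(sprintf(
    paste0("Growth-zone scenario (%s profile): %d plants, LER %g mm/h,\n",
           "  meristem %g um, cells %g -> %g -> %g um, growth zone ends at ",
           "%.3g cm\n"),
    x$profile_shape, x$n_plants, x$LER_true, x$mer_length_true,
    x$l_init, x$l_div_true, x$l_mat_true, x$x_gz_true))
  invisible(x)
}

# Infimum of {x : l*(x) >= mature_fraction * max} by bisection (profiles
# are nondecreasing; works across jumps), plus the plateau mean length.
true_growth_zone_end <- function(scn) {
  f <- scn$profile$f
  l_max <- f(scn$x_max)
  thr <- scn$mature_fraction * l_max
  lo <- 0; hi <- scn$x_max
  if (f(0) >= thr) stop("degenerate scenario: profile mature at the base",
                        call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) >= thr) hi <- mid else lo <- mid
  }
  x_gz <- hi
  # snap to an exact breakpoint when the threshold crossing is a jump
  br <- scn$profile$breaks
  if (length(br)) {
    near <- which(abs(br - x_gz) < 1e-9)
    if (length(near)) x_gz <- br[near[1L]]
  }
  list(x_gz = x_gz,
       l_mat = piecewise_integral(f, x_gz, scn$x_max, br) /
         (scn$x_max - x_gz))
}

# Integrate g over [a, b], splitting at profile breakpoints so adaptive
# quadrature never straddles a discontinuity.
piecewise_integral <- function(g, a, b, breaks = numeric()) {
  cuts <- sort(unique(c(a, breaks[breaks > a & breaks < b], b)))
  total <- 0
  for (i in seq_len(length(cuts) - 1L))
    total <- total + stats::integrate(g, cuts[i], cuts[i + 1L],
                                      rel.tol = 1e-12,
                                      subdivisions = 500L)$value
  total
}

#' Analytic ground truth of a scenario
#'
#' Evaluates the kinematic equation chain on the exact, noiseless profile
#' `l*(x)` of a scenario: the growth-zone end by the same
#' mature-fraction criterion used in the analysis, cell numbers by adaptive
#' quadrature of the cell density `1/l*(x)` (split at profile breakpoints,
#' so piecewise profiles are integrated exactly), and the rate/time chain on
#' top. This is the independent oracle the pipeline is validated against.
#'
#' @param scn a [growth_zone_scenario()].
#' @return A `kinematic_result` data.frame with one identical row per plant
#'   (all plants of a scenario share the same truth).
#' @export
ground_truth <- function(scn) {
  stopifnot(inherits(scn, "gz_scenario"))
  f <- scn$profile$f
  br <- scn$profile$breaks
  gz <- true_growth_zone_end(scn)
  mer_cm <- scn$mer_length_true / 1e4
  l_div <- f(mer_cm)
  dens <- function(x) 1 / f(x)
  N_mer <- 1e4 * piecewise_integral(dens, 0, mer_cm, br)
  N_el <- 1e4 * piecewise_integral(dens, mer_cm, gz$x_gz, br)
  P <- scn$LER_true * 1e3 / gz$l_mat
  D <- P / N_mer
  T_c <- log(2) / D
  T_el <- N_el / P
  out <- data.frame(
    plant_id = scn$plant_id,
    LER_mm_h = scn$LER_true,
    L_mer_mm = scn$mer_length_true / 1e3,
    L_el_mm = (gz$x_gz - mer_cm) * 10,
    L_gz_mm = gz$x_gz * 10,
    l_div_um = l_div, l_mat_um = gz$l_mat,
    N_mer = N_mer, N_el = N_el, N_gz = N_mer + N_el,
    P_cells_h = P, D_cells_cell_h = D,
    R_el_um_um_h = (log(gz$l_mat) - log(l_div)) / T_el,
    T_c_h = T_c, T_mer_h = T_c * log2(N_mer), T_el_h = T_el,
    stringsAsFactors = FALSE)
  class(out) <- c("kinematic_result", "data.frame")
  out
}

#' Simulate the measurement tables of a scenario
#'
#' Draws one synthetic dataset: the leaf length time series (true linear
#' growth at `LER_true` plus additive noise, with the missing-data mask
#' applied), the cell length measurements (`cells_per_position` noisy draws
#' of `l*(x)` at every sampling position) and the meristem table. Given the
#' same seed the output is identical.
#'
#' @param object a [growth_zone_scenario()].
#' @param nsim number of datasets (default 1; if more, a list is returned).
#' @param seed integer seed for the draws; the caller's RNG state is left
#'   untouched.
#' @param ... unused.
#' @return A list with components `leaf_lengths` (a [leaf_length_table()]),
#'   `cell_lengths` and `meristem_sizes` (data.frames in the input-table
#'   formats); or a list of `nsim` such lists.
#' @export
simulate.gz_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  one <- function() list(leaf_lengths = simulate_leaf_lengths(object),
                         cell_lengths = simulate_cell_lengths(object),
                         meristem_sizes = simulate_meristem(object))
  with_seed(seed, {
    if (nsim == 1L) one() else replicate(nsim, one(), simplify = FALSE)
  })
}

#' @rdname simulate.gz_scenario
#' @param scn a [growth_zone_scenario()].
#' @export
simulate_leaf_lengths <- function(scn, seed = NULL) {
  with_seed(seed, {
    hours <- as.numeric(difftime(scn$timepoints, scn$timepoints[1L],
                                 units = "hours"))
    L <- outer(rep(scn$leaf_length_start, scn$n_plants),
               scn$LER_true * hours, `+`)
    if (scn$leaf_noise_sd > 0)
      L <- L + matrix(stats::rnorm(length(L), 0, scn$leaf_noise_sd),
                      nrow = scn$n_plants)
    L <- pmax(L, 0)
    if (!is.null(scn$missing_pattern))
      for (i in seq_along(scn$missing_pattern)) {
        nm <- names(scn$missing_pattern)[i]
        row <- if (is.null(nm) || !nzchar(nm)) i
               else if (nm %in% scn$plant_id) match(nm, scn$plant_id)
               else as.integer(nm)
        L[row, scn$missing_pattern[[i]]] <- NA_real_
      }
    leaf_length_table(scn$plant_id, scn$timepoints, L)
  })
}

#' @rdname simulate.gz_scenario
#' @export
simulate_cell_lengths <- function(scn, seed = NULL) {
  with_seed(seed, {
    rows <- lapply(seq_len(scn$n_plants), function(i) {
      pos <- rep(scn$positions, each = scn$cells_per_position)
      mu <- scn$profile$f(pos)
      y <- if (scn$noise_sd <= 0) mu
      else if (scn$noise_type == "additive")
        pmax(1, mu + stats::rnorm(length(mu), 0, scn$noise_sd))
      else pmax(1, mu * exp(stats::rnorm(length(mu), 0, scn$noise_sd)))
      data.frame(plant_id = scn$plant_id[i], position = pos,
                 cell_length = y, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    row.names(out) <- NULL
    class(out) <- c("cell_length_table", "data.frame")
    out
  })
}

#' @rdname simulate.gz_scenario
#' @export
simulate_meristem <- function(scn, seed = NULL) {
  with_seed(seed, {
    m <- rep(scn$mer_length_true, scn$n_plants)
    if (scn$mer_jitter_sd > 0)
      m <- pmax(1, m + stats::rnorm(scn$n_plants, 0, scn$mer_jitter_sd))
    data.frame(plant_id = scn$plant_id, mer_length_um = m,
               stringsAsFactors = FALSE)
  })
}

#' Write a simulated dataset to disk
#'
#' Simulates one dataset (see [simulate.gz_scenario()]) and writes the three
#' tab-delimited input files plus `ground_truth.tsv` with the scenario's
#' analytic kinematic parameters. Output is byte-identical for identical
#' (scenario, seed).
#'
#' @param scn a [growth_zone_scenario()].
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_scenario_files <- function(scn, dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate(scn, seed = seed)
  paths <- c(
    leaf_lengths = file.path(dir, "leaf_lengths.txt"),
    cell_lengths = file.path(dir, "cell_lengths.txt"),
    meristem_sizes = file.path(dir, "meristem_sizes.txt"),
    ground_truth = file.path(dir, "ground_truth.tsv"))
  write_leaf_lengths(sim$leaf_lengths, paths["leaf_lengths"])
  write_cell_lengths(sim$cell_lengths, paths["cell_lengths"])
  write_meristem_sizes(sim$meristem_sizes, paths["meristem_sizes"])
  gt <- ground_truth(scn)
  gt[-1L] <- lapply(gt[-1L], function(v) format_table_num(v))
  write_tab_delim(gt, paths["ground_truth"])
  invisible(paths)
}
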