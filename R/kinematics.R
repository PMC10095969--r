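# Kinematic equations for a steady-state growing monocot leaf.
#
# The leaf is treated as a one-dimensional flow of cells: material moves
# from the meristem (division zone) through the elongation zone and exits
# the growth zone at mature cell length. Under steady state the flux of
# mature tissue out of the growth zone equals the leaf elongation rate, so
# the elongation rate, the spatial cell-length profile and the measured
# meristem length determine division and expansion rates.
#
# Units: positions cm, cell lengths um, leaf elongation rate mm/h. Outputs
# follow the conventional mixture: zone lengths mm, cell lengths um, rates
# per hour.

UM_PER_CM <- 1e4
UM_PER_MM <- 1e3
MM_PER_CM <- 10

#' Kinematic analysis configuration
#'
#' Pins the two numerical conventions of the analysis: the fraction of the
#' maximum fitted cell length that defines the end of the growth zone, and
#' the quadrature rule for the cell-density integral.
#'
#' @param mature_fraction fraction of the maximum fitted cell length at
#'   which cells are considered mature (default 0.95, the convention of the
#'   kinematic methodology literature).
#' @param integration_rule `"trapezoid"` (default) or `"midpoint"` rule for
#'   integrating the cell density `1/l(x)` over the grid. On the default
#'   1 mm grid the two agree to well under 0.1%.
#' @return A list of class `kinematic_config`.
#' @export
kinematic_config <- function(mature_fraction = 0.95,
                             integration_rule = c("trapezoid", "midpoint")) {
  stopifnot(is.numeric(mature_fraction), mature_fraction > 0,
            mature_fraction <= 1)
  structure(list(mature_fraction = mature_fraction,
                 integration_rule = match.arg(integration_rule)),
            class = "kinematic_config")
}

#' Locate the end of the growth zone
#'
#' The growth zone ends where cells reach their mature length. Operationally
#' this is the smallest grid position whose fitted cell length reaches
#' `mature_fraction` of the maximum fitted cell length; the mature cell
#' length is the mean of the fitted values from that position onwards.
#'
#' @param profile a [cell_profile()].
#' @param mature_fraction see [kinematic_config()].
#' @return list with `x_gz` (cm) and `l_mat` (um).
#' @export
growth_zone_end <- function(profile, mature_fraction = 0.95) {
  stopifnot(inherits(profile, "cell_profile"))
  f <- profile$fitted
  ok <- !is.na(f)
  if (sum(ok) < 2L) stop("profile has fewer than 2 fitted values",
                         call. = FALSE)
  l_max <- max(f[ok])
  idx <- which(ok & f >= mature_fraction * l_max)[1L]
  x_gz <- profile$grid[idx]
  if (idx == 1L)
    stop("degenerate profile: mature cell length reached at the leaf base ",
         "(no growth gradient)", call. = FALSE)
  list(x_gz = x_gz, l_mat = mean(f[profile$grid >= x_gz & ok]))
}

# Linear interpolation of the fitted profile at arbitrary positions.
profile_at <- function(profile, x) {
  stats::approx(profile$grid, profile$fitted, xout = x, rule = 1L)$y
}

#' Number of cells along a leaf segment
#'
#' The cell-length profile is the reciprocal of the linear cell density, so
#' the number of cells occupying the axis segment `[a, b]` is the integral
#' of `1/l(x)` over the segment. The integral is computed numerically over
#' the profile grid (trapezoid by default, midpoint as alternative), with
#' linear interpolation of `l(x)` at non-grid endpoints.
#'
#' @param profile a [cell_profile()]; positions cm, lengths um.
#' @param a,b segment bounds in cm, `0 <= a < b <=` grid end.
#' @param integration_rule see [kinematic_config()].
#' @return Number of cells (dimensionless, fractional allowed).
#' @export
cell_number <- function(profile, a, b,
                        integration_rule = c("trapezoid", "midpoint")) {
  integration_rule <- match.arg(integration_rule)
  stopifnot(inherits(profile, "cell_profile"))
  g <- profile$grid
  if (!(a >= 0 && a < b && b <= g[length(g)] + 1e-12))
    stop("need 0 <= a < b <= grid end", call. = FALSE)
  inner <- g[g > a & g < b]
  nodes <- unique(c(a, inner, b))
  l <- profile_at(profile, nodes)
  if (anyNA(l) || any(l <= 0))
    stop("non-positive or missing fitted cell length inside [a, b]",
         call. = FALSE)
  if (integration_rule == "trapezoid") {
    dens <- 1 / l
    int <- sum(diff(nodes) * (dens[-1L] + dens[-length(dens)]) / 2)
  } else {
    mid <- (nodes[-1L] + nodes[-length(nodes)]) / 2
    lmid <- profile_at(profile, mid)
    if (anyNA(lmid) || any(lmid <= 0))
      stop("non-positive or missing fitted cell length inside [a, b]",
           call. = FALSE)
    int <- sum(diff(nodes) / lmid)
  }
  int * UM_PER_CM
}

kinematic_columns <- c(
  "LER_mm_h", "L_mer_mm", "L_el_mm", "L_gz_mm", "l_div_um", "l_mat_um",
  "N_mer", "N_el", "N_gz", "P_cells_h", "D_cells_cell_h", "R_el_um_um_h",
  "T_c_h", "T_mer_h", "T_el_h")

#' Kinematic parameters for a single plant
#'
#' Runs the steady-state kinematic equation chain for one plant, combining
#' its mean leaf elongation rate, fitted cell-length profile and measured
#' meristem length:
#' \itemize{
#'   \item zone geometry: `L_mer` (measured), growth-zone end `x_gz` and
#'     mature cell length `l_mat` from [growth_zone_end()], `L_gz = x_gz`,
#'     `L_el = L_gz - L_mer`, `l_div = l(L_mer)`;
#'   \item cell counts: `N_mer`, `N_el` from the cell-density integral
#'     ([cell_number()]), `N_gz = N_mer + N_el`;
#'   \item rates: cell production `P = LER / l_mat` (cells/h), division rate
#'     `D = P / N_mer` (cells/cell/h), average relative elongation rate
#'     `R_el = ln(l_mat / l_div) / T_el`;
#'   \item times: cell cycle `T_c = ln(2) / D`, time in the meristem
#'     `T_mer = T_c log2(N_mer)` (a cell traverses a meristem of `N` cells
#'     in `log2 N` doublings under steady state), time in the elongation
#'     zone `T_el = N_el / P`.
#' }
#' When `N_mer < 1` or `P <= 0` the division-related quantities are
#' reported missing, with a warning, rather than as infinities.
#'
#' @param mean_LER mean leaf elongation rate (mm/h), positive.
#' @param profile the plant's fitted [cell_profile()].
#' @param mer_length_um measured meristem length (um).
#' @param config a [kinematic_config()].
#' @param plant_id label used in messages.
#' @return One-row data.frame with `plant_id` and the 15 kinematic
#'   parameters (`LER_mm_h`, `L_mer_mm`, `L_el_mm`, `L_gz_mm`, `l_div_um`,
#'   `l_mat_um`, `N_mer`, `N_el`, `N_gz`, `P_cells_h`, `D_cells_cell_h`,
#'   `R_el_um_um_h`, `T_c_h`, `T_mer_h`, `T_el_h`).
#' @export
analyze_plant <- function(mean_LER, profile, mer_length_um,
                          config = kinematic_config(),
                          plant_id = profile$plant_id) {
  stopifnot(inherits(profile, "cell_profile"),
            inherits(config, "kinematic_config"))
  if (!is.finite(mean_LER) || mean_LER <= 0)
    stop(sprintf("plant %s: mean LER must be positive", plant_id),
         call. = FALSE)
  if (!is.finite(mer_length_um) || mer_length_um <= 0)
    stop(sprintf("plant %s: meristem length must be positive", plant_id),
         call. = FALSE)
  gz <- growth_zone_end(profile, config$mature_fraction)
  mer_cm <- mer_length_um / UM_PER_CM
  if (mer_cm >= gz$x_gz)
    stop(sprintf("plant %s: meristem (%.3g cm) exceeds growth zone (%.3g cm)",
                 plant_id, mer_cm, gz$x_gz), call. = FALSE)
  l_div <- profile_at(profile, mer_cm)
  if (is.na(l_div) || l_div <= 0)
    stop(sprintf("plant %s: no fitted cell length at the meristem boundary",
                 plant_id), call. = FALSE)
  N_mer <- cell_number(profile, 0, mer_cm, config$integration_rule)
  N_el <- cell_number(profile, mer_cm, gz$x_gz, config$integration_rule)
  P <- mean_LER * UM_PER_MM / gz$l_mat
  if (N_mer < 1 || P <= 0) {
    warning(sprintf(
      "plant %s: N_mer < 1 or P <= 0; division-related parameters reported missing",
      plant_id), call. = FALSE)
    D <- T_c <- T_mer <- NA_real_
  } else {
    D <- P / N_mer
    T_c <- log(2) / D
    T_mer <- T_c * log2(N_mer)
  }
  T_el <- N_el / P
  R_el <- (log(gz$l_mat) - log(l_div)) / T_el
  out <- data.frame(
    plant_id = plant_id,
    LER_mm_h = mean_LER,
    L_mer_mm = mer_length_um / UM_PER_MM,
    L_el_mm = (gz$x_gz - mer_cm) * MM_PER_CM,
    L_gz_mm = gz$x_gz * MM_PER_CM,
    l_div_um = l_div,
    l_mat_um = gz$l_mat,
    N_mer = N_mer, N_el = N_el, N_gz = N_mer + N_el,
    P_cells_h = P, D_cells_cell_h = D, R_el_um_um_h = R_el,
    T_c_h = T_c, T_mer_h = T_mer, T_el_h = T_el,
    stringsAsFactors = FALSE)
  out
}

#' Kinematic analysis for all plants
#'
#' Performs the full kinematic calculation (see [analyze_plant()]) for every
#' plant present in the tidy fitted cell lengths, looking up its mean leaf
#' elongation rate and meristem length by plant ID. Plants that fail
#' (missing LER or meristem entry, meristem exceeding the growth zone,
#' degenerate profile) are reported in the `failures` attribute while the
#' remaining plants are still computed.
#'
#' @param mean_lers data.frame with `plant_id` and `mean_LER` (mm/h), as
#'   returned by [calculate_ler()] -- or any per-plant steady-state mean the
#'   user prefers.
#' @param tidy_cell_lengths tidy `(plant_id, position, fitted_length)`
#'   records on a regular position grid, as returned by
#'   [get_all_fitted_cell_lengths()].
#' @param meristem data.frame with `plant_id` and `mer_length_um`, see
#'   [read_meristem_sizes()].
#' @param config a [kinematic_config()].
#' @return data.frame of class `kinematic_result`: one row per successfully
#'   analysed plant, columns `plant_id` plus the 15 kinematic parameters.
#'   Attribute `failures`: data.frame `plant_id`, `error`. Attribute
#'   `config`: the configuration used.
#' @export
kinematic_analysis <- function(mean_lers, tidy_cell_lengths, meristem,
                               config = kinematic_config()) {
  stopifnot(all(c("plant_id", "mean_LER") %in% names(mean_lers)),
            ncol(tidy_cell_lengths) >= 3L,
            all(c("plant_id", "mer_length_um") %in% names(meristem)))
  plants <- unique(tidy_cell_lengths$plant_id)
  rows <- list(); fails <- list()
  for (p in plants) {
    res <- tryCatch({
      sel <- tidy_cell_lengths$plant_id == p
      pos <- tidy_cell_lengths[[2L]][sel]
      fitl <- tidy_cell_lengths[[3L]][sel]
      ord <- order(pos)
      i <- match(p, mean_lers$plant_id)
      if (is.na(i)) stop("no mean LER entry for this plant ID")
      j <- match(p, meristem$plant_id)
      if (is.na(j)) stop("no meristem size entry for this plant ID")
      prof <- cell_profile(pos[ord], fitl[ord], plant_id = p)
      analyze_plant(mean_lers$mean_LER[i], prof, meristem$mer_length_um[j],
                    config, plant_id = p)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[p]] <- data.frame(plant_id = p, error = conditionMessage(res),
                               stringsAsFactors = FALSE)
    } else rows[[p]] <- res
  }
  if (length(fails))
    warning("kinematic analysis failed for plant(s): ",
            paste(names(fails), collapse = ", "), call. = FALSE)
  out <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(
      rep(list(numeric()), length(kinematic_columns) + 1L),
      c("plant_id", kinematic_columns)))
  row.names(out) <- NULL
  structure(out, failures = if (length(fails)) do.call(rbind, fails) else NULL,
            config = config, class = c("kinematic_result", "data.frame"))
}

#' @export
print.kinematic_result <- function(x, digits = 4, ...) {
  cat(sprintf("Kinematic analysis: %d plant(s)\n", nrow(x)))
  print.data.frame(x, digits = digits, row.names = FALSE)
  f <- attr(x, "failures")
  if (!is.null(f)) {
    cat("Failed plants:\n")
    for (i in seq_len(nrow(f)))
      cat(sprintf("  - %s: %s\n", f$plant_id[i], f$error[i]))
  }
  invisible(x)
}

#' @export
summary.kinematic_result <- function(object, ...) {
  num <- object[kinematic_columns]
  out <- data.frame(
    parameter = kinematic_columns,
    mean = vapply(num, mean, numeric(1), na.rm = TRUE),
    se = vapply(num, function(v) stats::sd(v, na.rm = TRUE) /
                  sqrt(sum(!is.na(v))), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(n = nrow(object), table = out),
            class = "summary.kinematic_result")
}

#' @export
print.summary.kinematic_result <- function(x, ...) {
  cat(sprintf("Kinematic parameters, mean +/- SE over %d plant(s):\n", x$n))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
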