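#' Fitted cell-length profile for one plant
#'
#' Low-level container for a smoothed cell-length profile on a regular grid
#' along the leaf axis: positions in cm from the base, fitted cell lengths in
#' um, the first derivative of the fit in um/cm, and a flag marking grid
#' points outside the measured position range (extrapolations).
#'
#' @param grid numeric vector of grid positions (cm), constant spacing,
#'   starting at 0.
#' @param fitted fitted cell lengths (um) at the grid points; `NA` allowed.
#' @param derivative first derivative (um/cm); computed by central finite
#'   differences of `fitted` when omitted.
#' @param extrapolated logical flag per grid point; default all `FALSE`.
#' @param plant_id optional plant label.
#' @param h bandwidth used (cm), if any.
#' @return An object of class `cell_profile`.
#' @export
cell_profile <- function(grid, fitted, derivative = NULL,
                         extrapolated = NULL, plant_id = NA_character_,
                         h = NA_real_) {
  stopifnot(length(grid) >= 2L, length(fitted) == length(grid))
  steps <- diff(grid)
  if (any(steps <= 0) ||
      max(steps) - min(steps) > 1e-8 * max(steps))
    stop("grid must be strictly increasing with constant spacing",
         call. = FALSE)
  if (any(fitted <= 0, na.rm = TRUE))
    stop("fitted cell lengths must be positive", call. = FALSE)
  if (is.null(derivative)) derivative <- central_diff(fitted, steps[1L])
  stopifnot(length(derivative) == length(grid))
  if (is.null(extrapolated)) extrapolated <- rep(FALSE, length(grid))
  structure(list(plant_id = plant_id, grid = grid, fitted = fitted,
                 derivative = derivative,
                 extrapolated = as.logical(extrapolated),
                 h = h, interval = steps[1L]),
            class = "cell_profile")
}

central_diff <- function(f, dx) {
  n <- length(f)
  d <- rep(NA_real_, n)
  if (n >= 3L) d[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (2 * dx)
  d[1L] <- (f[2L] - f[1L]) / dx
  d[n] <- (f[n] - f[n - 1L]) / dx
  d
}

#' @export
print.cell_profile <- function(x, ...) {
  cat(sprintf(
    "Cell length profile%s: grid 0..%g cm (step %g), h = %s cm\n",
    if (is.na(x$plant_id)) "" else paste0(" [", x$plant_id, "]"),
    max(x$grid), x$interval,
    if (is.na(x$h)) "?" else format(signif(x$h, 4))))
  invisible(x)
}

#' Smooth one plant's cell lengths onto a regular grid
#'
#' Local-linear kernel regression (Gaussian kernel of scale `h_used`) of
#' cell length against position, evaluated on the grid `0, d, 2d, ...` up to
#' the largest measured position rounded down to the grid. The first
#' derivative is estimated from the fitted grid values by central finite
#' differences (one-sided at the ends) by default, or by a local-quadratic
#' derivative fit. Grid points outside the measured position range are
#' extrapolations of the local fit and are flagged as such; fitted values
#' that come out non-positive (possible far into an extrapolated tail) are
#' set to missing with a warning.
#'
#' @param x measurement positions (cm from the leaf base).
#' @param y cell lengths (um).
#' @param h_used bandwidth (cm), must be positive.
#' @param interval_in_cm grid spacing (cm, default 0.1).
#' @param max_position grid extent (cm); defaults to `max(x)`.
#' @param derivative `"central"` (finite differences of the grid fit) or
#'   `"local_quadratic"` (degree-2 local-polynomial first derivative with
#'   the same bandwidth).
#' @param plant_id optional label stored in the result.
#' @details The Gaussian-kernel local-linear fit is numerically undefined
#'   wherever the kernel covers fewer than two distinct positions, so the
#'   fit is evaluated with an effective bandwidth no smaller than half the
#'   largest gap between adjacent distinct sampling positions. This lower
#'   bound only engages when the selected bandwidth is smaller than the
#'   sampling resolution -- in practice only for (near-)noise-free data,
#'   where it makes the fit interpolatory. The requested bandwidth is kept
#'   in the result as `h_requested`.
#' @return A [cell_profile()].
#' @export
fit_profile <- function(x, y, h_used, interval_in_cm = 0.1,
                        max_position = max(x),
                        derivative = c("central", "local_quadratic"),
                        plant_id = NA_character_) {
  derivative <- match.arg(derivative)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (!is.finite(h_used) || h_used <= 0)
    stop("h_used must be a positive bandwidth", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("degenerate design: need at least 2 distinct positions",
         call. = FALSE)
  grid <- seq(0, by = interval_in_cm,
              length.out = floor(max_position / interval_in_cm + 1e-9) + 1L)
  h_eff <- max(h_used, max(diff(sort(unique(x)))) / 2)
  fitted <- locallinear_fit(x, y, grid, h_eff)
  nonpos <- !is.na(fitted) & fitted <= 0
  if (any(nonpos)) {
    warning(sprintf(
      "%d fitted value(s) were non-positive and set to missing%s",
      sum(nonpos),
      if (is.na(plant_id)) "" else paste0(" (plant ", plant_id, ")")),
      call. = FALSE)
    fitted[nonpos] <- NA_real_
  }
  deriv <- if (derivative == "central") central_diff(fitted, interval_in_cm)
           else locpoly_wls(x, y, grid, h_eff, degree = 2L, drv = 1L)
  out <- cell_profile(grid, fitted, deriv,
                      extrapolated = grid < min(x) | grid > max(x),
                      plant_id = plant_id, h = h_eff)
  out$h_requested <- h_used
  out
}

#' Fit cell-length profiles for all plants
#'
#' The central model-fitting step: for every plant in the cell length table,
#' selects a plug-in bandwidth (see [plugin_bandwidth()]), scales it by
#' `bw_multiplier`, and fits the local-linear profile on the regular grid.
#' When bandwidth selection degenerates for a plant (typically too few
#' measurements), the user-supplied `alternative_bw` is used as the final
#' bandwidth -- the multiplier is deliberately not applied to it -- the
#' bandwidth record is marked `"alternative"`, and a warning names the
#' plant. A plant that cannot be fitted at all (fewer than two distinct
#' positions) yields a missing profile plus a warning.
#'
#' @param cells cell length table with columns `plant_id`, `position` (cm),
#'   `cell_length` (um); see [read_cell_lengths()].
#' @param interval_in_cm grid spacing in cm (default 0.1, i.e. fitted cell
#'   lengths every millimetre).
#' @param bw_multiplier scaling of the selected bandwidth (default 1);
#'   values below 1 give a stricter fit tracking local variation, values
#'   above 1 smooth more.
#' @param alternative_bw fallback bandwidth in cm for plants whose selection
#'   failed (default 0.5).
#' @param derivative derivative estimator, see [fit_profile()].
#' @return An object of class `cell_profile_fit`: a list with `profiles`
#'   (named list of [cell_profile()] or `NULL`), `bandwidths` (data.frame
#'   `plant_id`, `h_plugin`, `multiplier`, `h_used`, `source`), the input
#'   `data` and the fitting parameters. Methods: `print`, `summary`, `coef`
#'   (bandwidth table), `fitted`, `predict`, `residuals`, `plot`.
#' @seealso [get_all_fitted_cell_lengths()] for the tidy/wide extraction,
#'   [render_fit_report()] for the diagnostic PDF.
#' @export
fit_cell_profiles <- function(cells, interval_in_cm = 0.1, bw_multiplier = 1,
                              alternative_bw = 0.5,
                              derivative = c("central", "local_quadratic")) {
  derivative <- match.arg(derivative)
  stopifnot(all(c("plant_id", "position", "cell_length") %in% names(cells)),
            bw_multiplier > 0, alternative_bw > 0, interval_in_cm > 0)
  plants <- unique(cells$plant_id)
  if (!length(plants)) stop("no plants in cell length data", call. = FALSE)
  profiles <- stats::setNames(vector("list", length(plants)), plants)
  bw <- data.frame(plant_id = plants, h_plugin = NA_real_,
                   multiplier = bw_multiplier, h_used = NA_real_,
                   source = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(plants)) {
    p <- plants[i]
    x <- cells$position[cells$plant_id == p]
    y <- cells$cell_length[cells$plant_id == p]
    h <- plugin_bandwidth(x, y)
    if (is.na(h)) {
      warning(sprintf(
        "bandwidth selection failed for plant %s (%s); using alternative_bw = %g",
        p, attr(h, "failure"), alternative_bw), call. = FALSE)
      bw$h_used[i] <- alternative_bw
      bw$source[i] <- "alternative"
    } else {
      bw$h_plugin[i] <- h
      bw$h_used[i] <- bw_multiplier * h
      bw$source[i] <- "computed"
    }
    profiles[[i]] <- tryCatch(
      fit_profile(x, y, bw$h_used[i], interval_in_cm,
                  derivative = derivative, plant_id = p),
      error = function(e) {
        warning(sprintf("could not fit plant %s: %s", p, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
  }
  structure(list(profiles = profiles, bandwidths = bw, data = cells,
                 interval_in_cm = interval_in_cm,
                 bw_multiplier = bw_multiplier,
                 alternative_bw = alternative_bw,
                 derivative = derivative, call = match.call()),
            class = "cell_profile_fit")
}

#' @export
print.cell_profile_fit <- function(x, ...) {
  nfail <- sum(x$bandwidths$source == "alternative")
  cat(sprintf(
    "Cell-length profile fit: %d plant(s), grid step %g cm, bw multiplier %g\n",
    nrow(x$bandwidths), x$interval_in_cm, x$bw_multiplier))
  if (nfail)
    cat(sprintf("  bandwidth selection failed for %d plant(s); alternative_bw = %g used\n",
                nfail, x$alternative_bw))
  invisible(x)
}

#' @export
summary.cell_profile_fit <- function(object, ...) {
  bw <- object$bandwidths
  bw$n_measurements <- vapply(bw$plant_id, function(p)
    sum(object$data$plant_id == p), integer(1))
  bw$max_position <- vapply(bw$plant_id, function(p)
    max(object$data$position[object$data$plant_id == p]), numeric(1))
  res <- residuals(object)
  structure(list(bandwidths = bw, sigma = stats::sd(res),
                 mean_h_plugin = mean(bw$h_plugin, na.rm = TRUE)),
            class = "summary.cell_profile_fit")
}

#' @export
print.summary.cell_profile_fit <- function(x, ...) {
  cat("Per-plant bandwidths and data extent:\n")
  print(x$bandwidths, row.names = FALSE)
  cat(sprintf("\nResidual SD: %.3g um; mean plug-in bandwidth: %.3g cm\n",
              x$sigma, x$mean_h_plugin))
  invisible(x)
}

#' @export
coef.cell_profile_fit <- function(object, ...) {
  stats::setNames(object$bandwidths$h_used, object$bandwidths$plant_id)
}

#' @export
fitted.cell_profile_fit <- function(object, ...) {
  do.call(rbind, lapply(object$profiles, function(p) {
    if (is.null(p)) return(NULL)
    data.frame(plant_id = p$plant_id, position = p$grid,
               fitted_length = p$fitted, stringsAsFactors = FALSE)
  })) -> out
  row.names(out) <- NULL
  out
}

#' Predict fitted cell lengths at arbitrary positions
#'
#' Re-evaluates each plant's local-linear fit (with its stored bandwidth) at
#' new positions.
#'
#' @param object a [fit_cell_profiles()] result.
#' @param positions numeric positions (cm); defaults to the fitting grid.
#' @param plants plants to predict for; default all fitted plants.
#' @param ... unused.
#' @return data.frame `plant_id`, `position`, `fitted_length`.
#' @export
predict.cell_profile_fit <- function(object, positions = NULL, plants = NULL,
                                     ...) {
  plants <- plants %||% names(object$profiles)
  out <- lapply(plants, function(p) {
    prof <- object$profiles[[p]]
    if (is.null(prof)) return(NULL)
    xout <- positions %||% prof$grid
    x <- object$data$position[object$data$plant_id == p]
    y <- object$data$cell_length[object$data$plant_id == p]
    data.frame(plant_id = p, position = xout,
               fitted_length = locallinear_fit(x, y, xout, prof$h),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  row.names(out) <- NULL
  out
}

#' @export
residuals.cell_profile_fit <- function(object, ...) {
  res <- rep(NA_real_, nrow(object$data))
  for (p in names(object$profiles)) {
    prof <- object$profiles[[p]]
    if (is.null(prof)) next
    sel <- object$data$plant_id == p
    x <- object$data$position[sel]
    y <- object$data$cell_length[sel]
    res[sel] <- y - locallinear_fit(x, y, x, prof$h)
  }
  res
}

#' Extract fitted cell lengths for all plants
#'
#' Convenience wrapper around [fit_cell_profiles()] returning just the
#' fitted grid values, in the tidy layout consumed by
#' [kinematic_analysis()] (default) or in a wide, more human-readable
#' layout with positions as rows and plants as columns.
#'
#' @inheritParams fit_cell_profiles
#' @param tidy `TRUE` for tidy `(plant_id, position, fitted_length)`
#'   records, `FALSE` for the wide layout.
#' @param fit optionally, an existing [fit_cell_profiles()] object to
#'   extract from (avoids refitting).
#' @return A data.frame, tidy or wide.
#' @export
get_all_fitted_cell_lengths <- function(cells, interval_in_cm = 0.1,
                                        bw_multiplier = 1,
                                        alternative_bw = 0.5, tidy = TRUE,
                                        fit = NULL) {
  fit <- fit %||% fit_cell_profiles(cells, interval_in_cm, bw_multiplier,
                                    alternative_bw)
  out <- fitted(fit)
  if (tidy) return(out)
  # positions as rows, plants as columns; positions matched numerically so
  # floating-point grid values survive the reshape
  pos <- sort(unique(out$position))
  plants <- unique(out$plant_id)
  m <- matrix(NA_real_, length(pos), length(plants),
              dimnames = list(NULL, plants))
  m[cbind(match(out$position, pos), match(out$plant_id, plants))] <-
    out$fitted_length
  cbind(data.frame(position = pos), as.data.frame(m))
}

#' Mean of the successfully selected bandwidths
#'
#' The mean of the per-plant plug-in bandwidths is usually a suitable
#' `alternative_bw` for the plants whose own selection failed.
#'
#' @param fit a [fit_cell_profiles()] result or its bandwidth table.
#' @return Mean plug-in bandwidth (cm), `NaN` when none was computed.
#' @export
mean_bandwidth <- function(fit) {
  bw <- if (inherits(fit, "cell_profile_fit")) fit$bandwidths else fit
  mean(bw$h_plugin, na.rm = TRUE)
}

#' Plot diagnostic panels of a profile fit
#'
#' One page per plant: measured cell lengths with the fitted profile, plus a
#' lower panel with the first derivative of the fit. Plants whose bandwidth
#' selection failed and that were not fitted show raw data only. The last
#' page plots the calculated plug-in bandwidth per plant, with gaps where
#' selection failed.
#'
#' @param x a [fit_cell_profiles()] object.
#' @param which plants to plot (default all), plus the bandwidth panel.
#' @param bandwidth_panel include the final bandwidth-per-plant plot.
#' @param show_alternative if `FALSE` (default), plants whose bandwidth
#'   selection failed are shown as raw data without a fit curve -- the
#'   fallback bandwidth is an extraction convenience, not a fit worth
#'   evaluating; set `TRUE` to draw those fits too.
#' @param ... unused.
#' @export
plot.cell_profile_fit <- function(x, which = NULL, bandwidth_panel = TRUE,
                                  show_alternative = FALSE, ...) {
  plants <- which %||% x$bandwidths$plant_id
  for (p in plants) {
    sel <- x$data$plant_id == p
    prof <- x$profiles[[p]]
    if (!show_alternative &&
        x$bandwidths$source[x$bandwidths$plant_id == p] == "alternative")
      prof <- NULL
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    graphics::plot(x$data$position[sel], x$data$cell_length[sel],
                   xlab = "position (cm)", ylab = "cell length (um)",
                   main = sprintf("%s (h = %s cm, %s)", p,
                                  format(signif(x$bandwidths$h_used[
                                    x$bandwidths$plant_id == p], 3)),
                                  x$bandwidths$source[
                                    x$bandwidths$plant_id == p]),
                   col = "grey40", pch = 16, cex = 0.6)
    if (!is.null(prof))
      graphics::lines(prof$grid, prof$fitted, col = "firebrick", lwd = 2)
    if (!is.null(prof)) {
      graphics::plot(prof$grid, prof$derivative, type = "l",
                     xlab = "position (cm)",
                     ylab = "d cell length / dx (um/cm)", col = "steelblue")
      graphics::abline(h = 0, lty = 3)
    } else {
      graphics::plot.new()
      graphics::text(0.5, 0.5, "no fit (bandwidth selection failed)")
    }
    graphics::par(op)
  }
  if (bandwidth_panel) {
    bw <- x$bandwidths
    graphics::par(mfrow = c(1, 1), mar = c(6, 4, 2, 1))
    graphics::plot(seq_len(nrow(bw)), bw$h_plugin, xaxt = "n",
                   xlab = "", ylab = "calculated bandwidth (cm)",
                   main = "Plug-in bandwidth per plant", pch = 16)
    graphics::axis(1, at = seq_len(nrow(bw)), labels = bw$plant_id, las = 2)
  }
  invisible(x)
}

#' Write the diagnostic PDF report
#'
#' Renders [plot.cell_profile_fit()] into
#' `fit_plots_using_bandwidth_multiplier_<X>.pdf` in `out_dir`: one page per
#' plant (raw data, fit and derivative; pages in input plant order) and a
#' final page with the calculated bandwidths.
#'
#' @param fit a [fit_cell_profiles()] object, or a cell length table (which
#'   is then fitted with the given parameters).
#' @param out_dir output directory (default the working directory).
#' @inheritParams fit_cell_profiles
#' @return The PDF path, invisibly.
#' @export
render_fit_report <- function(fit, out_dir = ".", interval_in_cm = 0.1,
                              bw_multiplier = 1, alternative_bw = 0.5) {
  if (!inherits(fit, "cell_profile_fit"))
    fit <- fit_cell_profiles(fit, interval_in_cm, bw_multiplier,
                             alternative_bw)
  if (!dir.exists(out_dir))
    stop("output directory does not exist: ", out_dir, call. = FALSE)
  path <- file.path(out_dir, sprintf(
    "fit_plots_using_bandwidth_multiplier_%s.pdf",
    format(fit$bw_multiplier, trim = TRUE)))
  grDevices::pdf(path, width = 7, height = 8, onefile = TRUE)
  on.exit(grDevices::dev.off())
  plot(fit)
  invisible(path)
}
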