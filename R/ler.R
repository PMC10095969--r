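#' Per-interval leaf elongation rates
#'
#' Computes the leaf elongation rate (LER) for every interval between
#' consecutive non-missing measurements of each plant. A missing measurement
#' in the middle of the series merges its two bracketing intervals into one
#' longer interval: time intervals and growth increments are adjusted so the
#' rate always refers to actually observed growth over actually elapsed time.
#'
#' Time differences are exact minute arithmetic expressed in hours; LER is
#' `delta_L / delta_t` in mm/h. Negative rates (shrinking measurements) are
#' computed as-is but flagged with a warning since they indicate measurement
#' or data-entry error. Plants with fewer than two non-missing measurements
#' contribute no intervals and trigger a warning.
#'
#' @param leaf a [leaf_length_table()].
#' @return A `data.frame` (class `ler_series`) with columns `plant_id`,
#'   `interval_index` (1-based, chronological per plant), `t_start`, `t_end`,
#'   `delta_t` (h), `delta_L` (mm) and `LER` (mm/h).
#' @export
compute_interval_lers <- function(leaf) {
  stopifnot(inherits(leaf, "leaf_length_table"))
  rows <- lapply(seq_along(leaf$plant_id), function(i) {
    y <- leaf$lengths[i, ]
    ok <- which(!is.na(y))
    if (length(ok) < 2L) return(NULL)
    t0 <- leaf$timepoints[ok[-length(ok)]]
    t1 <- leaf$timepoints[ok[-1L]]
    dL <- diff(y[ok])
    dt <- as.numeric(difftime(t1, t0, units = "hours"))
    data.frame(plant_id = leaf$plant_id[i],
               interval_index = seq_along(dL),
               t_start = t0, t_end = t1,
               delta_t = dt, delta_L = as.numeric(dL),
               LER = as.numeric(dL) / dt,
               stringsAsFactors = FALSE)
  })
  none <- vapply(rows, is.null, logical(1))
  if (any(none))
    warning("cannot compute any LER (fewer than 2 measurements) for ",
            "plant(s): ", paste(leaf$plant_id[none], collapse = ", "),
            call. = FALSE)
  out <- do.call(rbind, rows[!none])
  if (is.null(out))
    out <- data.frame(plant_id = character(), interval_index = integer(),
                      t_start = as.POSIXct(character(), tz = "UTC"),
                      t_end = as.POSIXct(character(), tz = "UTC"),
                      delta_t = numeric(), delta_L = numeric(),
                      LER = numeric(), stringsAsFactors = FALSE)
  if (any(out$LER < 0))
    warning("negative LER for plant(s): ",
            paste(unique(out$plant_id[out$LER < 0]), collapse = ", "),
            " (leaf lengths should not decrease)", call. = FALSE)
  row.names(out) <- NULL
  class(out) <- c("ler_series", "data.frame")
  out
}

#' Leaf elongation rates and per-plant means
#'
#' The workhorse for leaf growth time series: computes all per-interval
#' elongation rates (see [compute_interval_lers()]) and, by default, returns
#' the mean LER of each plant over its first `n_LER_for_mean` intervals,
#' counted chronologically from the first non-missing measurement. Plants
#' with fewer intervals than requested use all the intervals they have;
#' plants with no interval at all appear with a missing mean (and a warning)
#' rather than being dropped.
#'
#' @param leaf a [leaf_length_table()].
#' @param n_LER_for_mean number of initial intervals entering the mean
#'   (default 2, matching a design with three daily measurements before
#'   dissection).
#' @param output `"means"` for per-plant mean LERs, `"tidy_LER"` for the full
#'   interval series in long form, or `"wide_LER"` for the same series with
#'   one row per plant and one column per interval index.
#' @param time_weighted if `TRUE` the mean is total growth over total elapsed
#'   time of the first `n_LER_for_mean` intervals (duration-weighted);
#'   default `FALSE` is the plain arithmetic mean of the interval rates. The
#'   two differ only when intervals are unequal.
#' @return `"means"`: data.frame with `plant_id`, `mean_LER` (mm/h) and
#'   `n_intervals_used`. Otherwise the interval series, tidy or wide.
#' @examples
#' tp <- as.POSIXct("2020/01/06 10:00", format = "%Y/%m/%d %H:%M", tz = "UTC") +
#'   86400 * 0:2
#' leaf <- leaf_length_table("C1", tp, matrix(c(100, 148, 196), 1))
#' calculate_ler(leaf)
#' @export
calculate_ler <- function(leaf, n_LER_for_mean = 2,
                          output = c("means", "tidy_LER", "wide_LER"),
                          time_weighted = FALSE) {
  if (!is.character(output))
    stop("output must be one of 'means', 'tidy_LER', 'wide_LER'",
         call. = FALSE)
  output <- match.arg(output)
  stopifnot(n_LER_for_mean >= 1)
  series <- compute_interval_lers(leaf)
  if (output == "tidy_LER") return(series)
  if (output == "wide_LER") {
    wide <- tidy_to_wide(series[c("plant_id", "interval_index", "LER")])
    names(wide)[-1L] <- paste0("LER_", names(wide)[-1L])
    return(wide)
  }
  means <- lapply(leaf$plant_id, function(p) {
    s <- series[series$plant_id == p, , drop = FALSE]
    n_used <- min(n_LER_for_mean, nrow(s))
    if (n_used == 0L)
      return(data.frame(plant_id = p, mean_LER = NA_real_,
                        n_intervals_used = 0L, stringsAsFactors = FALSE))
    s <- s[order(s$interval_index)[seq_len(n_used)], , drop = FALSE]
    m <- if (time_weighted) sum(s$delta_L) / sum(s$delta_t) else mean(s$LER)
    data.frame(plant_id = p, mean_LER = m, n_intervals_used = n_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, means)
  row.names(out) <- NULL
  out
}

#' Treatment-level LER inhibition
#'
#' Summarises per-plant mean LERs by treatment group and expresses each
#' group's mean as a percentage change relative to a control group -- the
#' usual presentation of elongation-rate inhibition under stress treatments.
#'
#' @param mean_lers data.frame with columns `plant_id` and `mean_LER`, as
#'   returned by [calculate_ler()].
#' @param groups treatment label per row of `mean_lers` (recycled factor or
#'   character), e.g. derived from a plant-id prefix.
#' @param control the label of the reference group.
#' @return data.frame with `group`, `n`, `mean_LER`, `se_LER` and
#'   `inhibition_pct` (positive = slower elongation than control; `NA` for
#'   the control row).
#' @export
ler_inhibition <- function(mean_lers, groups, control) {
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(mean_lers), control %in% groups)
  keep <- !is.na(mean_lers$mean_LER)
  g <- groups[keep]; v <- mean_lers$mean_LER[keep]
  lev <- unique(groups)
  mu <- vapply(lev, function(l) mean(v[g == l]), numeric(1))
  se <- vapply(lev, function(l) stats::sd(v[g == l]) / sqrt(sum(g == l)),
               numeric(1))
  n <- vapply(lev, function(l) sum(g == l), integer(1))
  data.frame(group = lev, n = n, mean_LER = mu, se_LER = se,
             inhibition_pct = ifelse(lev == control, NA_real_,
                                     100 * (1 - mu / mu[lev == control])),
             stringsAsFactors = FALSE, row.names = NULL)
}
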