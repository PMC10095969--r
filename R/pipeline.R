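#' Run the full kinematic analysis from the three input files
#'
#' End-to-end driver: reads and cross-validates the leaf length, cell length
#' and meristem tables, computes per-plant mean elongation rates, fits the
#' cell-length profiles, renders the diagnostic PDF, performs the kinematic
#' analysis, and writes all artefacts to `out_dir`:
#' `ler_means.txt`, `interval_lers.txt`, `bandwidths.txt`,
#' `fitted_cell_lengths.txt`, `kinematics.txt`, the fit-report PDF,
#' `run.log` (all warnings raised during the run) and `metadata.json`
#' (configuration, bandwidths and package version).
#'
#' @param leaf_path,cells_path,mer_path paths to the three tab-delimited
#'   input files.
#' @param out_dir output directory (created if needed).
#' @param n_LER_for_mean see [calculate_ler()].
#' @param interval_in_cm,bw_multiplier,alternative_bw,derivative see
#'   [fit_cell_profiles()].
#' @param mature_fraction,integration_rule see [kinematic_config()].
#' @param time_weighted see [calculate_ler()].
#' @param report write the diagnostic PDF (default `TRUE`).
#' @return Invisibly, a list with the intermediate objects (`validation`,
#'   `ler_means`, `fit`, `kinematics`) and the vector of output `paths`.
#' @export
run_kinematic_pipeline <- function(leaf_path, cells_path, mer_path,
                                   out_dir = ".",
                                   n_LER_for_mean = 2,
                                   interval_in_cm = 0.1,
                                   bw_multiplier = 1,
                                   alternative_bw = 0.5,
                                   mature_fraction = 0.95,
                                   integration_rule = "trapezoid",
                                   derivative = "central",
                                   time_weighted = FALSE,
                                   report = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character()
  run <- function(expr) withCallingHandlers(expr, warning = function(w) {
    log_lines <<- c(log_lines, paste("WARNING:", conditionMessage(w)))
    invokeRestart("muffleWarning")
  })

  leaf <- read_leaf_lengths(leaf_path)
  cells <- read_cell_lengths(cells_path)
  mer <- read_meristem_sizes(mer_path)
  validation <- run(validate_inputs(leaf, cells, mer))
  if (!validation$ok)
    log_lines <- c(log_lines, paste0("FINDING: ", validation$findings$plant_id,
                                     ": ", validation$findings$issue))

  ler_means <- run(calculate_ler(leaf, n_LER_for_mean,
                                 time_weighted = time_weighted))
  lers <- run(calculate_ler(leaf, n_LER_for_mean, output = "tidy_LER"))
  fit <- run(fit_cell_profiles(cells, interval_in_cm, bw_multiplier,
                               alternative_bw, derivative))
  tidy_fit <- fitted(fit)
  config <- kinematic_config(mature_fraction, integration_rule)
  kin <- run(kinematic_analysis(ler_means, tidy_fit, mer, config))

  paths <- c(ler_means = file.path(out_dir, "ler_means.txt"),
             interval_lers = file.path(out_dir, "interval_lers.txt"),
             bandwidths = file.path(out_dir, "bandwidths.txt"),
             fitted_cell_lengths = file.path(out_dir,
                                             "fitted_cell_lengths.txt"),
             kinematics = file.path(out_dir, "kinematics.txt"),
             log = file.path(out_dir, "run.log"),
             metadata = file.path(out_dir, "metadata.json"))
  fm <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], format_table_num)
    df
  }
  lers_out <- lers
  lers_out$t_start <- format_timestamp(lers_out$t_start)
  lers_out$t_end <- format_timestamp(lers_out$t_end)
  write_tab_delim(fm(ler_means), paths["ler_means"])
  write_tab_delim(fm(lers_out), paths["interval_lers"])
  write_tab_delim(fm(fit$bandwidths), paths["bandwidths"])
  write_tab_delim(fm(tidy_fit), paths["fitted_cell_lengths"])
  write_tab_delim(fm(kin), paths["kinematics"])
  if (report)
    paths["report"] <- run(render_fit_report(fit, out_dir))
  writeLines(log_lines, paths["log"])
  meta <- list(
    package = "growkin",
    version = as.character(utils::packageVersion("growkin")),
    config = list(n_LER_for_mean = n_LER_for_mean,
                  interval_in_cm = interval_in_cm,
                  bw_multiplier = bw_multiplier,
                  alternative_bw = alternative_bw,
                  mature_fraction = mature_fraction,
                  integration_rule = integration_rule,
                  derivative = derivative,
                  time_weighted = time_weighted),
    bandwidths = fit$bandwidths,
    failures = attr(kin, "failures"))
  jsonlite::write_json(meta, paths["metadata"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (length(log_lines)) message(paste(log_lines, collapse = "\n"))
  invisible(list(validation = validation, ler_means = ler_means, fit = fit,
                 kinematics = kin, paths = paths))
}
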