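#' Leaf length table
#'
#' Container for per-plant leaf length time series. Rows are plants, columns
#' are timestamped measurements (in mm); missing entries are allowed and are
#' handled downstream by the elongation-rate calculation.
#'
#' @param plant_id character vector of unique plant labels.
#' @param timepoints `POSIXct` vector of measurement times (minute
#'   resolution, timezone-naive).
#' @param lengths numeric matrix of leaf lengths in mm, one row per plant and
#'   one column per timepoint; `NA` marks a missing measurement.
#' @return An object of class `leaf_length_table` with components `plant_id`,
#'   `timepoints` (sorted increasing) and `lengths` (columns reordered to
#'   match).
#' @export
leaf_length_table <- function(plant_id, timepoints, lengths) {
  plant_id <- as.character(plant_id)
  if (anyDuplicated(plant_id))
    stop("duplicate plant_id: ",
         paste(unique(plant_id[duplicated(plant_id)]), collapse = ", "),
         call. = FALSE)
  lengths <- as.matrix(lengths)
  stopifnot(length(timepoints) == ncol(lengths),
            length(plant_id) == nrow(lengths))
  if (anyDuplicated(as.numeric(timepoints)))
    stop("duplicated measurement timestamps", call. = FALSE)
  ord <- order(timepoints)
  timepoints <- timepoints[ord]
  lengths <- lengths[, ord, drop = FALSE]
  if (any(lengths < 0, na.rm = TRUE))
    stop("negative leaf length", call. = FALSE)
  dimnames(lengths) <- list(plant_id, format_timestamp(timepoints))
  # Shrinking measurements are physically impossible but legal input
  # (measurement noise); report, do not reject.
  dec <- apply(lengths, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) > 1L && any(diff(r) < 0)
  })
  if (any(dec))
    warning("leaf length decreases over time for plant(s): ",
            paste(plant_id[dec], collapse = ", "), call. = FALSE)
  structure(list(plant_id = plant_id, timepoints = timepoints,
                 lengths = lengths),
            class = "leaf_length_table")
}

#' @export
print.leaf_length_table <- function(x, ...) {
  cat(sprintf("Leaf length table: %d plant(s), %d timepoint(s) (%s .. %s)\n",
              length(x$plant_id), length(x$timepoints),
              format_timestamp(x$timepoints[1]),
              format_timestamp(x$timepoints[length(x$timepoints)])))
  cat(sprintf("missing measurements: %d\n", sum(is.na(x$lengths))))
  invisible(x)
}

#' Read leaf length measurements
#'
#' Reads the tab-delimited leaf length file: a `plant_id` column followed by
#' one column per measurement time, with headers in `yyyy/mm/dd hh:mm` or
#' `yyyy/mm/dd hh:mm:ss` format and leaf lengths in mm. Columns supplied out
#' of chronological order are sorted internally; empty cells and the tokens
#' `NA`/`na`/`NaN` are read as missing.
#'
#' @param path path to a tab-delimited text file.
#' @return A [leaf_length_table()].
#' @seealso [read_cell_lengths()], [read_meristem_sizes()],
#'   [validate_inputs()]
#' @export
read_leaf_lengths <- function(path) {
  df <- read_tab_delim(path)
  if (names(df)[1] != "plant_id")
    stop(sprintf("first column header must be 'plant_id', found '%s'",
                 names(df)[1]), call. = FALSE)
  if (ncol(df) < 2L)
    stop("no measurement columns found", call. = FALSE)
  heads <- names(df)[-1]
  tp <- parse_timestamp(heads)
  if (anyNA(tp))
    stop(sprintf(paste0("cannot parse column header '%s' as a date-time; ",
                        "expected 'yyyy/mm/dd hh:mm' or 'yyyy/mm/dd hh:mm:ss'"),
                 heads[which(is.na(tp))[1]]), call. = FALSE)
  lengths <- vapply(seq_along(heads), function(j)
    parse_numeric_cells(df[[j + 1L]], sprintf("column '%s'", heads[j])),
    numeric(nrow(df)))
  if (nrow(df) == 1L) lengths <- matrix(lengths, nrow = 1L)
  leaf_length_table(df$plant_id, tp, lengths)
}

read_three_column <- function(path, expected) {
  df <- read_tab_delim(path)
  if (!identical(names(df), expected))
    stop(sprintf("column headers must be exactly {%s}, found {%s}",
                 paste(expected, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  df
}

#' Read cell length measurements
#'
#' Reads the tab-delimited cell length file with columns exactly
#' `plant_id`, `position` (cm from the leaf base) and `cell_length` (um).
#' Several cells may be measured at the same position of the same plant;
#' duplicate rows are retained and row order is preserved.
#'
#' @param path path to a tab-delimited text file.
#' @return A `data.frame` (class `cell_length_table`) with columns
#'   `plant_id`, `position`, `cell_length`.
#' @export
read_cell_lengths <- function(path) {
  df <- read_three_column(path, c("plant_id", "position", "cell_length"))
  out <- data.frame(plant_id = as.character(df$plant_id),
                    position = parse_numeric_cells(df$position, "'position'"),
                    cell_length = parse_numeric_cells(df$cell_length,
                                                      "'cell_length'"),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$position) | out$position < 0)
  if (length(bad))
    stop("missing or negative position (row ", bad[1], ")", call. = FALSE)
  bad <- which(is.na(out$cell_length) | out$cell_length <= 0)
  if (length(bad))
    stop("missing or non-positive cell_length (row ", bad[1], ")",
         call. = FALSE)
  class(out) <- c("cell_length_table", "data.frame")
  out
}

#' Read meristem size measurements
#'
#' Reads the tab-delimited meristem file with columns exactly `plant_id` and
#' `mer_length_um` (meristem length in um, one row per plant).
#'
#' @param path path to a tab-delimited text file.
#' @return A `data.frame` with columns `plant_id` and `mer_length_um`.
#' @export
read_meristem_sizes <- function(path) {
  df <- read_three_column(path, c("plant_id", "mer_length_um"))
  out <- data.frame(plant_id = as.character(df$plant_id),
                    mer_length_um = parse_numeric_cells(df$mer_length_um,
                                                        "'mer_length_um'"),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$plant_id))
    stop("duplicate plant_id in meristem table: ",
         paste(unique(out$plant_id[duplicated(out$plant_id)]), collapse = ", "),
         call. = FALSE)
  bad <- which(is.na(out$mer_length_um) | out$mer_length_um <= 0)
  if (length(bad))
    stop("missing or non-positive mer_length_um (row ", bad[1], ")",
         call. = FALSE)
  out
}

#' Cross-check the three input tables
#'
#' Plant IDs must agree across the three files because they are the keys used
#' to combine leaf growth, cell length and meristem measurements. This check
#' reports, without failing, every plant that appears in the cell length data
#' but lacks a leaf-length or meristem entry (these would make the kinematic
#' analysis fail), plus per-plant measurement counts and plants with fewer
#' than two leaf-length measurements (for which no elongation rate exists).
#'
#' @param leaf a [leaf_length_table()].
#' @param cells a cell length table, see [read_cell_lengths()].
#' @param mer a meristem table, see [read_meristem_sizes()].
#' @return An object of class `validation_report` with components `findings`
#'   (data.frame: `plant_id`, `issue`), `counts` (per-plant measurement
#'   counts) and `ok` (`TRUE` iff no findings).
#' @export
validate_inputs <- function(leaf, cells, mer) {
  cp <- unique(cells$plant_id)
  findings <- data.frame(plant_id = character(), issue = character(),
                         stringsAsFactors = FALSE)
  add <- function(ids, issue) {
    if (length(ids))
      findings <<- rbind(findings,
                         data.frame(plant_id = ids, issue = issue,
                                    stringsAsFactors = FALSE))
  }
  add(setdiff(cp, leaf$plant_id), "missing leaf length measurements")
  add(setdiff(cp, mer$plant_id), "missing meristem size")
  n_nonmiss <- apply(leaf$lengths, 1L, function(r) sum(!is.na(r)))
  add(leaf$plant_id[n_nonmiss < 2L],
      "fewer than 2 leaf length measurements: cannot compute any LER")
  counts <- data.frame(
    plant_id = leaf$plant_id,
    n_leaf_measurements = as.integer(n_nonmiss),
    n_cell_measurements = as.integer(
      vapply(leaf$plant_id, function(p) sum(cells$plant_id == p), integer(1))),
    has_meristem = leaf$plant_id %in% mer$plant_id,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(findings = findings, counts = counts,
                 ok = nrow(findings) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) {
    cat("All structural checks passed.\n")
  } else {
    cat("Input validation findings:\n")
    for (i in seq_len(nrow(x$findings)))
      cat(sprintf("  - %s: %s\n", x$findings$plant_id[i], x$findings$issue[i]))
  }
  invisible(x)
}

#' Reshape between tidy and wide layouts
#'
#' `tidy_to_wide()` turns tidy `(plant_id, key, value)` records into a wide
#' table with one row per plant and one column per key; `wide_to_tidy()` is
#' its inverse. Missing combinations become missing cells in the wide form
#' and are dropped again on the way back, so the pair is lossless on the set
#' of observed records.
#'
#' @param records data.frame with three columns: plant id, key, value (names
#'   are kept).
#' @return `tidy_to_wide()`: a data.frame whose first column is the plant id
#'   and remaining columns are the sorted unique keys. `wide_to_tidy()`: a
#'   tidy three-column data.frame.
#' @export
tidy_to_wide <- function(records) {
  stopifnot(is.data.frame(records), ncol(records) == 3L)
  id <- as.character(records[[1L]]); key <- records[[2L]]; val <- records[[3L]]
  pair <- paste(id, as.character(key), sep = "\r")
  if (anyDuplicated(pair)) {
    dup <- pair[duplicated(pair)]
    conflict <- vapply(unique(dup), function(p) {
      v <- val[pair == p]
      any(v != v[1L])
    }, logical(1))
    if (any(conflict))
      stop("conflicting duplicate records for (",
           gsub("\r", ", ", unique(dup)[conflict][1]), ")", call. = FALSE)
    keep <- !duplicated(pair)
    id <- id[keep]; key <- key[keep]; val <- val[keep]
  }
  ids <- unique(id)
  keys <- sort(unique(key))
  m <- matrix(NA_real_, length(ids), length(keys),
              dimnames = list(ids, as.character(keys)))
  m[cbind(match(id, ids), match(key, keys))] <- val
  out <- data.frame(ids, m, check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out) <- c(names(records)[1L], as.character(keys))
  out
}

#' @rdname tidy_to_wide
#' @param wide a wide table as produced by `tidy_to_wide()`.
#' @param names character of length 3: the column names for the tidy output.
#' @export
wide_to_tidy <- function(wide, names = c("plant_id", "key", "value")) {
  stopifnot(is.data.frame(wide), ncol(wide) >= 2L)
  keys <- colnames(wide)[-1L]
  id <- rep(as.character(wide[[1L]]), times = length(keys))
  key <- rep(keys, each = nrow(wide))
  val <- unlist(wide[-1L], use.names = FALSE)
  keynum <- suppressWarnings(as.numeric(key))
  if (!anyNA(keynum)) key <- keynum
  out <- data.frame(id, key, val, stringsAsFactors = FALSE)
  names(out) <- names
  out <- out[!is.na(out[[3L]]), , drop = FALSE]
  ord <- order(match(out[[1L]], as.character(wide[[1L]])), out[[2L]])
  out <- out[ord, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Write the input tables back to tab-delimited text
#'
#' Numeric values are written with 6 significant digits; timestamps with the
#' same `yyyy/mm/dd hh:mm[:ss]` headers accepted by the readers, so a
#' read-write-read round trip reproduces the table.
#'
#' @param x the table to write.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_leaf_lengths <- function(x, path) {
  stopifnot(inherits(x, "leaf_length_table"))
  df <- data.frame(plant_id = x$plant_id, stringsAsFactors = FALSE)
  for (j in seq_along(x$timepoints))
    df[[format_timestamp(x$timepoints[j])]] <- format_table_num(x$lengths[, j])
  write_tab_delim(df, path)
}

#' @rdname write_leaf_lengths
#' @export
write_cell_lengths <- function(x, path) {
  df <- data.frame(plant_id = x$plant_id,
                   position = format_table_num(x$position),
                   cell_length = format_table_num(x$cell_length),
                   stringsAsFactors = FALSE)
  write_tab_delim(df, path)
}

#' @rdname write_leaf_lengths
#' @export
write_meristem_sizes <- function(x, path) {
  df <- data.frame(plant_id = x$plant_id,
                   mer_length_um = format_table_num(x$mer_length_um),
                   stringsAsFactors = FALSE)
  write_tab_delim(df, path)
}
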