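# Internal helpers shared across modules.

# Run `expr` with a private RNG stream seeded by `seed`, restoring any
# pre-existing .Random.seed afterwards so callers' streams are untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Timestamp parsing: minute resolution, optional seconds, timezone-naive
# (represented in UTC so arithmetic is exact minute arithmetic).
parse_timestamp <- function(x) {
  x <- trimws(x)
  out <- as.POSIXct(x, format = "%Y/%m/%d %H:%M:%S", tz = "UTC")
  miss <- is.na(out)
  if (any(miss))
    out[miss] <- as.POSIXct(x[miss], format = "%Y/%m/%d %H:%M", tz = "UTC")
  out
}

format_timestamp <- function(t) {
  has_sec <- any(as.integer(format(t, "%S", tz = "UTC")) != 0L)
  fmt <- if (has_sec) "%Y/%m/%d %H:%M:%S" else "%Y/%m/%d %H:%M"
  format(t, fmt, tz = "UTC")
}

# Numeric parsing for table cells: empty / NA / na / NaN are missing, a comma
# decimal separator is a hard error (frequent Excel-locale export problem).
parse_numeric_cells <- function(x, what) {
  x <- trimws(x)
  missing_tok <- x == "" | x %in% c("NA", "na", "NaN")
  out <- rep(NA_real_, length(x))
  keep <- !missing_tok
  if (any(grepl(",", x[keep], fixed = TRUE)))
    stop(sprintf(paste0(
      "comma found in numeric %s values (e.g. %s); the decimal separator ",
      "must be '.', check the locale used when exporting the file"),
      what, dQuote(x[keep][grepl(",", x[keep], fixed = TRUE)][1])),
      call. = FALSE)
  suppressWarnings(out[keep] <- as.numeric(x[keep]))
  bad <- keep & is.na(out)
  if (any(bad))
    stop(sprintf("non-numeric value %s in %s (row %d)",
                 dQuote(x[bad][1]), what, which(bad)[1]), call. = FALSE)
  out
}

# Read a tab-delimited text file as character, tolerating a UTF-8 BOM.
read_tab_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, fileEncoding = "UTF-8-BOM",
                          blank.lines.skip = FALSE, quote = "")
  names(df)[1] <- sub("^﻿", "", names(df)[1])
  df
}

# 6 significant digits for written tables: exceeds measurement precision
# while keeping file diffs stable.
format_table_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(signif(v, 6), scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

write_tab_delim <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
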