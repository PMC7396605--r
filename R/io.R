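# measurement CSV schema v1 (comma-separated, "." decimal, UTF-8,
# "#"-prefixed comment lines allowed before and after the header)
MEASUREMENT_COLUMNS <- c(
  "series_id", "compound", "cultivation_acceptor", "vial_id", "replicate",
  "f", "delta13C_permil", "delta37Cl_permil", "sd13C_permil",
  "sd37Cl_permil"
)
MEASUREMENT_NUMERIC <- c("f", "delta13C_permil", "delta37Cl_permil",
                         "sd13C_permil", "sd37Cl_permil")
SCHEMA_HEADER <- "# dualcsia measurement schema v1"

#' Read a measurement table
#'
#' Reads the package's CSV measurement schema: one row per individual
#' isotope measurement, columns `series_id, compound,
#' cultivation_acceptor, vial_id, replicate, f, delta13C_permil,
#' delta37Cl_permil, sd13C_permil, sd37Cl_permil`. Empty cells are
#' missing values; unknown columns are preserved but ignored; lines
#' starting with `#` are comments. A missing required column aborts the
#' read (all-or-nothing on header errors); unparseable numeric cells and
#' out-of-range fractions are collected per row with their file line
#' numbers. Rows with `replicate == 0` and `f == 1` are per-series
#' initial-composition references (see [write_measurements()]).
#'
#' @param path CSV file path.
#' @return An object of class `measurement_table`: `data` (typed clean
#'   rows), `row_errors` (data frame with `line`, `column`, `message`),
#'   `row_warnings` (same shape, e.g. f slightly above 1), `path`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  is_comment <- grepl("^\\s*#", lines) | !nzchar(trimws(lines))
  content_idx <- which(!is_comment)
  if (length(content_idx) == 0L) {
    stop("empty file: no header line found", call. = FALSE)
  }
  header_line <- content_idx[1]
  raw <- utils::read.csv(text = paste(lines[content_idx], collapse = "\n"),
                         colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  data_lines <- content_idx[-1]  # file line number of each data row
  errors <- list(); warns <- list()
  note <- function(store, i, column, message) {
    entry <- data.frame(line = data_lines[i], column = column,
                        message = message, stringsAsFactors = FALSE)
    if (store == "error") errors[[length(errors) + 1L]] <<- entry
    else warns[[length(warns) + 1L]] <<- entry
  }
  typed <- raw[MEASUREMENT_COLUMNS]
  bad_row <- rep(FALSE, nrow(raw))
  for (col in c("replicate", MEASUREMENT_NUMERIC)) {
    vals <- trimws(typed[[col]])
    num <- suppressWarnings(as.numeric(vals))
    bad <- nzchar(vals) & is.na(num)
    for (i in which(bad)) {
      note("error", i, col,
           sprintf("unparseable numeric value '%s'", vals[i]))
    }
    bad_row <- bad_row | bad
    typed[[col]] <- num
  }
  ok_f <- !is.na(typed$f)
  out_of_range <- ok_f & (typed$f <= 0 | typed$f >= 1.5)
  for (i in which(out_of_range)) {
    note("error", i, "f",
         sprintf("f = %s outside (0, 1.5)", typed$f[i]))
  }
  bad_row <- bad_row | out_of_range
  above_one <- ok_f & !out_of_range & typed$f > 1
  for (i in which(above_one)) {
    note("warning", i, "f",
         sprintf("f = %s > 1 accepted (measurement noise?)", typed$f[i]))
  }
  no_delta <- is.na(typed$delta13C_permil) & is.na(typed$delta37Cl_permil)
  for (i in which(no_delta)) {
    note("error", i, "delta13C_permil",
         "neither delta13C_permil nor delta37Cl_permil present")
  }
  bad_row <- bad_row | no_delta
  typed$replicate <- as.integer(typed$replicate)
  empty_df <- data.frame(line = integer(), column = character(),
                         message = character(), stringsAsFactors = FALSE)
  structure(list(
    data = typed[!bad_row, , drop = FALSE],
    row_errors = if (length(errors)) do.call(rbind, errors) else empty_df,
    row_warnings = if (length(warns)) do.call(rbind, warns) else empty_df,
    path = path
  ), class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("measurement_table: %d clean rows, %d row errors, %d warnings (%s)\n",
              nrow(x$data), nrow(x$row_errors), nrow(x$row_warnings),
              x$path))
  invisible(x)
}

#' Write experiment series to the measurement CSV schema
#'
#' Serializes one or more [experiment_series] to the schema read back by
#' [read_measurements()]. Each series' initial composition is written as a
#' reference row with `vial_id = "initial"`, `replicate = 0`, `f = 1`.
#' Output is deterministic: fixed column order and a fixed significant-
#' digit float format.
#'
#' @param series an [experiment_series] or a list of them.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_measurements <- function(series, path) {
  if (inherits(series, "experiment_series")) series <- list(series)
  stopifnot(all(vapply(series, inherits, logical(1), "experiment_series")))
  # 17 significant digits: lossless round-trip for doubles
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, format = "g",
                                                  digits = 17))
  rows <- lapply(series, function(s) {
    m <- s$measurements
    ref <- data.frame(
      series_id = s$series_id, compound = s$compound,
      cultivation_acceptor = s$cultivation_acceptor,
      vial_id = "initial", replicate = "0", f = "1",
      delta13C_permil = fmt(s$delta0_c),
      delta37Cl_permil = fmt(s$delta0_cl),
      sd13C_permil = "0", sd37Cl_permil = "0",
      stringsAsFactors = FALSE
    )
    dat <- data.frame(
      series_id = s$series_id, compound = s$compound,
      cultivation_acceptor = s$cultivation_acceptor,
      vial_id = m$vial_id, replicate = as.character(m$replicate),
      f = fmt(m$f),
      delta13C_permil = fmt(m$delta_c),
      delta37Cl_permil = fmt(m$delta_cl),
      sd13C_permil = fmt(m$sd_c),
      sd37Cl_permil = fmt(m$sd_cl),
      stringsAsFactors = FALSE
    )
    rbind(ref, dat)
  })
  tab <- do.call(rbind, rows)
  con <- file(path, open = "wb")  # binary mode: byte-stable line endings
  on.exit(close(con))
  writeLines(SCHEMA_HEADER, con)
  writeLines(paste(MEASUREMENT_COLUMNS, collapse = ","), con)
  body <- apply(tab, 1L, function(r) {
    r <- ifelse(grepl("[,\"]", r), sprintf("\"%s\"", gsub("\"", "\"\"", r)),
                r)
    paste(r, collapse = ",")
  })
  writeLines(body, con)
  invisible(path)
}

#' Split a measurement table into experiment series
#'
#' Groups the clean rows of a [read_measurements()] result by `series_id`.
#' Reference rows (`replicate == 0`, `f == 1`) become the series' initial
#' composition (averaged if several); remaining rows become measurements.
#'
#' @param table a `measurement_table`.
#' @return A named list of [experiment_series].
#' @export
as_experiment_series <- function(table) {
  stopifnot(inherits(table, "measurement_table"))
  d <- table$data
  if (nrow(d) == 0L) return(list())
  out <- lapply(split(d, d$series_id), function(g) {
    is_ref <- g$replicate == 0 & g$f == 1
    ref <- g[is_ref, , drop = FALSE]
    dat <- g[!is_ref, , drop = FALSE]
    d0c <- if (any(!is.na(ref$delta13C_permil))) {
      mean(ref$delta13C_permil, na.rm = TRUE)
    } else NULL
    d0cl <- if (any(!is.na(ref$delta37Cl_permil))) {
      mean(ref$delta37Cl_permil, na.rm = TRUE)
    } else NULL
    experiment_series(
      compound = dat$compound[1],
      cultivation_acceptor = dat$cultivation_acceptor[1],
      f = dat$f,
      delta_c = dat$delta13C_permil,
      delta_cl = dat$delta37Cl_permil,
      sd_c = dat$sd13C_permil,
      sd_cl = dat$sd37Cl_permil,
      vial_id = dat$vial_id,
      replicate = dat$replicate,
      delta0_c = d0c,
      delta0_cl = d0cl,
      series_id = dat$series_id[1]
    )
  })
  out
}
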