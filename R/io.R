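#' Read a time series from delimited text
#'
#' Accepts CSV, TSV or whitespace-delimited files with either a single value
#' column or a time column followed by a value column. Lines starting with
#' `#` and blank lines are ignored; a single non-numeric leading row is
#' treated as a header. When a time column is present, the sampling interval
#' is inferred and the grid is required to be uniform (within a relative
#' tolerance of 1e-6); otherwise `dt` must be supplied.
#'
#' @param path File to read.
#' @param dt Sampling interval (ns); required for single-column files,
#'   cross-checked against the time column otherwise.
#' @param time_col,value_col Optional 1-based column indices; defaults are
#'   column 1 = time and column 2 = value for multi-column files, column 1 =
#'   value for single-column files.
#' @return A [sim_series()].
#' @export
read_series <- function(path, dt = NULL, time_col = NULL, value_col = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no data rows in ", path)

  sep <- if (grepl(",", lines[1L])) "," else ""
  split_row <- function(s) {
    if (sep == ",") trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
    else strsplit(trimws(s), "\\s+")[[1L]]
  }
  rows <- lapply(lines, split_row)

  numeric_row <- function(r) {
    suppressWarnings(vals <- as.numeric(r))
    if (anyNA(vals)) NULL else vals
  }
  first <- numeric_row(rows[[1L]])
  if (is.null(first)) { # header row
    rows <- rows[-1L]
    lineno <- lineno[-1L]
    if (!length(rows)) stop("no data rows after header in ", path)
  }

  ncols <- length(rows[[1L]])
  parsed <- matrix(NA_real_, length(rows), ncols)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != ncols) {
      stop("line ", lineno[i], ": expected ", ncols, " fields, got ",
           length(rows[[i]]))
    }
    vals <- numeric_row(rows[[i]])
    if (is.null(vals)) stop("line ", lineno[i], ": non-numeric value")
    if (any(!is.finite(vals))) stop("line ", lineno[i], ": non-finite value")
    parsed[i, ] <- vals
  }
  if (nrow(parsed) < 2L) stop("need at least 2 data rows, got ", nrow(parsed))

  if (ncols == 1L) {
    if (!is.null(time_col)) stop("time_col given but file has one column")
    if (is.null(dt)) {
      stop("single-column input: supply dt (the sampling interval)")
    }
    return(sim_series(parsed[, if (is.null(value_col)) 1L else value_col],
                      dt = dt))
  }

  tc <- if (is.null(time_col)) 1L else time_col
  vc <- if (is.null(value_col)) 2L else value_col
  times <- parsed[, tc]
  d <- diff(times)
  dt_inferred <- stats::median(d)
  if (dt_inferred <= 0 || any(abs(d - dt_inferred) > 1e-6 * dt_inferred)) {
    stop("time column is not a uniform increasing grid")
  }
  if (!is.null(dt) && abs(dt - dt_inferred) > 1e-6 * dt_inferred) {
    stop("supplied dt (", dt, ") disagrees with the time column (",
         dt_inferred, ")")
  }
  sim_series(parsed[, vc], dt = dt_inferred, t0 = times[1L])
}

#' Write a time series as delimited text
#'
#' Writes a two-column (time, value) file at full double precision, so a
#' [read_series()] round trip reproduces the values exactly.
#'
#' @param series A [sim_series()].
#' @param path Output file; `.csv` extension selects comma separation,
#'   anything else tab.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("time", sep, "value"), con)
  writeLines(
    paste0(sprintf("%.17g", series_times(series)), sep,
           sprintf("%.17g", series$values)),
    con
  )
  invisible(path)
}

#' Serialize an ensemble to a directory
#'
#' Writes one delimited-text file per series plus a `manifest.json`
#' recording the generating model parameters, seed, sampling interval and
#' variant provenance.
#'
#' @param ens A `synthetic_ensemble`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ens, dir) {
  stopifnot(inherits(ens, "synthetic_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ns <- n_series(ens)
  files <- sprintf("series_%04d.csv", seq_len(ns))
  for (j in seq_len(ns)) {
    write_series(ensemble_series(ens, j), file.path(dir, files[j]))
  }
  manifest <- list(
    package = "truncsel",
    version = as.character(utils::packageVersion("truncsel")),
    n_series = ns,
    n_points = nrow(ens$values),
    dt = ens$dt,
    t0 = ens$t0,
    true_mean = ens$true_mean,
    seed = ens$seed,
    variant = ens$variant,
    variant_params = ens$variant_params,
    transient = unclass(ens$transient),
    acv = list(dt = ens$acv$dt, max_lag_index = ens$acv$max_lag_index,
               total_var_mean = ens$acv$total_var_mean,
               gamma = ens$acv$gamma),
    files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an ensemble written by [write_ensemble()]
#'
#' @param dir Directory containing `manifest.json` and the series files.
#' @return A `synthetic_ensemble`.
#' @export
read_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  values <- vapply(
    manifest$files,
    function(f) read_series(file.path(dir, f))$values,
    numeric(manifest$n_points)
  )
  dim(values) <- c(manifest$n_points, manifest$n_series)
  tr <- manifest$transient
  # JSON cannot carry Inf natively; accept null or the string "Inf"
  fix_inf <- function(x) {
    if (is.null(x)) return(Inf)
    x <- suppressWarnings(as.numeric(x))
    if (is.na(x)) Inf else x
  }
  structure(
    list(
      values = values, dt = manifest$dt, t0 = manifest$t0,
      true_mean = manifest$true_mean,
      transient = transient_model(tr$a_slow, fix_inf(tr$hl_slow),
                                  tr$a_fast, fix_inf(tr$hl_fast)),
      acv = autocov_model(manifest$acv$gamma, manifest$acv$dt),
      seed = manifest$seed,
      variant = manifest$variant,
      variant_params = as.list(manifest$variant_params)
    ),
    class = "synthetic_ensemble"
  )
}
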