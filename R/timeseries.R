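# Uniformly sampled scalar time series and delimited-text I/O.

#' Construct a uniformly sampled time series
#'
#' A `ts_series` holds one scalar observable sampled on a uniform time grid.
#' Units of the values are context dependent (nm for separation coordinates,
#' rad for angles, dimensionless for unit-vector scalar products); times are
#' always in picoseconds.
#'
#' @param values Numeric vector of observations, one per frame; all finite,
#'   length at least 2.
#' @param dt Sampling interval in ps; must be positive.
#' @param label Free-text label carried through downstream analyses.
#' @return An object of class `ts_series`.
#' @export
ts_series <- function(values, dt, label = "") {
  values <- as.numeric(values)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number (ps)")
  if (length(values) < 2L)
    stop("a time series needs at least 2 frames")
  if (!all(is.finite(values)))
    stop("non-finite value at frame ", which(!is.finite(values))[1L])
  structure(list(values = values, dt = dt, label = as.character(label)[1L]),
            class = "ts_series")
}

#' @export
print.ts_series <- function(x, ...) {
  cat(sprintf("<ts_series> '%s': %d frames, dt = %g ps, span %g ps\n",
              x$label, length(x$values), x$dt, (length(x$values) - 1L) * x$dt))
  invisible(x)
}

#' @export
length.ts_series <- function(x) length(x$values)

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
}

#' Read time series from delimited text
#'
#' Expects one header line; the first column is time in ps on a strictly
#' increasing, uniform grid. TSV/whitespace or CSV is auto-detected from the
#' file extension. Each remaining (or selected) column becomes one
#' [ts_series()] with `dt` inferred from the time column.
#'
#' @param path Path to the file.
#' @param columns Optional column selection (names or integer indices of the
#'   value columns, excluding the time column). Default: all value columns.
#' @param rel_tol Relative tolerance on time-step uniformity.
#' @return Named list of `ts_series`.
#' @export
read_timeseries <- function(path, columns = NULL, rel_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("need a time column plus at least one value column")
  tvec <- df[[1L]]
  if (!is.numeric(tvec)) stop("time column is not numeric")
  if (nrow(df) < 2L) stop("need at least 2 rows")
  dts <- diff(tvec)
  if (any(dts <= 0))
    stop("time column not strictly increasing at row ",
         which(dts <= 0)[1L] + 1L)
  dt <- stats::median(dts)
  bad <- which(abs(dts - dt) > rel_tol * dt)
  if (length(bad))
    stop("non-uniform time grid: gap at row ", bad[1L] + 1L,
         " (step ", format(dts[bad[1L]]), " vs ", format(dt), " ps)")
  vals <- df[-1L]
  if (!is.null(columns)) vals <- vals[columns]
  out <- lapply(seq_along(vals), function(i) {
    v <- vals[[i]]
    if (!is.numeric(v))
      stop("non-numeric cell in column '", names(vals)[i], "', row ",
           which(is.na(suppressWarnings(as.numeric(v))))[1L] + 1L)
    if (anyNA(v)) stop("missing value in column '", names(vals)[i],
                       "', row ", which(is.na(v))[1L] + 1L)
    ts_series(v, dt, names(vals)[i])
  })
  names(out) <- names(vals)
  out
}

#' Write time series to delimited text
#'
#' Inverse of [read_timeseries()]: writes a header line, a `time_ps` column
#' and one column per series. All series must share `dt` and length. Values
#' are written with full double precision so a write/read round trip is
#' bit-exact.
#'
#' @param series A `ts_series` or (named) list of them.
#' @param path Output path; `.csv` selects comma separation, anything else tab.
#' @export
write_timeseries <- function(series, path) {
  if (inherits(series, "ts_series")) series <- list(series)
  dts <- vapply(series, `[[`, numeric(1), "dt")
  lens <- vapply(series, function(s) length(s$values), integer(1))
  if (length(unique(dts)) != 1L || length(unique(lens)) != 1L)
    stop("all series must share dt and length")
  nm <- names(series)
  if (is.null(nm) || any(nm == ""))
    nm <- vapply(seq_along(series), function(i) {
      l <- series[[i]]$label
      if (nzchar(l)) l else paste0("V", i)
    }, character(1))
  df <- data.frame(time_ps = (seq_len(lens[1L]) - 1L) * dts[1L])
  for (i in seq_along(series)) df[[nm[i]]] <- series[[i]]$values
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a time series into contiguous blocks
#'
#' Used for block-averaged error estimates: the series is cut into
#' `n_blocks` contiguous, non-overlapping, equal-length segments; remainder
#' frames are dropped from the end so the blocks stay statistically
#' equivalent.
#'
#' @param series A [ts_series()].
#' @param n_blocks Number of blocks, at least 2.
#' @return List of `ts_series` of equal length.
#' @export
block_split <- function(series, n_blocks) {
  stopifnot(inherits(series, "ts_series"))
  if (!is.numeric(n_blocks) || length(n_blocks) != 1L || n_blocks < 2L)
    stop("`n_blocks` must be a single integer >= 2")
  n_blocks <- as.integer(n_blocks)
  L <- length(series$values)
  bl <- L %/% n_blocks
  if (bl < 2L)
    stop("too few frames (", L, ") for ", n_blocks, " blocks")
  lapply(seq_len(n_blocks), function(b) {
    idx <- ((b - 1L) * bl + 1L):(b * bl)
    ts_series(series$values[idx], series$dt,
              paste0(series$label, "#block", b))
  })
}
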