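# Core in-memory model of the sensor network: regular-grid concentration
# series, site metadata, and CSV readers/writers.

.POLLUTANTS <- c("NO", "NO2")
.ZONES <- c("OR", "SR", "OA", "BA")
.TERMINALS <- c("PCT2", "PCT4")
.CADENCE_SEC <- c(minute = 60, hour = 3600)

#' Regular-grid concentration time series
#'
#' A `nox_ts` is a data frame with columns `time` (POSIXct, time-zone-aware
#' local time) and `value` (concentration in ug/m3, `NA` for missing),
#' carrying the site id, pollutant and cadence as attributes. Timestamps
#' must be strictly increasing on a fixed 1-minute or 1-hour grid; hour
#' labels are interval starts (half-open intervals).
#'
#' @param time POSIXct vector (or coercible), strictly increasing, constant
#'   spacing matching `cadence`.
#' @param value numeric concentrations in ug/m3; `NA` marks missing.
#' @param site_id site identifier.
#' @param pollutant `"NO"` or `"NO2"`.
#' @param cadence `"minute"` or `"hour"`.
#' @return an object of class `nox_ts`.
#' @examples
#' t0 <- as.POSIXct("2023-10-21 00:00:00", tz = "Asia/Shanghai")
#' nox_ts(t0 + 60 * (0:9), rlnorm(10, 3), site_id = "s1", pollutant = "NO")
#' @export
nox_ts <- function(time, value, site_id = "site", pollutant = c("NO", "NO2"),
                   cadence = c("minute", "hour")) {
  pollutant <- match.arg(pollutant)
  cadence <- match.arg(cadence)
  time <- as.POSIXct(time)
  value <- as.numeric(value)
  if (length(time) != length(value))
    stop("`time` and `value` must have equal length", call. = FALSE)
  if (length(time) > 1L) {
    d <- diff(as.numeric(time))
    if (any(d <= 0))
      stop("timestamps must be strictly increasing", call. = FALSE)
    if (any(abs(d - .CADENCE_SEC[[cadence]]) > 1e-6))
      stop("timestamps must lie on a regular ", cadence, " grid", call. = FALSE)
  }
  structure(data.frame(time = time, value = value),
            site_id = as.character(site_id), pollutant = pollutant,
            cadence = cadence, class = c("nox_ts", "data.frame"))
}

#' @export
print.nox_ts <- function(x, ...) {
  cat(sprintf("<nox_ts> site %s, %s, %s cadence, %d points (%d missing)\n",
              attr(x, "site_id"), attr(x, "pollutant"), attr(x, "cadence"),
              nrow(x), sum(is.na(x$value))))
  if (nrow(x)) {
    cat(sprintf("  %s .. %s\n", format(x$time[1L]), format(x$time[nrow(x)])))
    v <- x$value[!is.na(x$value)]
    if (length(v))
      cat(sprintf("  value range %.2f .. %.2f ug/m3\n", min(v), max(v)))
  }
  invisible(x)
}

ts_meta <- function(ts) {
  list(site_id = attr(ts, "site_id"), pollutant = attr(ts, "pollutant"),
       cadence = attr(ts, "cadence"))
}

# Full regular grid between two instants (inclusive).
time_grid <- function(from, to, cadence) {
  seq(from, to, by = .CADENCE_SEC[[cadence]])
}

#' Site metadata table
#'
#' Builds and validates a site-metadata table: one row per sensor node with
#' its functional zone (outer ring `OR`, surrounding roads `SR`,
#' operational area `OA`, berthing area `BA`), terminal, and whether it is
#' colocated with a reference air-quality monitoring station.
#'
#' @param site_id unique site identifiers.
#' @param zone functional zone, one of `"OR"`, `"SR"`, `"OA"`, `"BA"`.
#' @param terminal `"PCT2"` or `"PCT4"`.
#' @param colocated logical; `TRUE` for reference-paired sites.
#' @return data frame of class `site_meta`.
#' @export
site_meta <- function(site_id, zone, terminal, colocated = FALSE) {
  site_id <- as.character(site_id)
  if (anyDuplicated(site_id))
    stop("site_id must be unique within a network", call. = FALSE)
  zone <- as.character(zone)
  terminal <- as.character(terminal)
  if (!all(zone %in% .ZONES))
    stop("zone must be one of ", paste(.ZONES, collapse = ", "), call. = FALSE)
  if (!all(terminal %in% .TERMINALS))
    stop("terminal must be one of ", paste(.TERMINALS, collapse = ", "),
         call. = FALSE)
  structure(data.frame(site_id = site_id, zone = zone, terminal = terminal,
                       colocated = rep_len(as.logical(colocated),
                                           length(site_id))),
            class = c("site_meta", "data.frame"))
}

parse_iso_times <- function(x, tz) {
  x <- as.character(x)
  out <- as.POSIXct(x, tz = tz, format = "%Y-%m-%dT%H:%M:%S")
  plain <- is.na(out)
  if (any(plain))  # fall back to "YYYY-mm-dd HH:MM:SS"
    out[plain] <- as.POSIXct(x[plain], tz = tz,
                             format = "%Y-%m-%d %H:%M:%S")
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("malformed timestamp '%s' at data row %d", x[bad], bad),
         call. = FALSE)
  }
  out
}

#' Read a long-format time-series CSV into `nox_ts` objects
#'
#' Expects columns `timestamp` (ISO-8601), `site_id`, `pollutant` and
#' `value_ugm3` (empty field = missing). One `nox_ts` is returned per
#' (site, pollutant) pair; gaps in the regular grid are filled with missing
#' markers so every returned series is complete between its first and last
#' observation.
#'
#' @param path CSV file path.
#' @param tz IANA time zone for timestamp interpretation (diurnal and
#'   8-hour-window computations are defined in local time).
#' @param cadence grid cadence of the file, `"minute"` or `"hour"`.
#' @param schema named character vector mapping the canonical column names
#'   (`timestamp`, `site_id`, `pollutant`, `value`) to the file's columns.
#' @return named list of `nox_ts` (`"<site>.<pollutant>"`).
#' @export
read_timeseries_csv <- function(path, tz = "Asia/Shanghai",
                                cadence = c("minute", "hour"),
                                schema = c(timestamp = "timestamp",
                                           site_id = "site_id",
                                           pollutant = "pollutant",
                                           value = "value_ugm3")) {
  cadence <- match.arg(cadence)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- unname(schema[c("timestamp", "site_id", "pollutant", "value")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  tstamp <- parse_iso_times(raw[[schema[["timestamp"]]]], tz)
  key <- paste(raw[[schema[["site_id"]]]], raw[[schema[["pollutant"]]]],
               format(tstamp, "%Y%m%d%H%M%S"))
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1L]
    stop(sprintf("duplicate (site, pollutant, timestamp) at data row %d", bad),
         call. = FALSE)
  }
  groups <- split(seq_len(nrow(raw)),
                  paste(raw[[schema[["site_id"]]]],
                        raw[[schema[["pollutant"]]]], sep = "."))
  out <- lapply(groups, function(idx) {
    tt <- tstamp[idx]
    o <- order(tt)
    idx <- idx[o]; tt <- tt[o]
    grid <- time_grid(tt[1L], tt[length(tt)], cadence)
    v <- rep(NA_real_, length(grid))
    pos <- match(as.numeric(tt), as.numeric(grid))
    if (anyNA(pos))
      stop("timestamps do not lie on a regular ", cadence, " grid for group ",
           raw[[schema[["site_id"]]]][idx[1L]], call. = FALSE)
    v[pos] <- as.numeric(raw[[schema[["value"]]]][idx])
    nox_ts(grid, v, site_id = raw[[schema[["site_id"]]]][idx[1L]],
           pollutant = raw[[schema[["pollutant"]]]][idx[1L]],
           cadence = cadence)
  })
  out
}

#' Read a site-metadata CSV
#'
#' Columns: `site_id`, `zone`, `terminal`, `colocated`.
#'
#' @param path CSV file path.
#' @return data frame of class `site_meta`.
#' @export
read_sitemeta_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  site_meta(raw$site_id, raw$zone, raw$terminal, as.logical(raw$colocated))
}

#' Aggregate a minute-cadence series to hourly means
#'
#' Each hour (half-open `[t, t+1h)`, labelled by its start) becomes the
#' arithmetic mean of its non-missing minutes; an hour with fewer valid
#' minutes than `completeness * 60` is marked missing. The default 0.75
#' completeness follows common regulatory practice for hourly averages.
#'
#' @param ts minute-cadence `nox_ts`.
#' @param completeness required fraction of valid minutes in `(0, 1]`.
#' @return hour-cadence `nox_ts`.
#' @export
hourly_aggregate <- function(ts, completeness = 0.75) {
  stopifnot(inherits(ts, "nox_ts"))
  if (attr(ts, "cadence") != "minute")
    stop("hourly_aggregate() expects a minute-cadence series", call. = FALSE)
  if (!(completeness > 0 && completeness <= 1))
    stop("completeness must be in (0, 1]", call. = FALSE)
  m <- ts_meta(ts)
  if (nrow(ts) == 0L)
    return(nox_ts(ts$time, numeric(0), m$site_id, m$pollutant, "hour"))
  hour <- trunc(ts$time, units = "hours")
  grid <- time_grid(hour[1L], hour[length(hour)], "hour")
  f <- match(as.numeric(hour), as.numeric(grid))
  n_ok <- tapply(!is.na(ts$value), f, sum)
  mean_ok <- tapply(ts$value, f, function(v) mean(v, na.rm = TRUE))
  v <- rep(NA_real_, length(grid))
  idx <- as.integer(names(n_ok))
  keep <- n_ok >= completeness * 60
  v[idx[keep]] <- mean_ok[keep]
  v[!is.finite(v)] <- NA_real_
  nox_ts(grid, v, m$site_id, m$pollutant, "hour")
}

#' Write and read result tables
#'
#' `write_results_csv()` writes a baseline decomposition (the per-timestamp
#' total/baseline/local table) or any plain results data frame to CSV with
#' full double precision, so a write/read round trip reproduces values to
#' well within 6 significant digits. `read_results_csv()` reads it back,
#' re-parsing the `time` column when present.
#'
#' @param x a `nox_decomp` or a data frame.
#' @param path output CSV path.
#' @param tz time zone used when re-parsing timestamps.
#' @return `write_results_csv()` returns `path` invisibly;
#'   `read_results_csv()` returns a data frame.
#' @export
write_results_csv <- function(x, path) {
  if (inherits(x, "nox_decomp")) x <- x$data
  if (!is.data.frame(x)) stop("x must be a data frame", call. = FALSE)
  df <- x
  for (cl in names(df))
    if (inherits(df[[cl]], "POSIXct"))
      df[[cl]] <- format(df[[cl]], "%Y-%m-%dT%H:%M:%S")
  ok <- tryCatch({
    suppressWarnings(utils::write.csv(df, path, row.names = FALSE,
                                      quote = FALSE, na = ""))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write results to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path, tz = "Asia/Shanghai") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("time" %in% names(df)) df$time <- parse_iso_times(df$time, tz)
  df
}
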