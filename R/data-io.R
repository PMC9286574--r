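#' Construct one bat-day of skin-temperature telemetry
#'
#' @param bat_id identifier.
#' @param date ISO date (one bat-day per trace).
#' @param t minutes since midnight, strictly increasing at constant spacing.
#' @param skin_temp skin temperature, degC, finite, within [0, 45].
#' @param body_mass body mass at capture, g.
#' @param ambient optional ambient temperature series aligned with `t`.
#' @return an object of class `skin_trace` with fields `bat_id`, `date`,
#'   `t`, `skin_temp`, `body_mass`, `ambient`, the inferred sampling
#'   interval `dt`, and `has_gaps` (TRUE when spacing exceeds `dt` anywhere).
#' @export
skin_trace <- function(bat_id, date, t, skin_temp, body_mass, ambient = NULL) {
  if (length(t) < 2L) stop_fmt("skin trace %s/%s: need >= 2 samples", bat_id, date)
  if (length(t) != length(skin_temp)) stop_fmt("t and skin_temp lengths differ")
  d <- diff(t)
  if (any(d <= 0)) {
    stop_fmt("non-monotone timestamps in skin trace for bat '%s' on %s", bat_id, date)
  }
  if (any(!is.finite(skin_temp)) || any(skin_temp < 0) || any(skin_temp > 45)) {
    stop_fmt("skin trace %s/%s: skin_temp must be finite and within [0, 45] degC",
             bat_id, date)
  }
  if (!is.null(ambient) && length(ambient) != length(t)) {
    stop_fmt("ambient series must align with t")
  }
  dt <- min(d)
  structure(
    list(bat_id = as.character(bat_id), date = as.character(date),
         t = as.numeric(t), skin_temp = as.numeric(skin_temp),
         body_mass = as.numeric(body_mass), ambient = ambient,
         dt = dt, has_gaps = any(d > dt + 1e-9)),
    class = "skin_trace")
}

#' @export
print.skin_trace <- function(x, ...) {
  cat(sprintf("<skin_trace> bat %s on %s: %d samples @ %g min, %.1f-%.1f degC%s\n",
              x$bat_id, x$date, length(x$t), x$dt,
              min(x$skin_temp), max(x$skin_temp),
              if (x$has_gaps) " [gaps]" else ""))
  invisible(x)
}

#' Construct a roost temperature-logger trace
#'
#' @param roost_id identifier (one trace per roost).
#' @param substrate `"rock"` or `"tree"`.
#' @param status `"used"` or `"available"`.
#' @param date ISO date per sample.
#' @param t minutes since midnight per sample.
#' @param temp logged temperature, degC.
#' @return an object of class `microhabitat_trace`.
#' @export
microhabitat_trace <- function(roost_id, substrate, status, date, t, temp) {
  substrate <- as.character(substrate)[1]
  status <- as.character(status)[1]
  if (!substrate %in% c("rock", "tree")) {
    stop_fmt("roost '%s': unknown substrate '%s' (expected rock|tree)", roost_id, substrate)
  }
  if (!status %in% c("used", "available")) {
    stop_fmt("roost '%s': unknown status '%s' (expected used|available)", roost_id, status)
  }
  if (length(t) != length(temp) || length(t) != length(date)) {
    stop_fmt("roost '%s': date, t and temp must align", roost_id)
  }
  abs_t <- as.numeric(as.Date(date)) * 1440 + as.numeric(t)
  if (any(diff(abs_t) <= 0)) stop_fmt("roost '%s': timestamps must be increasing", roost_id)
  structure(
    list(roost_id = as.character(roost_id), substrate = substrate, status = status,
         date = as.character(date), t = as.numeric(t), temp = as.numeric(temp)),
    class = "microhabitat_trace")
}

#' @export
print.microhabitat_trace <- function(x, ...) {
  cat(sprintf("<microhabitat_trace> roost %s (%s, %s): %d samples over %d day(s)\n",
              x$roost_id, x$substrate, x$status, length(x$t),
              length(unique(x$date))))
  invisible(x)
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_fmt("file '%s' lacks required column(s): %s", path,
             paste(missing, collapse = ", "))
  }
}

#' Read and write skin-temperature telemetry tables
#'
#' The interchange format is a comma-separated file with a header row and
#' columns `bat_id`, `date` (ISO), `time` (minutes since midnight),
#' `skin_temp_c`, `body_mass_g`, plus an optional `ambient_c`. One
#' [skin_trace()] is produced per bat-day; every input row ends up in
#' exactly one trace (nothing is silently dropped).
#'
#' @param path file path.
#' @param traces list of `skin_trace` objects.
#' @return `read_skin_traces()` returns a list of `skin_trace`;
#'   `write_skin_traces()` returns `path` invisibly.
#' @export
read_skin_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("bat_id", "date", "time", "skin_temp_c", "body_mass_g"), path)
  if (nrow(df) == 0L) {
    warn_fmt("'%s' contains no data rows", path)
    return(list())
  }
  key <- paste(df$bat_id, df$date, sep = "/")
  traces <- lapply(split(df, factor(key, levels = unique(key))), function(g) {
    skin_trace(g$bat_id[1], g$date[1], g$time, g$skin_temp_c, g$body_mass_g[1],
               ambient = if ("ambient_c" %in% names(g)) g$ambient_c else NULL)
  })
  n_out <- sum(vapply(traces, function(tr) length(tr$t), integer(1)))
  stopifnot(n_out == nrow(df))
  unname(traces)
}

#' @rdname read_skin_traces
#' @export
write_skin_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    out <- data.frame(bat_id = tr$bat_id, date = tr$date, time = tr$t,
                      skin_temp_c = tr$skin_temp, body_mass_g = tr$body_mass)
    if (!is.null(tr$ambient)) out$ambient_c <- tr$ambient
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write roost temperature-logger tables
#'
#' Comma-separated with header: `roost_id`, `substrate` (rock|tree),
#' `status` (used|available), `timestamp` (`"YYYY-MM-DD HH:MM"`, local clock
#' time), `temp_c`. One [microhabitat_trace()] per roost; substrate and
#' status are validated against their two-level vocabularies. An empty file
#' yields an empty collection with a warning.
#'
#' @param path file path.
#' @param traces list of `microhabitat_trace` objects.
#' @return `read_logger_traces()` returns a list of `microhabitat_trace`.
#' @export
read_logger_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("roost_id", "substrate", "status", "timestamp", "temp_c"), path)
  if (nrow(df) == 0L) {
    warn_fmt("'%s' contains no data rows", path)
    return(list())
  }
  date <- substr(df$timestamp, 1, 10)
  tmin <- clock_to_minutes(substr(df$timestamp, 12, 16))
  traces <- lapply(split(seq_len(nrow(df)),
                         factor(df$roost_id, levels = unique(df$roost_id))),
                   function(i) {
    microhabitat_trace(df$roost_id[i[1]], df$substrate[i[1]], df$status[i[1]],
                       date[i], tmin[i], df$temp_c[i])
  })
  n_out <- sum(vapply(traces, function(tr) length(tr$t), integer(1)))
  stopifnot(n_out == nrow(df))
  unname(traces)
}

#' @rdname read_logger_traces
#' @export
write_logger_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(roost_id = tr$roost_id, substrate = tr$substrate, status = tr$status,
               timestamp = paste(tr$date, minutes_to_clock(as.integer(round(tr$t)))),
               temp_c = tr$temp)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and re-read a results table losslessly
#'
#' Comma-separated text with a deterministic column order (the order of
#' `rows`) and numeric fields at full double precision (15 significant
#' digits), so numeric columns survive a round trip to at least 12
#' significant digits. An empty data frame produces a header-only file.
#'
#' @param rows a data frame.
#' @param path file path.
#' @return `write_results_table()` returns `path` invisibly;
#'   `read_results_table()` returns a data frame.
#' @export
write_results_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15, trim = TRUE,
                                                  scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Save or load posterior draws as a long table
#'
#' Draws are stored in long format with columns `chain`, `iteration`
#' (post-warmup index), `parameter`, `value`, the interchange format for
#' fitted posteriors.
#'
#' @param fit a fit object with a `draws` list of chains-by-draws matrices
#'   (e.g. from [fit_torpor_model()] or [fit_selection_model()]).
#' @param path file path.
#' @return `read_draws_table()` returns a named list of chains-by-draws
#'   matrices.
#' @export
write_draws_table <- function(fit, path) {
  stopifnot(is.list(fit$draws))
  long <- do.call(rbind, lapply(names(fit$draws), function(p) {
    m <- fit$draws[[p]]
    data.frame(chain = rep(seq_len(nrow(m)), ncol(m)),
               iteration = rep(seq_len(ncol(m)), each = nrow(m)),
               parameter = p, value = as.vector(m))
  }))
  write_results_table(long, path)
}

#' @rdname write_draws_table
#' @export
read_draws_table <- function(path) {
  long <- read_results_table(path)
  check_columns(long, c("chain", "iteration", "parameter", "value"), path)
  lapply(split(long, factor(long$parameter, levels = unique(long$parameter))),
         function(g) {
           m <- matrix(NA_real_, max(g$chain), max(g$iteration))
           m[cbind(g$chain, g$iteration)] <- g$value
           m
         })
}
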