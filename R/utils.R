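`%||%` <- function(a, b) if (is.null(a)) b else a

# window membership is half-open [start, end) everywhere in the package so
# that a 975-min window contains exactly 975 one-minute samples
in_window <- function(t, window) t >= window[1] & t < window[2]

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_fmt("`%s` must be a single finite number", name)
  }
  invisible(x)
}

#' Convert minutes since midnight to decimal hours
#'
#' @param m numeric vector of minutes since midnight (0-based).
#' @return decimal hours.
#' @export
minutes_to_hours <- function(m) m / 60

#' Format minutes since midnight as "HH:MM" clock time
#'
#' @param m integer minutes since midnight.
#' @return character vector.
#' @export
minutes_to_clock <- function(m) {
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

clock_to_minutes <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) as.integer(p[1]) * 60L + as.integer(p[2]), integer(1))
}
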