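#' Post-thrombectomy blood-pressure monitoring schedule
#'
#' The local monitoring protocol after endovascular thrombectomy (EVT)
#' schedules 21 systolic blood pressure (SBP) measurements over the first
#' 24 hours: every 30 minutes from 0 to 4 hours, hourly from 4 to 8 hours,
#' and every 2 hours from 8 to 24 hours. Eight further measurements at the
#' odd hours 9 to 23 are optional and recorded only when available.
#'
#' @return An object of class `measurement_schedule`: a list with
#'   `scheduled` (21 hours) and `optional` (8 hours), both in hours since
#'   the end of the EVT procedure.
#' @examples
#' sched <- default_schedule()
#' length(sched$scheduled) # 21
#' @export
default_schedule <- function() {
  scheduled <- c(seq(0, 4, by = 0.5), 5, 6, 7, 8, seq(10, 24, by = 2))
  optional <- seq(9, 23, by = 2)
  new_measurement_schedule(scheduled, optional)
}

new_measurement_schedule <- function(scheduled, optional) {
  s <- structure(list(scheduled = scheduled, optional = optional),
                 class = "measurement_schedule")
  validate_schedule(s)
  s
}

validate_schedule <- function(s) {
  if (length(s$scheduled) != 21L)
    stop_sbp("schedule must have exactly 21 scheduled times, got %d",
             length(s$scheduled))
  if (length(s$optional) != 8L)
    stop_sbp("schedule must have exactly 8 optional times, got %d",
             length(s$optional))
  all_t <- c(s$scheduled, s$optional)
  if (any(all_t < 0) || any(all_t > 24))
    stop_sbp("schedule times must lie in [0, 24]")
  if (is.unsorted(s$scheduled, strictly = TRUE) ||
      is.unsorted(s$optional, strictly = TRUE))
    stop_sbp("schedule times must be strictly increasing")
  if (anyDuplicated(all_t))
    stop_sbp("scheduled and optional times must not overlap")
  invisible(s)
}

#' @export
print.measurement_schedule <- function(x, ...) {
  cat("Post-EVT SBP monitoring schedule\n")
  cat("  scheduled (", length(x$scheduled), "): ",
      paste(x$scheduled, collapse = ", "), " h\n", sep = "")
  cat("  optional  (", length(x$optional), "): ",
      paste(x$optional, collapse = ", "), " h\n", sep = "")
  invisible(x)
}
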