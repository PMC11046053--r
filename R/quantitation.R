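# Bioprocess quantitation. Unit conventions are fixed throughout: VCD in
# cells/mL, titer in ug/mL, specific productivity q_p in pg/cell/day
# (1 ug/mL = 1e6 pg/mL), IVCD in cell*day/mL.

check_series <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("day", "vcd", "titer") %in% names(series)))
  if (is.unsorted(series$day, strictly = TRUE))
    stop("day must be strictly increasing")
  invisible(series)
}

#' Integral viable cell density
#'
#' Trapezoidal integral of VCD over `[from_day, to_day]`, with linear
#' interpolation at interval endpoints that fall between samples.
#'
#' @param series A culture series (`day`, `vcd`, `titer`).
#' @param from_day,to_day Integration interval (days).
#' @return IVCD in cell*day/mL.
#' @export
ivcd <- function(series, from_day = min(series$day), to_day = max(series$day)) {
  check_series(series)
  if (from_day > to_day) stop("reversed interval")
  if (from_day < min(series$day) || to_day > max(series$day))
    stop("interval outside the series")
  if (from_day == to_day) return(0)
  grid <- sort(unique(c(from_day, to_day,
                        series$day[series$day > from_day & series$day < to_day])))
  v <- approx(series$day, series$vcd, xout = grid)$y
  sum(diff(grid) * (head(v, -1) + tail(v, -1)) / 2)
}

#' Specific productivity
#'
#' q_p = titer increment over the interval (converted to pg/mL) divided by
#' the IVCD of the interval.
#'
#' @inheritParams ivcd
#' @return q_p in pg/cell/day.
#' @export
specific_productivity <- function(series, from_day = min(series$day),
                                  to_day = max(series$day)) {
  check_series(series)
  iv <- ivcd(series, from_day, to_day)
  if (iv <= 0) stop("zero IVCD over the interval")
  titer <- approx(series$day, series$titer, xout = c(from_day, to_day))$y
  (titer[2] - titer[1]) * 1e6 / iv
}

#' Maximum product titer
#' @param series A culture series.
#' @return P_max in ug/mL.
#' @export
p_max <- function(series) {
  check_series(series)
  max(series$titer)
}

#' Fold change with presentation rounding
#'
#' `value_test / value_control`, rounded half-to-even to the requested
#' decimals (internal computations elsewhere keep full precision; rounding
#' here is presentation only).
#'
#' @param value_test,value_control Positive readouts.
#' @param decimals Decimal places.
#' @return The rounded ratio.
#' @export
fold_change <- function(value_test, value_control, decimals = 2L) {
  if (any(value_control <= 0)) stop("control value must be positive")
  round(value_test / value_control, decimals)
}

#' Normalize a readout by copy number
#' @param readout Expression readout (e.g. MFI).
#' @param copies Integer copy number, >= 1.
#' @return readout / copies.
#' @export
per_copy_normalize <- function(readout, copies) {
  if (any(copies < 1)) stop("copies must be >= 1")
  readout / copies
}

#' Detect the exponential growth phase
#'
#' Longest day interval (at least `min_points` samples) whose log-linear
#' VCD fit reaches R-squared >= `r2_min`. Offered as a helper; quantitation
#' functions always take an explicit interval and never apply this
#' silently.
#'
#' @param series A culture series.
#' @param min_points Minimum samples in the window.
#' @param r2_min Minimum R-squared of the log-linear fit.
#' @return `c(from_day, to_day)`, or NULL when no window qualifies.
#' @export
detect_exponential_phase <- function(series, min_points = 3L, r2_min = 0.98) {
  check_series(series)
  n <- nrow(series)
  best <- NULL; best_span <- -Inf
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq.int(i + min_points - 1L, n)) {
      v <- series$vcd[i:j]
      if (any(v <= 0)) next
      fit <- lm(log(v) ~ series$day[i:j])
      r2 <- summary(fit)$r.squared
      span <- series$day[j] - series$day[i]
      if (r2 >= r2_min && span > best_span) {
        best <- c(series$day[i], series$day[j]); best_span <- span
      }
    }
  }
  best
}

#' Productivity summary of a batch culture
#'
#' @inheritParams ivcd
#' @return `list(ivcd, q_p, p_max, interval)` of class
#'   `productivity_summary`; the interval used is always reported.
#' @export
productivity_summary <- function(series, from_day = min(series$day),
                                 to_day = max(series$day)) {
  structure(list(ivcd = ivcd(series, from_day, to_day),
                 q_p = specific_productivity(series, from_day, to_day),
                 p_max = p_max(series),
                 interval = c(from_day, to_day)),
            class = "productivity_summary")
}

#' @export
print.productivity_summary <- function(x, ...) {
  cat(sprintf(paste0("<productivity_summary> days %g-%g: IVCD %.3g",
                     " cell*day/mL, q_p %.3g pg/cell/day, P_max %.3g ug/mL\n"),
              x$interval[1], x$interval[2], x$ivcd, x$q_p, x$p_max))
  invisible(x)
}
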