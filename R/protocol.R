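#' Treatment-group labels
#'
#' The three experimental arms: asphyxia-normothermia (`A-NT`),
#' asphyxia plus continuous molecular-hydrogen ventilation (`A-H2`), and
#' asphyxia plus therapeutic hypothermia (`A-TH`).
#' @return character vector of the three labels.
#' @export
group_labels <- function() c("A-NT", "A-H2", "A-TH")

check_group <- function(group) {
  if (!is.character(group) || length(group) != 1L ||
      !group %in% group_labels())
    stop_invalid("`group` must be one of ",
                 paste(group_labels(), collapse = ", "))
  group
}

#' Target rectal-temperature protocol schedule
#'
#' Builds the piecewise-linear target temperature trajectory over the 48 h
#' observation period (time 0 = reventilation onset). Normothermic arms stay
#' at the 38.5 C setpoint. The hypothermia arm cools to 33.5 C within
#' 45-50 min after asphyxia, holds until hour 37, then rewarms at 0.5 C/h
#' for 10 h, reaching the normothermic setpoint one hour before the end of
#' observation.
#'
#' @param group one of [group_labels()].
#' @param normothermia_c normothermic setpoint (default 38.5 C).
#' @param hypothermia_c cooling target (default 33.5 C).
#' @param cooling_min minutes to reach the cooling target (default 47.5,
#'   i.e. the middle of the stated 45-50 min).
#' @param hold_until_h end of the hypothermia hold, hours post-asphyxia.
#' @param rewarm_rate_c_per_h rewarming rate (default 0.5 C/h).
#' @param duration_h observation period (default 48 h).
#' @param asphyxia_start_min,asphyxia_duration_min the asphyxic insult
#'   interval, minutes relative to reventilation (defaults -20 and 20).
#' @return `protocol_schedule` object: breakpoints data frame `time_h`,
#'   `temp_c`, plus group and asphyxia-interval metadata.
#' @export
generate_protocol_schedule <- function(group,
                                       normothermia_c = 38.5,
                                       hypothermia_c = 33.5,
                                       cooling_min = 47.5,
                                       hold_until_h = 37,
                                       rewarm_rate_c_per_h = 0.5,
                                       duration_h = 48,
                                       asphyxia_start_min = -20,
                                       asphyxia_duration_min = 20) {
  check_group(group)
  if (group %in% c("A-NT", "A-H2")) {
    bp <- data.frame(time_h = c(0, duration_h),
                     temp_c = c(normothermia_c, normothermia_c))
  } else {
    rewarm_h <- (normothermia_c - hypothermia_c) / rewarm_rate_c_per_h
    end_rewarm <- hold_until_h + rewarm_h
    bp <- data.frame(
      time_h = c(0, cooling_min / 60, hold_until_h, end_rewarm, duration_h),
      temp_c = c(normothermia_c, hypothermia_c, hypothermia_c,
                 normothermia_c, normothermia_c))
    bp <- bp[!duplicated(bp$time_h), , drop = FALSE]
  }
  structure(list(group = group, breakpoints = bp,
                 asphyxia_interval_min = c(start = asphyxia_start_min,
                                           duration = asphyxia_duration_min)),
            class = "protocol_schedule")
}

#' Evaluate a protocol schedule at given times
#'
#' Linear interpolation of the target-temperature breakpoints.
#'
#' @param schedule a [generate_protocol_schedule()] object.
#' @param time_h hours post-asphyxia (vectorized).
#' @return target temperatures in degrees C.
#' @export
schedule_temperature <- function(schedule, time_h) {
  stats::approx(schedule$breakpoints$time_h, schedule$breakpoints$temp_c,
                xout = time_h, rule = 2)$y
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat(sprintf("<protocol_schedule> %s, %d breakpoints over 0-%g h\n",
              x$group, nrow(x$breakpoints), max(x$breakpoints$time_h)))
  invisible(x)
}
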