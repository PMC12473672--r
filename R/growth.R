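#' Relative growth rate of frond number
#'
#' Exponential growth constant of frond number between two counting days,
#' `(ln FN_t2 - ln FN_t1) / (t2 - t1)`, the standard index used in duckweed
#' growth assays (OECD-style 7-day tests).
#'
#' @param fn0,fn7 Frond counts on the first and second counting day (>= 1).
#' @param day0,day7 Day indices of the two counts; `day7 > day0`.
#' @return Relative growth rate in day^-1.
#' @examples
#' relative_growth_rate(10, 124)  # ~0.36 day^-1
#' @export
relative_growth_rate <- function(fn0, fn7, day0 = 0, day7 = 7) {
  stopifnot(is.numeric(fn0), is.numeric(fn7))
  if (any(fn0 < 1) || any(fn7 < 1))
    stop("frond counts must be >= 1 (log of zero counts is undefined)")
  if (any(day7 <= day0))
    stop("day7 must be later than day0")
  (log(fn7) - log(fn0)) / (day7 - day0)
}

#' Population doubling time from a relative growth rate
#'
#' @param rgr Relative growth rate in day^-1; must be positive.
#' @return Doubling time in days, `ln(2)/rgr`.
#' @examples
#' doubling_time(0.55)  # < 1.3 days
#' @export
doubling_time <- function(rgr) {
  if (any(rgr <= 0))
    stop("doubling time is undefined for non-positive growth rates")
  log(2) / rgr
}

#' Mean colony size
#'
#' Fronds per colony, `FN/CN`, from the frond and colony counts of a vessel.
#'
#' @param fn Frond count.
#' @param cn Colony count (>= 1).
#' @return Fronds per colony.
#' @export
colony_size <- function(fn, cn) {
  if (any(cn < 1)) stop("colony count must be >= 1")
  if (any(fn < cn)) stop("frond count cannot be smaller than colony count")
  fn / cn
}

#' Percentage of senescent fronds
#'
#' Fronds showing any sign of yellowing, as a percentage of the total frond
#' number in the vessel.
#'
#' @param senescent Count of senescent fronds.
#' @param fn Total frond count (>= 1).
#' @return Percentage in \[0, 100\].
#' @export
senescence_percent <- function(senescent, fn) {
  if (any(fn < 1)) stop("total frond count must be >= 1")
  if (any(senescent < 0) || any(senescent > fn))
    stop("senescent count must lie in [0, fn]")
  100 * senescent / fn
}

#' Frond area from length and width assuming an ellipse
#'
#' `A = a * b * pi` with `a`, `b` the half-length and half-width of the frond.
#'
#' @param length,width Frond length and width in mm; `length >= width > 0`.
#' @return Area in mm^2.
#' @export
ellipse_area <- function(length, width) {
  if (any(width <= 0)) stop("frond dimensions must be positive")
  if (any(length < width)) stop("length must be >= width")
  pi * (length / 2) * (width / 2)
}

#' Frond roundness (length-to-width ratio)
#'
#' @param length,width Frond dimensions in mm; `length >= width > 0`.
#' @return Dimensionless ratio >= 1; 1 denotes a circular frond.
#' @export
frond_roundness <- function(length, width) {
  if (any(width <= 0)) stop("frond dimensions must be positive")
  if (any(length < width)) stop("length must be >= width")
  length / width
}

#' Daily light integral
#'
#' Integrates a constant photosynthetic photon flux density over the
#' photoperiod: `DLI = PPFD * photoperiod_h * 3600 / 1e6`.
#'
#' @param ppfd Photon flux density in umol m^-2 s^-1.
#' @param photoperiod_h Photoperiod in hours per day (0-24).
#' @return DLI in mol m^-2 day^-1.
#' @examples
#' daily_light_integral(100, 24)  # 8.64
#' daily_light_integral(243, 24)  # ~21.00
#' @export
daily_light_integral <- function(ppfd, photoperiod_h) {
  if (any(ppfd < 0)) stop("PPFD must be non-negative")
  if (any(photoperiod_h < 0) || any(photoperiod_h > 24))
    stop("photoperiod must lie in [0, 24] hours")
  ppfd * photoperiod_h * 3600 / 1e6
}

#' Frond mass-to-area ratio
#'
#' `FMA = DM / Area`, dry mass per projected plant area, a proxy for frond
#' thickness and tissue density.
#'
#' @param dm Dry mass in mg.
#' @param area Projected area in cm^2; must be positive.
#' @return FMA in mg cm^-2.
#' @export
frond_mass_area <- function(dm, area) {
  if (any(area <= 0)) stop("area must be positive")
  if (any(dm < 0)) stop("dry mass must be non-negative")
  dm / area
}

#' Average per-frond values on a vessel basis
#'
#' Morphometric readings taken on individual fronds are reported as their
#' vessel mean.
#'
#' @param frond_values Non-empty numeric vector of per-frond values.
#' @return Arithmetic mean.
#' @export
vessel_average <- function(frond_values) {
  if (length(frond_values) == 0) stop("no frond values supplied")
  if (anyNA(frond_values)) stop("frond values contain NA")
  mean(frond_values)
}

#' Growth and morphometric summary of a simulated or observed culture
#'
#' Convenience wrapper that takes a per-day count table (as produced by
#' [simulate_growth_series()]) and returns the day-0 to day-7 growth indices.
#'
#' @param counts Data frame with columns `day`, `frond_count`, `colony_count`,
#'   `senescent_count`.
#' @param day0,day7 Days to use as the start and end of the growth interval.
#' @return One-row data frame with `rgr`, `doubling_days`, `colony_size`,
#'   `senescence_pct` (the latter two evaluated on `day7`).
#' @export
growth_summary <- function(counts, day0 = 0, day7 = 7) {
  stopifnot(all(c("day", "frond_count", "colony_count", "senescent_count")
                %in% names(counts)))
  r0 <- counts[counts$day == day0, ]
  r7 <- counts[counts$day == day7, ]
  if (nrow(r0) != 1 || nrow(r7) != 1)
    stop("counts table must contain exactly one row for each of day0 and day7")
  rgr <- relative_growth_rate(r0$frond_count, r7$frond_count, day0, day7)
  data.frame(
    rgr = rgr,
    doubling_days = doubling_time(rgr),
    colony_size = colony_size(r7$frond_count, r7$colony_count),
    senescence_pct = senescence_percent(r7$senescent_count, r7$frond_count)
  )
}
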