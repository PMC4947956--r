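#' Convert OD600 to dry cell weight
#'
#' Linear conversion of an optical-density reading at 600 nm to biomass,
#' using the calibrated factor 0.396 g/L dry cell weight per OD unit by
#' default.
#'
#' @param od OD600 reading(s), `>= 0`.
#' @param factor g/L DCW per OD unit, `> 0`.
#' @return Biomass in g/L DCW.
#' @examples
#' od_to_dcw(1.0)   # 0.396
#' @export
od_to_dcw <- function(od, factor = 0.396) {
  if (any(od < 0)) abort_validation("od must be non-negative")
  check_number(factor, "factor", lower = 0, strict_lower = TRUE)
  od * factor
}

#' Butyrate/acetate ratio
#'
#' The headline selectivity metric of butyrate fermentations: the ratio
#' of butyrate to acetate mass concentration. Zero acetate makes the
#' ratio undefined; `NA` is returned (flagged, not an error).
#'
#' @param butyrate g/L, `>= 0`.
#' @param acetate g/L, `>= 0`.
#' @return The dimensionless ratio, `NA` where acetate is zero.
#' @export
ba_ratio <- function(butyrate, acetate) {
  if (any(butyrate < 0) || any(acetate < 0))
    abort_validation("concentrations must be non-negative")
  ifelse(acetate == 0, NA_real_, butyrate / acetate)
}

#' MTT growth-delay survival fraction
#'
#' Survival fraction of irradiated versus control cultures inferred from
#' the growth delay of the MTT absorbance curve: a delay of one doubling
#' time halves the surviving fraction, giving
#' `S = 2^(-T_delay / T_doubling)`. Equal to 1 at zero delay and
#' strictly decreasing in the delay.
#'
#' @param t_delay hours to reach the reference absorbance, irradiated
#'   minus control, `>= 0`.
#' @param t_doubling culture doubling time in hours, `> 0`.
#' @return Survival fraction in `(0, 1]`.
#' @export
mtt_survival <- function(t_delay, t_doubling) {
  if (any(t_delay < 0)) abort_validation("t_delay must be non-negative")
  if (any(t_doubling <= 0)) abort_validation("t_doubling must be positive")
  2^(-t_delay / t_doubling)
}

#' Multichannel fermentation time series
#'
#' @param time hours, strictly increasing.
#' @param butyrate,acetate,glucose g/L, non-negative.
#' @param od600 dimensionless optical density, non-negative.
#' @param gas cumulative gas production (arbitrary units), non-negative
#'   and non-decreasing.
#' @return A `data.frame` of class `"fermentation_series"` with columns
#'   `time_h`, `butyrate_gL`, `acetate_gL`, `glucose_gL`, `od600`, `gas`.
#' @export
fermentation_series <- function(time, butyrate, acetate, glucose, od600, gas) {
  lens <- lengths(list(time, butyrate, acetate, glucose, od600, gas))
  if (length(unique(lens)) != 1L)
    abort_validation("all channels must have equal length")
  if (any(diff(time) <= 0)) abort_validation("time must be strictly increasing")
  chans <- list(butyrate = butyrate, acetate = acetate, glucose = glucose,
                od600 = od600, gas = gas)
  for (nm in names(chans))
    if (any(chans[[nm]] < 0))
      abort_validation(sprintf("channel '%s' must be non-negative", nm))
  if (any(diff(gas) < -1e-12))
    abort_validation("cumulative gas must be non-decreasing")
  out <- data.frame(time_h = as.numeric(time), butyrate_gL = as.numeric(butyrate),
                    acetate_gL = as.numeric(acetate), glucose_gL = as.numeric(glucose),
                    od600 = as.numeric(od600), gas = as.numeric(gas))
  class(out) <- c("fermentation_series", "data.frame")
  out
}

#' Summarize a batch fermentation
#'
#' Endpoint and extremum metrics of a batch run: final titres at the last
#' recorded time point, the final butyrate/acetate ratio, maximum biomass
#' (peak OD600 converted to dry cell weight), glucose consumed
#' (first minus last reading), and the butyrate yield per gram of glucose
#' consumed (`NA`-flagged when no glucose was consumed).
#'
#' @param series a [fermentation_series()].
#' @param od_factor g/L DCW per OD unit (default 0.396).
#' @return An object of class `"fermentation_summary"` (named list):
#'   `final_butyrate`, `final_acetate`, `ba_ratio`, `max_biomass`,
#'   `glucose_consumed`, `butyrate_yield`.
#' @examples
#' s <- gen_fermentation("pH5.0", noise = FALSE)
#' summarize_fermentation(s)
#' @export
summarize_fermentation <- function(series, od_factor = 0.396) {
  stopifnot(inherits(series, "fermentation_series"))
  if (nrow(series) == 0L) abort_validation("series is empty")
  last <- nrow(series)
  fb <- series$butyrate_gL[last]
  fa <- series$acetate_gL[last]
  consumed <- series$glucose_gL[1] - series$glucose_gL[last]
  structure(list(
    final_butyrate = fb,
    final_acetate = fa,
    ba_ratio = ba_ratio(fb, fa),
    max_biomass = od_to_dcw(max(series$od600), od_factor),
    glucose_consumed = consumed,
    butyrate_yield = if (consumed > 0) fb / consumed else NA_real_),
    class = "fermentation_summary")
}

#' @export
print.fermentation_summary <- function(x, digits = 4, ...) {
  cat("Batch fermentation summary\n")
  cat("  final butyrate:   ", format(x$final_butyrate, digits = digits), "g/L\n")
  cat("  final acetate:    ", format(x$final_acetate, digits = digits), "g/L\n")
  cat("  B/A ratio:        ", format(x$ba_ratio, digits = digits), "\n")
  cat("  max biomass:      ", format(x$max_biomass, digits = digits), "g/L DCW\n")
  cat("  glucose consumed: ", format(x$glucose_consumed, digits = digits), "g/L\n")
  cat("  butyrate yield:   ", format(x$butyrate_yield, digits = digits), "g/g\n")
  invisible(x)
}
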