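#' US EPA PM2.5 / AQI breakpoint table
#'
#' Piecewise-linear breakpoints mapping 24-h PM2.5 concentration (ug/m^3,
#' truncated to 0.1) to the US Air Quality Index, with the standard health
#' category bands. Concentration breakpoints follow the EPA PM2.5 sub-index
#' in force through 2023.
#'
#' @format data.frame with columns `c_lo`, `c_hi` (ug/m^3), `i_lo`, `i_hi`
#'   (AQI), `category`.
#' @export
aqi_breakpoints <- function() {
  data.frame(
    c_lo = c(0.0, 12.1, 35.5, 55.5, 150.5, 250.5, 350.5),
    c_hi = c(12.0, 35.4, 55.4, 150.4, 250.4, 350.4, 500.4),
    i_lo = c(0, 51, 101, 151, 201, 301, 401),
    i_hi = c(50, 100, 150, 200, 300, 400, 500),
    category = c("good", "moderate", "unhealthy_sensitive", "unhealthy",
                 "very_unhealthy", "hazardous", "hazardous"),
    stringsAsFactors = FALSE)
}

#' Convert PM2.5 concentration to US AQI
#'
#' Standard EPA piecewise-linear interpolation:
#' `AQI = (i_hi - i_lo) / (c_hi - c_lo) * (C - c_lo) + i_lo` on the segment
#' containing `C` (truncated to one decimal). Concentrations above the table
#' maximum are clamped with a warning.
#'
#' @param conc PM2.5 concentration in ug/m^3 (vectorised, >= 0).
#' @return AQI values.
#' @export
pm25_to_aqi <- function(conc) {
  stopifnot(all(conc >= 0, na.rm = TRUE))
  bp <- aqi_breakpoints()
  conc <- trunc(conc * 10) / 10
  top <- max(bp$c_hi)
  if (any(conc > top, na.rm = TRUE)) {
    warning("PM2.5 above ", top, " ug/m^3 clamped to table maximum")
    conc <- pmin(conc, top)
  }
  seg <- findInterval(conc, bp$c_lo)
  (bp$i_hi[seg] - bp$i_lo[seg]) / (bp$c_hi[seg] - bp$c_lo[seg]) *
    (conc - bp$c_lo[seg]) + bp$i_lo[seg]
}

#' Convert US AQI to PM2.5 concentration
#'
#' Inverse of [pm25_to_aqi()]; exact at every breakpoint. AQI values above
#' 500 are clamped with a warning.
#'
#' @param aqi AQI values (vectorised, >= 0).
#' @return PM2.5 concentration in ug/m^3.
#' @export
aqi_to_pm25 <- function(aqi) {
  stopifnot(all(aqi >= 0, na.rm = TRUE))
  bp <- aqi_breakpoints()
  top <- max(bp$i_hi)
  if (any(aqi > top, na.rm = TRUE)) {
    warning("AQI above ", top, " clamped to table maximum")
    aqi <- pmin(aqi, top)
  }
  seg <- findInterval(aqi, bp$i_lo)
  (bp$c_hi[seg] - bp$c_lo[seg]) / (bp$i_hi[seg] - bp$i_lo[seg]) *
    (aqi - bp$i_lo[seg]) + bp$c_lo[seg]
}

#' AQI health category
#'
#' Bands: <= 50 good, 51-100 moderate, 101-150 unhealthy for sensitive
#' groups, 151-200 unhealthy, 201-300 very unhealthy, above 300 hazardous.
#'
#' @param aqi AQI values (vectorised).
#' @return character vector of category labels.
#' @export
aqi_category <- function(aqi) {
  stopifnot(all(aqi >= 0, na.rm = TRUE))
  cut(aqi, breaks = c(-Inf, 50, 100, 150, 200, 300, Inf),
      labels = c("good", "moderate", "unhealthy_sensitive", "unhealthy",
                 "very_unhealthy", "hazardous")) |> as.character()
}
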