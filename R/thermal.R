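#' Define a growth window
#'
#' A validated sowing/flowering/maturity date triple used by the thermal
#' summaries. The vegetative sub-window is `[sowing, flowering)`, the
#' reproductive sub-window `[flowering, maturity]`.
#'
#' @param sowing,flowering,maturity Calendar dates (Date or ISO strings);
#'   `flowering` may be omitted if only whole-window summaries are needed.
#' @return An object of class `growth_window`.
#' @examples
#' growth_window("2017-03-01", "2017-05-01", "2017-06-05")
#' @export
growth_window <- function(sowing, flowering = NULL, maturity) {
  sowing <- as.Date(sowing)
  maturity <- as.Date(maturity)
  if (!is.null(flowering)) {
    flowering <- as.Date(flowering)
    if (!(sowing < flowering && flowering < maturity)) {
      abort("growth window requires sowing < flowering < maturity")
    }
  } else if (sowing >= maturity) {
    abort("growth window requires sowing < maturity")
  }
  structure(list(sowing = sowing, flowering = flowering, maturity = maturity),
            class = "growth_window")
}

# slice a temperature tibble to the days of a (sub-)window
window_slice <- function(temps, window,
                         part = c("total", "vegetative", "reproductive")) {
  assert_columns(temps, c("date", "t_mean"), "temps")
  part <- match.arg(part)
  stopifnot(inherits(window, "growth_window"))
  if (part != "total" && is.null(window$flowering)) {
    abort("sub-window summaries need a flowering date in the growth window")
  }
  bounds <- switch(part,
    total = c(window$sowing, window$maturity),
    vegetative = c(window$sowing, window$flowering - 1),
    reproductive = c(window$flowering, window$maturity))
  dates <- as.Date(temps$date)
  if (bounds[1] < min(dates) || bounds[2] > max(dates)) {
    abort("growth window falls outside the temperature series span")
  }
  temps[dates >= bounds[1] & dates <= bounds[2], , drop = FALSE]
}

#' Count heat-stress days above temperature thresholds
#'
#' Number of days in the growth window whose daily mean temperature is
#' strictly above each threshold. The default thresholds bracket the crop's
#' comfort range (16, 20, 22 deg C) and acute stress (30 deg C).
#'
#' @param temps Tibble with `date`, `t_mean` (see [sim_temperatures()]).
#' @param window A [growth_window()].
#' @param thresholds Numeric vector of thresholds, deg C.
#' @param part Which sub-window to summarize.
#' @return Tibble with columns `threshold` and `days`; zero rows if
#'   `thresholds` is empty.
#' @examples
#' temps <- sim_temperatures(2017, noise_sd = 0, seed = 1)
#' w <- growth_window("2017-03-01", maturity = "2017-06-01")
#' heat_stress_days(temps, w)
#' @export
heat_stress_days <- function(temps, window, thresholds = c(16, 20, 22, 30),
                             part = "total") {
  sl <- window_slice(temps, window, part)
  tibble::tibble(
    threshold = as.numeric(thresholds),
    days = vapply(thresholds, function(th) sum(sl$t_mean > th), integer(1))
  )
}

#' Thermal-unit (growing degree-day) accumulation over a growth window
#'
#' Sum over window days of `max(0, t_mean - base_temp)`. The base temperature
#' defaults to 0 deg C and is fully configurable.
#'
#' @inheritParams heat_stress_days
#' @param base_temp Base temperature, deg C.
#' @return Degree-days (numeric scalar, >= 0).
#' @examples
#' temps <- sim_temperatures(2017, noise_sd = 0, seed = 1)
#' w <- growth_window("2017-03-01", maturity = "2017-04-01")
#' thermal_units(temps, w)
#' @export
thermal_units <- function(temps, window, base_temp = 0, part = "total") {
  stopifnot(is.finite(base_temp))
  sl <- window_slice(temps, window, part)
  sum(pmax(0, sl$t_mean - base_temp))
}

#' Mean daily temperature over a growth window
#'
#' @inheritParams heat_stress_days
#' @return Mean of daily means, deg C.
#' @export
window_mean <- function(temps, window, part = "total") {
  sl <- window_slice(temps, window, part)
  if (nrow(sl) == 0) abort("empty growth window")
  mean(sl$t_mean)
}

#' Read a daily temperature table
#'
#' Expects a delimited file with columns `date` (ISO) and `t_mean`.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return Tibble with `date` (Date) and `t_mean`.
#' @export
read_temperature_table <- function(path, delim = "\t") {
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  assert_columns(out, c("date", "t_mean"), "temperature table")
  out$date <- as.Date(out$date)
  out
}
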