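#' Seasonal step function for annual integration
#'
#' A calendar of rate multipliers used to integrate a peak-season flux over
#' the growing season. The default calendar assumes daily fixation is
#' half-maximal May 20-31, maximal June 1 - August 15, half-maximal for the
#' last two weeks of August (taken as August 16-31) and quarter-maximal for
#' the first two weeks of September (September 1-14), and zero otherwise.
#' Dates are month-day strings ("MM-DD"); segment ends are inclusive and a
#' non-leap calendar is assumed (no segment touches February).
#'
#' @param segments data frame with columns `start`, `end` (\"MM-DD\") and
#'   `multiplier` in \[0, 1\]. Default: the calendar above (93.5 effective
#'   full-rate days).
#' @return object of class `step_function`.
#' @examples
#' effective_full_rate_days(seasonal_step_function())
#' @export
seasonal_step_function <- function(segments = NULL) {
  if (is.null(segments)) {
    segments <- data.frame(
      start = c("05-20", "06-01", "08-16", "09-01"),
      end = c("05-31", "08-15", "08-31", "09-14"),
      multiplier = c(0.5, 1.0, 0.5, 0.25),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(segments)) {
    start_d <- md_to_date(segments$start)
    end_d <- md_to_date(segments$end)
    if (any(end_d < start_d)) stop("segment end precedes start", call. = FALSE)
    if (any(segments$multiplier < 0 | segments$multiplier > 1)) {
      stop("multipliers must lie in [0, 1]", call. = FALSE)
    }
    ord <- order(start_d)
    if (!identical(ord, seq_len(nrow(segments)))) {
      stop("segments must be chronologically ordered", call. = FALSE)
    }
    if (nrow(segments) > 1 &&
        any(start_d[-1] <= end_d[-nrow(segments)])) {
      stop("segments must not overlap", call. = FALSE)
    }
  }
  structure(list(segments = segments), class = "step_function")
}

# anchor month-day strings in a fixed non-leap year for day arithmetic
md_to_date <- function(md) as.Date(paste0("2001-", md))

#' Effective full-rate days of a step function
#'
#' Sum over segments of (inclusive length in days) x multiplier: the number
#' of days at the maximal rate that would deliver the same seasonal total.
#'
#' @param step a [seasonal_step_function()].
#' @return days (numeric; the default calendar gives 93.5).
#' @export
effective_full_rate_days <- function(step) {
  stopifnot(inherits(step, "step_function"))
  seg <- step$segments
  if (nrow(seg) == 0) return(0)
  len <- as.numeric(md_to_date(seg$end) - md_to_date(seg$start)) + 1
  sum(len * seg$multiplier)
}

#' Peak-season area flux of fixed N
#'
#' Product of nodule biomass density (g nodule m^-2 ground) and per-nodule
#' fixation rate (umol N g^-1 nodule h^-1).
#'
#' @param nodule_density g nodule m^-2 ground, >= 0.
#' @param nodule_rate umol N g^-1 dry nodule h^-1, >= 0.
#' @return umol N m^-2 ground h^-1.
#' @export
peak_area_flux <- function(nodule_density, nodule_rate) {
  if (any(nodule_density < 0, na.rm = TRUE) ||
      any(nodule_rate < 0, na.rm = TRUE)) {
    stop("nodule density and rate must be >= 0", call. = FALSE)
  }
  nodule_density * nodule_rate
}

#' Annual N fixation from a peak-season flux
#'
#' Integrates a peak-season hourly flux over the growing season assuming a
#' flat diel rate: annual = peak_flux x 24 h x effective full-rate days x
#' molar mass x 1e-6 (umol -> g).
#'
#' @param peak_flux umol N m^-2 h^-1, >= 0.
#' @param step seasonal step function (default calendar if omitted).
#' @param molar_mass g mol^-1 for N.
#' @return g N m^-2 yr^-1.
#' @examples
#' annual_n_fixation(62)  # ~1.95 g N m^-2 yr^-1
#' @export
annual_n_fixation <- function(peak_flux, step = seasonal_step_function(),
                              molar_mass = N_MOLAR_MASS) {
  if (any(peak_flux < 0, na.rm = TRUE)) {
    stop("peak_flux must be >= 0", call. = FALSE)
  }
  peak_flux * 24 * effective_full_rate_days(step) * molar_mass * 1e-6
}

#' Fixation as a fraction of the community nitrogen requirement
#'
#' @param annual_fix g N m^-2 yr^-1.
#' @param n_req community annual N requirement, g N m^-2 yr^-1, > 0.
#' @return percent of N_req supplied by fixation.
#' @export
fraction_of_nreq <- function(annual_fix, n_req) {
  if (any(n_req <= 0, na.rm = TRUE)) stop("n_req must be > 0", call. = FALSE)
  annual_fix / n_req * 100
}

#' Percent change between two areas
#'
#' @param a_start,a_end areas (same units); `a_start` > 0.
#' @return percent change relative to `a_start`.
#' @export
percent_change <- function(a_start, a_end) {
  if (any(a_start <= 0, na.rm = TRUE)) {
    stop("starting area must be > 0", call. = FALSE)
  }
  (a_end - a_start) / a_start * 100
}

#' Linear rate of areal change
#'
#' @param a_start,a_end areas in m^2.
#' @param year_start,year_end calendar years; `year_end` > `year_start`.
#' @return m^2 yr^-1.
#' @export
linear_rate_of_change <- function(a_start, a_end, year_start, year_end) {
  if (any(year_end <= year_start)) {
    stop("year_end must exceed year_start", call. = FALSE)
  }
  (a_end - a_start) / (year_end - year_start)
}

#' Landscape fixation through time under a constant areal rate
#'
#' Applies a constant annual fixation rate (g N m^-2 yr^-1) to a time series
#' of shrubland area, giving whole-landscape fixation per year, and the
#' percent change in total fixation between the first and last years. With a
#' constant rate the percent change in fixation equals the percent change in
#' area by construction.
#'
#' @param series data frame with columns `year` (strictly increasing) and
#'   `area_m2` (>= 0).
#' @param annual_rate g N m^-2 yr^-1, >= 0.
#' @return list with `series` (year, area_m2, fixation_g_n) and
#'   `percent_change` of total fixation first -> last year.
#' @export
landscape_fixation_series <- function(series, annual_rate) {
  if (nrow(series) == 0) stop("empty area series", call. = FALSE)
  if (any(diff(series$year) <= 0)) {
    stop("years must be strictly increasing", call. = FALSE)
  }
  if (any(series$area_m2 < 0) || annual_rate < 0) {
    stop("areas and rate must be >= 0", call. = FALSE)
  }
  fix <- series$area_m2 * annual_rate
  pc <- if (series$area_m2[1] > 0 && annual_rate > 0) {
    percent_change(fix[1], fix[length(fix)])
  } else NA_real_
  list(series = data.frame(year = series$year, area_m2 = series$area_m2,
                           fixation_g_n = fix),
       percent_change = pc)
}
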