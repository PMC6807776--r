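#' Ground area of a soil core
#'
#' @param diameter_cm core diameter in cm (field default 7.3).
#' @return core cross-sectional area in m^2.
#' @examples
#' core_area(7.3)
#' @export
core_area <- function(diameter_cm) {
  if (any(diameter_cm <= 0, na.rm = TRUE)) {
    stop("core diameter must be > 0", call. = FALSE)
  }
  pi * (diameter_cm / 200)^2
}

per_core_density <- function(cores) {
  required <- c("mass_g", "diameter_cm")
  missing_cols <- setdiff(required, names(cores))
  if (length(missing_cols)) {
    stop("core table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(cores$mass_g < 0, na.rm = TRUE)) {
    stop("live nodule mass must be >= 0", call. = FALSE)
  }
  cores$mass_g / core_area(cores$diameter_cm)
}

sample_se <- function(x) {
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Plot-level nodule biomass density for a gridded plot
#'
#' For square gridded plots sampled on a regular cell grid, the plot density
#' is the unweighted mean over collected cores of per-core density
#' (mass / core area). Cells skipped in the field are simply absent; cores
#' that contained no live nodules count as zeros.
#'
#' @param cores data frame with `mass_g` (g dry live nodule) and
#'   `diameter_cm` per core.
#' @return list of class `plot_estimate` with `density` (g m^-2), `se`
#'   (over cores) and `n_cores`.
#' @export
grid_plot_density <- function(cores) {
  if (nrow(cores) == 0) stop("no cores supplied", call. = FALSE)
  d <- per_core_density(cores)
  structure(list(density = mean(d), se = sample_se(d), n_cores = length(d)),
            class = "plot_estimate")
}

#' Plot-level nodule biomass density for a bullseye plot
#'
#' Bullseye plots have an inner circle spanning the shrub canopy and an
#' outer ring extending the radius (by 0.5 m in the field design). The plot
#' density is the area-weighted average of the inner- and outer-zone mean
#' core densities, with weights A_in = pi r_in^2 and
#' A_ring = pi (r_out^2 - r_in^2). The standard error combines the zone
#' standard errors with the same weights (stratified-sampling variance).
#'
#' @param inner_cores,outer_cores core data frames as in
#'   [grid_plot_density()].
#' @param inner_radius,outer_radius zone radii in m; `outer_radius` must
#'   exceed `inner_radius`.
#' @return `plot_estimate` list with `density`, `se`, `n_cores` and the
#'   zone weights used.
#' @export
bullseye_plot_density <- function(inner_cores, outer_cores,
                                  inner_radius, outer_radius = inner_radius + 0.5) {
  if (nrow(inner_cores) == 0 || nrow(outer_cores) == 0) {
    stop("both inner and outer zones need at least one core", call. = FALSE)
  }
  if (!(outer_radius > inner_radius && inner_radius > 0)) {
    stop("need outer_radius > inner_radius > 0", call. = FALSE)
  }
  a_in <- pi * inner_radius^2
  a_ring <- pi * (outer_radius^2 - inner_radius^2)
  w_in <- a_in / (a_in + a_ring)
  w_out <- a_ring / (a_in + a_ring)
  d_in <- per_core_density(inner_cores)
  d_out <- per_core_density(outer_cores)
  se_in <- sample_se(d_in)
  se_out <- sample_se(d_out)
  se <- if (is.na(se_in) || is.na(se_out)) NA_real_ else
    sqrt(w_in^2 * se_in^2 + w_out^2 * se_out^2)
  structure(list(density = w_in * mean(d_in) + w_out * mean(d_out),
                 se = se, n_cores = length(d_in) + length(d_out),
                 weights = c(inner = w_in, outer = w_out)),
            class = "plot_estimate")
}

#' Community-level nodule biomass density
#'
#' Unweighted mean of plot-level densities with its standard error over
#' plots. Because plots, not cores, are the replication unit for the
#' community, the SE over plots is the primary uncertainty; the pooled SE
#' over all cores is also reported for comparison.
#'
#' @param plot_estimates list of `plot_estimate` objects (or a numeric
#'   vector of plot densities).
#' @return list with `density`, `se` (over plots), `n_plots`, and
#'   `se_cores` (pooled over cores, NA when core SEs are unavailable).
#' @export
community_density <- function(plot_estimates) {
  if (is.numeric(plot_estimates)) {
    d <- plot_estimates
    se_cores <- NA_real_
  } else {
    if (length(plot_estimates) == 0) stop("no plots supplied", call. = FALSE)
    d <- vapply(plot_estimates, function(p) p$density, numeric(1))
    ses <- vapply(plot_estimates, function(p) p$se %||% NA_real_, numeric(1))
    ns <- vapply(plot_estimates, function(p) p$n_cores, numeric(1))
    se_cores <- if (any(is.na(ses))) NA_real_ else
      sqrt(sum(ses^2 * ns^2)) / sum(ns)
  }
  list(density = mean(d), se = sample_se(d), n_plots = length(d),
       se_cores = se_cores)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.plot_estimate <- function(x, ...) {
  cat(sprintf("Nodule biomass: %.2f g m^-2 (SE %.2f, %d cores)\n",
              x$density, x$se, x$n_cores))
  invisible(x)
}
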