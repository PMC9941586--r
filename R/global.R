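# station production vs satellite-PIC regression, area-weighted global
# integration, low-PIC minimum estimate, unit conversions

#' Regression of annual CaCO3 production on satellite PIC
#'
#' Ordinary least squares of station annual production (mol m-2 yr-1) on
#' annual-mean satellite PIC (mg m-3), with intercept. The non-zero
#' intercept absorbs subsurface production invisible to the satellite.
#' The residual standard error is `sqrt(SSres / (n - 2))`.
#'
#' @param annual_production_mol_m2_yr station production values.
#' @param satellite_pic_mg_m3 satellite PIC at the station locations.
#' @return object of class `pic_regression`: `intercept`, `slope`,
#'   `r_squared`, `std_error`, `n`, and the underlying `lm` fit.
#' @export
fit_pic_regression <- function(annual_production_mol_m2_yr, satellite_pic_mg_m3) {
  y <- annual_production_mol_m2_yr
  x <- satellite_pic_mg_m3
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 stations", call. = FALSE)
  if (stats::var(x) == 0) stop("no variance in satellite PIC predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant production across stations; R^2 reported as 0")
    r2 <- 0
  } else {
    r2 <- 1 - ss_res / ss_tot
  }
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 std_error = sqrt(ss_res / (n - 2)),
                 n = n, lm = fit),
            class = "pic_regression")
}

#' @export
print.pic_regression <- function(x, ...) {
  cat("Annual CaCO3 production vs satellite PIC (OLS)\n")
  cat(sprintf("  production = %.3g + %.3g x PIC   (mol m-2 yr-1; PIC in mg m-3)\n",
              x$intercept, x$slope))
  cat(sprintf("  R^2 = %.3f, SE = %.3g, n = %d\n", x$r_squared, x$std_error, x$n))
  invisible(x)
}

#' @export
coef.pic_regression <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.pic_regression <- function(object, satellite_pic_mg_m3, floor = TRUE, ...) {
  p <- object$intercept + object$slope * satellite_pic_mg_m3
  if (floor) pmax(p, 0) else p
}

#' Construct a satellite PIC grid
#'
#' A regular latitude x longitude (x month) grid of satellite PIC
#' (mg CaCO3 m-3) with an ocean mask. The annual field is the unweighted
#' mean over months with valid retrievals per cell (high-latitude winter
#' gaps are excluded from the mean, not zero-filled); the mask defaults to
#' cells with at least one valid monthly retrieval.
#'
#' @param lat,lon cell-center coordinate vectors, degrees, regular spacing.
#' @param values matrix `length(lat) x length(lon)` (annual) or array with a
#'   third month dimension.
#' @param mask logical matrix of ocean cells; default derived from `values`.
#' @return object of class `pic_grid` with `lat`, `lon`, `values`,
#'   `annual`, `mask`.
#' @export
pic_grid <- function(lat, lon, values, mask = NULL) {
  stopifnot(all(abs(lat) <= 90))
  d <- dim(values)
  stopifnot(d[1] == length(lat), d[2] == length(lon))
  annual <- if (length(d) == 3L) {
    apply(values, c(1, 2), function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  } else {
    values
  }
  if (is.null(mask)) mask <- !is.na(annual)
  stopifnot(identical(dim(mask), dim(annual)))
  structure(list(lat = lat, lon = lon, values = values,
                 annual = annual, mask = mask),
            class = "pic_grid")
}

#' Spherical cell areas of a regular grid
#'
#' Exact spherical band areas: a cell centred at latitude phi with spacing
#' dphi x dlam has area `R^2 * dlam * (sin(phi + dphi/2) - sin(phi - dphi/2))`
#' (angles in radians), so the areas of a global grid sum exactly to
#' `4 * pi * R^2`.
#'
#' @param grid a [pic_grid()].
#' @param radius_m Earth radius, m (default 6371 km; spherical Earth).
#' @return matrix of cell areas, m^2, matching the grid.
#' @export
cell_areas <- function(grid, radius_m = 6371e3) {
  lat <- grid$lat
  dphi <- if (length(lat) > 1) abs(stats::median(diff(lat))) else 180
  dlam <- if (length(grid$lon) > 1) abs(stats::median(diff(grid$lon))) else 360
  to_rad <- pi / 180
  band <- radius_m^2 * (dlam * to_rad) *
    (sin(pmin(lat + dphi / 2, 90) * to_rad) - sin(pmax(lat - dphi / 2, -90) * to_rad))
  matrix(band, nrow = length(lat), ncol = length(grid$lon))
}

#' Area-weighted global integration of predicted production
#'
#' Applies a [fit_pic_regression()] to every ocean cell of the annual PIC
#' field (predictions floored at zero) and integrates over the sphere,
#' weighting by spherical cell area.
#'
#' @param grid a [pic_grid()].
#' @param fit a `pic_regression` (or list with `intercept` and `slope`).
#' @param radius_m Earth radius, m.
#' @return list with `total_mol_yr`, `total_pg_c_yr` (via the molar mass of
#'   carbon), `ocean_area_m2`, `mean_rate_mol_m2_yr`.
#' @export
integrate_global <- function(grid, fit, radius_m = 6371e3) {
  stopifnot(inherits(grid, "pic_grid"))
  area <- cell_areas(grid, radius_m)
  ocean <- grid$mask & !is.na(grid$annual)
  if (!any(ocean)) {
    warning("empty ocean mask; global integral is zero")
    return(list(total_mol_yr = 0, total_pg_c_yr = 0,
                ocean_area_m2 = 0, mean_rate_mol_m2_yr = NA_real_))
  }
  pred <- pmax(0, fit$intercept + fit$slope * grid$annual[ocean])
  a <- area[ocean]
  total <- sum(pred * a)
  list(total_mol_yr = total,
       total_pg_c_yr = total * M_C / 1e15,
       ocean_area_m2 = sum(a),
       mean_rate_mol_m2_yr = total / sum(a))
}

#' Low-PIC area fraction and minimum global production estimate
#'
#' Fraction of the ocean surface whose annual-mean PIC is below a threshold,
#' and the minimum global production it implies when the low-PIC area is
#' assigned station-like production rates (the remaining high-PIC area is
#' assumed to produce at least as much and is ignored).
#'
#' @param grid a [pic_grid()].
#' @param threshold_mg_m3 low-PIC threshold (default 10 mg m-3).
#' @param station_rates_mol_m2_yr production rates observed at low-PIC
#'   stations, mol m-2 yr-1.
#' @param radius_m Earth radius, m.
#' @return list with `fraction` (of ocean area below threshold),
#'   `ocean_area_m2`, `estimates_mol_yr` (one per supplied rate) and
#'   `mean_estimate_mol_yr`.
#' @export
low_pic_minimum <- function(grid, threshold_mg_m3 = 10,
                            station_rates_mol_m2_yr = numeric(),
                            radius_m = 6371e3) {
  stopifnot(inherits(grid, "pic_grid"))
  area <- cell_areas(grid, radius_m)
  ocean <- grid$mask & !is.na(grid$annual)
  ocean_area <- sum(area[ocean])
  low <- ocean & grid$annual < threshold_mg_m3
  fraction <- sum(area[low]) / ocean_area
  est <- fraction * ocean_area * station_rates_mol_m2_yr
  list(fraction = fraction, ocean_area_m2 = ocean_area,
       estimates_mol_yr = est,
       mean_estimate_mol_yr = if (length(est)) mean(est) else NA_real_)
}

#' Unit conversions for carbonate budgets
#'
#' `mol_to_PgC`: mol CaCO3 yr-1 to Pg C yr-1 (x 12.011 g/mol / 1e15);
#' `mmolCaCO3_to_mg`: mmol m-3 to mg m-3 (x 100.09);
#' `mgCaCO3_to_mol`: mg to mol (/ 100.09 / 1e3).
#'
#' @param value non-negative value(s) to convert.
#' @param kind conversion name.
#' @return converted value(s).
#' @export
convert_units <- function(value, kind = c("mol_to_PgC", "mmolCaCO3_to_mg",
                                          "mgCaCO3_to_mol")) {
  kind <- match.arg(kind)
  if (any(value < 0)) stop("value must be >= 0", call. = FALSE)
  switch(kind,
         mol_to_PgC = value * M_C / 1e15,
         mmolCaCO3_to_mg = value * M_CACO3,
         mgCaCO3_to_mol = value / M_CACO3 / 1e3)
}
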