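# volumetric and depth-integrated standing stocks per taxon and station

#' Volume of water sampled by an oblique net tow
#'
#' Net mouth area times the distance travelled through the water as recorded
#' by a flowmeter.
#'
#' @param net_diameter_m net mouth diameter, m (cruise default 0.5).
#' @param flow_distance_m flowmeter distance, m; must be > 0.
#' @return sampled volume, m^3.
#' @export
tow_volume <- function(net_diameter_m = 0.5, flow_distance_m) {
  if (missing(flow_distance_m) || any(!is.finite(flow_distance_m))) {
    stop("flowmeter distance is required", call. = FALSE)
  }
  assert_positive(flow_distance_m, "flowmeter distance")
  assert_positive(net_diameter_m, "net diameter")
  pi * (net_diameter_m / 2)^2 * flow_distance_m
}

#' Standing stock from a net tow
#'
#' Converts per-individual CaCO3 masses into a volumetric concentration
#' (mg m-3) and a depth-integrated areal stock (mg m-2). Counts are scaled
#' up by the analysed split fraction; the volumetric concentration is the
#' split-corrected total mass over the tow volume; the areal stock treats
#' the oblique tow as a column-integrating sampler, multiplying the mean
#' concentration by the maximum tow depth.
#'
#' @param caco3_mg per-individual CaCO3 masses, mg (one entry per record).
#' @param count individuals per record (default 1 each).
#' @param split_fraction fraction of the tow analysed, in (0, 1].
#' @param volume_m3 tow volume from [tow_volume()], m^3.
#' @param max_depth_m maximum tow depth, m.
#' @return list with `volumetric` (mg m-3) and `areal` (mg m-2). An empty
#'   record set is a valid zero stock.
#' @export
tow_standing_stock <- function(caco3_mg, count = rep(1, length(caco3_mg)),
                               split_fraction, volume_m3, max_depth_m) {
  if (split_fraction <= 0 || split_fraction > 1) {
    stop("split_fraction must be in (0, 1]", call. = FALSE)
  }
  assert_positive(volume_m3, "tow volume")
  assert_positive(max_depth_m, "max tow depth")
  total <- if (length(caco3_mg) == 0L) 0 else sum(count * caco3_mg) / split_fraction
  volumetric <- total / volume_m3
  list(volumetric = volumetric, areal = volumetric * max_depth_m)
}

#' Lower integration bound from a fluorescence profile
#'
#' The production layer's lower bound is the shallowest depth below the
#' fluorescence maximum where fluorescence falls to 1% of its peak, linearly
#' interpolated between cast sample depths. If fluorescence never falls
#' below the threshold within the profile, the deepest sample is returned.
#'
#' @param depth_m sample depths, m, strictly increasing.
#' @param fluorescence fluorescence values at those depths.
#' @param frac threshold as a fraction of the peak (default 0.01).
#' @return lower bound depth, m.
#' @export
fluor_lower_bound <- function(depth_m, fluorescence, frac = 0.01) {
  stopifnot(length(depth_m) == length(fluorescence), length(depth_m) >= 2)
  if (is.unsorted(depth_m, strictly = TRUE)) stop("depths must be strictly increasing")
  peak <- max(fluorescence)
  ipk <- which.max(fluorescence)
  thr <- frac * peak
  below <- seq_along(depth_m) > ipk & fluorescence <= thr
  if (!any(below)) return(depth_m[length(depth_m)])
  j <- which(below)[1L]
  # interpolate between the last sample above threshold and this one
  d0 <- depth_m[j - 1L]; f0 <- fluorescence[j - 1L]
  d1 <- depth_m[j]; f1 <- fluorescence[j]
  if (f0 == f1) return(d1)
  d0 + (thr - f0) * (d1 - d0) / (f1 - f0)
}

#' Depth-integrate a concentration profile
#'
#' Trapezoidal integration of a bottle-cast concentration profile (mg m-3)
#' over depth, from the first (shallowest) sample down to the lesser of the
#' deepest sample and `lower_bound_m` (e.g. the 1%-of-fluorescence-peak
#' depth). The profile is never extrapolated above the first sample or below
#' the last; if the bound falls between samples the profile is linearly
#' interpolated at the bound.
#'
#' @param depth_m sample depths, m, strictly increasing (>= 2 points).
#' @param value_mg_m3 concentrations at those depths, >= 0.
#' @param lower_bound_m lower integration bound, m (default: deepest sample).
#' @param station optional station id used in error messages.
#' @return areal stock, mg m-2.
#' @export
integrate_profile <- function(depth_m, value_mg_m3,
                              lower_bound_m = max(depth_m), station = NULL) {
  if (length(depth_m) < 2L) {
    stop(sprintf("profile%s has fewer than 2 depths; cannot integrate",
                 if (is.null(station)) "" else paste0(" at station ", station)),
         call. = FALSE)
  }
  stopifnot(length(depth_m) == length(value_mg_m3))
  if (is.unsorted(depth_m, strictly = TRUE)) stop("depths must be strictly increasing")
  if (any(value_mg_m3 < 0)) stop("profile values must be >= 0")
  zmax <- min(max(depth_m), lower_bound_m)
  if (zmax <= min(depth_m)) return(0)
  keep <- depth_m <= zmax
  z <- depth_m[keep]
  v <- value_mg_m3[keep]
  if (zmax != z[length(z)]) {
    v_at <- stats::approx(depth_m, value_mg_m3, xout = zmax)$y
    z <- c(z, zmax)
    v <- c(v, v_at)
  }
  pracma::trapz(z, v)
}
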