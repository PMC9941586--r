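# synthetic study data with known ground truth for every pipeline input:
# net-tow shell counts, foraminiferal weighings, coccolithophore filter
# counts, basin biomass compilations, satellite PIC climatologies and
# sediment-trap fluxes

#' Configuration for the synthetic study generators
#'
#' Defaults emulate a subtropical-to-subpolar transect: total standing
#' stocks rising from ~700 to ~4500 mg CaCO3 m-2, per-taxon shares of
#' 79/14/6/1% (coccolithophores / pteropods / foraminifera / heteropods),
#' lognormal shell-length distributions per family, Gaussian-in-depth
#' coccolithophore profiles shoaling poleward, ~7% zero-inflated lognormal
#' biomass compilations, and a low-subtropical / high-subpolar satellite
#' PIC field with an August maximum at high latitude and 87% of the ocean
#' below 10 mg m-3.
#'
#' @param seed integer seed; all generators are bit-reproducible given
#'   (seed, config).
#' @param n_stations number of survey stations.
#' @param latitudes station latitudes, deg N.
#' @param total_stock_mg_m2 per-station total CaCO3 standing stock truth.
#' @param shares named per-taxon share vector summing to 1.
#' @param pteropod_family_split,heteropod_family_split named splits of the
#'   pteropod/heteropod stock across shell families.
#' @param shell_meanlog,shell_sdlog named lognormal shell-length parameters
#'   (mm) per family.
#' @param cocco_peak_depth_m peak depths of the coccolithophore profile at
#'   the first and last station (linearly interpolated in between).
#' @param cocco_width_m Gaussian width of the profile, m.
#' @param lith_table a [coccolith_mass_table()].
#' @param residence_days_true loose-coccolith residence time used to scale
#'   loose-coccolith stocks.
#' @param maredat_n,maredat_meanlog,maredat_sdlog,zero_fraction,n_outliers
#'   biomass-compilation parameters (carbon biomass, mg C m-3).
#' @param pic_low,pic_high,low_area_fraction,seasonal_amp_high satellite
#'   climatology parameters (mg m-3; area fraction below threshold;
#'   high-latitude seasonal amplitude).
#' @param grid_step grid spacing, degrees.
#' @param export_efficiency_true trap flux / production truth.
#' @param trap_noise_sd lognormal sd of trap-flux noise (0 = exact).
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_stations = 5,
                         latitudes = seq(22.75, 50.1, length.out = n_stations),
                         total_stock_mg_m2 = exp(seq(log(700), log(4500),
                                                     length.out = n_stations)),
                         shares = c(coccolithophore = 0.79, pteropod = 0.14,
                                    foraminifera = 0.06, heteropod = 0.01),
                         pteropod_family_split = c(Limacinidae = 0.7,
                                                   Cavoliniidae = 0.2,
                                                   Cymbuliidae = 0.1),
                         heteropod_family_split = c(Atlantidae = 0.5,
                                                    Carinidae = 0.5),
                         shell_meanlog = c(Cavoliniidae = log(1.5),
                                           Carinidae = log(2),
                                           Limacinidae = log(0.5),
                                           Cymbuliidae = log(2),
                                           Atlantidae = log(1.5)),
                         shell_sdlog = c(Cavoliniidae = 0.4, Carinidae = 0.3,
                                         Limacinidae = 0.4, Cymbuliidae = 0.4,
                                         Atlantidae = 0.3),
                         cocco_peak_depth_m = c(110, 30),
                         cocco_width_m = 25,
                         lith_table = coccolith_mass_table(),
                         residence_days_true = 8,
                         maredat_n = 1793,
                         maredat_meanlog = log(0.22),
                         maredat_sdlog = 1.2,
                         zero_fraction = 0.067,
                         n_outliers = 0,
                         pic_low = 5, pic_high = 80,
                         low_area_fraction = 0.87,
                         seasonal_amp_high = 0.8,
                         grid_step = 2,
                         export_efficiency_true = 0.2,
                         trap_noise_sd = 0) {
  stopifnot(abs(sum(shares) - 1) < 1e-9, zero_fraction >= 0, zero_fraction < 1,
            all(total_stock_mg_m2 >= 0), length(latitudes) == n_stations,
            length(total_stock_mg_m2) == n_stations)
  structure(as.list(environment()), class = "synth_config")
}

# draw individuals of one family until their cumulative split-level mass
# reaches the target (keeps realized stock within one individual of truth)
#' @noRd
.draw_family_shells <- function(family, target_split_mass_mg, cfg) {
  if (target_split_mass_mg <= 0) {
    return(data.frame(family = character(), length_mm = numeric(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  ml <- cfg$shell_meanlog[[family]]
  sl <- cfg$shell_sdlog[[family]]
  lengths <- numeric(0)
  total <- 0
  mean_mass <- mean(suppressWarnings(
    shell_caco3(family, stats::qlnorm(seq(0.05, 0.95, 0.1), ml, sl))))
  while (total < target_split_mass_mg) {
    need <- ceiling((target_split_mass_mg - total) / mean_mass * 1.1) + 10
    L <- stats::rlnorm(need, ml, sl)
    m <- suppressWarnings(shell_caco3(family, L))
    cm <- total + cumsum(m)
    stop_at <- which(cm >= target_split_mass_mg)
    if (length(stop_at)) {
      j <- stop_at[1L]
      before <- if (j > 1L) cm[j - 1L] else total
      # keep the overshooting individual with probability such that the
      # expected realized mass equals the target (matters for taxa whose
      # per-individual mass is comparable to the target)
      keep_last <- stats::runif(1) < (target_split_mass_mg - before) / m[j]
      take <- if (keep_last) j else j - 1L
      lengths <- c(lengths, L[seq_len(take)])
      total <- target_split_mass_mg  # terminate either way
    } else {
      lengths <- c(lengths, L)
      total <- cm[need]
    }
  }
  data.frame(family = rep(family, length(lengths)), length_mm = lengths,
             count = rep(1L, length(lengths)), stringsAsFactors = FALSE)
}

#' Generate a synthetic station survey
#'
#' Emits, for each station, a net-tow record (geometry, flowmeter distance,
#' split fraction), shell records for the gastropod families, foraminiferal
#' weighings, coccolithophore filter counts along a Niskin profile (with
#' loose coccoliths), and a fluorescence profile — drawn so that running the
#' biomass-conversion and standing-stock stages recovers the configured
#' per-taxon stocks. A machine-readable truth record (configured and
#' realized stocks) is returned alongside; downstream recovery tests should
#' read truth only from it.
#'
#' @param cfg a [synth_config()].
#' @return list with `stations` (each holding `tow`, `shells`, `forams`,
#'   `filters`, `fluor`) and `truth`.
#' @export
gen_station_survey <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stage_seed(cfg$seed, "station_survey"))
  lith <- cfg$lith_table
  sphere_mass_pg <- lith$coccoliths_per_sphere[1] * lith$coccolith_mass_pg[1]
  stations <- vector("list", cfg$n_stations)
  truth <- vector("list", cfg$n_stations)
  for (s in seq_len(cfg$n_stations)) {
    lat <- cfg$latitudes[s]
    frac_north <- if (cfg$n_stations > 1) (s - 1) / (cfg$n_stations - 1) else 0
    max_depth <- round(300 - 150 * frac_north)           # 300 m -> 150 m
    flow_distance <- stats::runif(1, 1.8, 2.8) * max_depth
    split <- sample(c(0.5, 0.25, 0.125), 1)
    volume <- tow_volume(0.5, flow_distance)
    targets <- cfg$shares * cfg$total_stock_mg_m2[s]

    # gastropods: counts drawn so split-level mass matches the areal target
    shells <- list()
    fam_targets <- c(targets[["pteropod"]] * cfg$pteropod_family_split,
                     targets[["heteropod"]] * cfg$heteropod_family_split)
    for (fam in names(fam_targets)) {
      tgt <- fam_targets[[fam]] * volume * split / max_depth
      shells[[fam]] <- .draw_family_shells(fam, tgt, cfg)
    }
    shells <- do.call(rbind, shells)
    rownames(shells) <- NULL
    realized_mass <- function(fams) {
      if (nrow(shells) == 0) return(0)
      i <- shells$family %in% fams
      sum(suppressWarnings(shell_caco3(shells$family[i], shells$length_mm[i])) *
            shells$count[i])
    }
    ptero_real <- realized_mass(names(cfg$pteropod_family_split)) /
      split / volume * max_depth
    hetero_real <- realized_mass(names(cfg$heteropod_family_split)) /
      split / volume * max_depth

    # foraminifera: two size classes weighed from the analysed split
    foram_split_mass <- targets[["foraminifera"]] * volume * split / max_depth
    w_small <- 0.45 * foram_split_mass
    w_large <- foram_split_mass - w_small
    forams <- data.frame(size_class = c("lt125", "ge125"),
                         total_weight_mg = c(w_small, w_large),
                         count = c(round(w_small / 0.002), round(w_large / 0.006)),
                         split_fraction = split, stringsAsFactors = FALSE)
    foram_real <- foram_caco3(forams$total_weight_mg, forams$split_fraction) /
      volume * max_depth

    # coccolithophores: Gaussian profile scaled so the integral over the
    # production layer equals the target, then converted back to counts
    zpk <- cfg$cocco_peak_depth_m[1] +
      (cfg$cocco_peak_depth_m[2] - cfg$cocco_peak_depth_m[1]) * frac_north
    depths <- seq(5, 175, by = 10)
    fluor_z <- seq(0, 250, by = 5)
    fluor <- exp(-(fluor_z - zpk)^2 / (2 * cfg$cocco_width_m^2))
    lb <- fluor_lower_bound(fluor_z, fluor)
    g <- exp(-(depths - zpk)^2 / (2 * cfg$cocco_width_m^2))
    base_int <- integrate_profile(depths, g, lower_bound_m = lb)
    scale <- targets[["coccolithophore"]] / base_int
    prof <- g * scale                                    # mg m-3
    # loose-coccolith stock = residence x expected daily coccosphere production
    # E[1/tau] for tau = 1/rate, rate ~ U(a, b), is E[rate] = (a + b)/2
    p <- taxon_params()$coccolithophore
    e_inv_tau <- mean(p$division_rate_range)
    loose_target <- cfg$residence_days_true * targets[["coccolithophore"]] * e_inv_tau
    loose_prof <- g / base_int * loose_target
    A <- stats::runif(length(depths), 0.35, 3.14)
    V <- stats::runif(length(depths), 2.1, 6.0)
    F_mm2 <- rep(1000, length(depths))
    conc_cells <- prof / (sphere_mass_pg * 1e3 * 1e-9)
    conc_liths <- loose_prof / (lith$coccolith_mass_pg[1] * 1e3 * 1e-9)
    filters <- data.frame(depth_m = depths, F_mm2 = F_mm2, A_mm2 = A, V_L = V,
                          species = lith$species[1],
                          coccosphere_count = round(conc_cells * A * V / F_mm2),
                          loose_coccolith_count = round(conc_liths * A * V / F_mm2),
                          stringsAsFactors = FALSE)
    # realized profile after count rounding
    conc_real <- cocco_concentration(filters$coccosphere_count, F_mm2, A, V)
    prof_real <- cocco_caco3(conc_real, filters$species, lith, "coccosphere")
    cocco_real <- integrate_profile(depths, prof_real, lower_bound_m = lb)
    loose_real <- integrate_profile(
      depths,
      cocco_caco3(cocco_concentration(filters$loose_coccolith_count, F_mm2, A, V),
                  filters$species, lith, "loose_coccolith"),
      lower_bound_m = lb)

    stations[[s]] <- list(
      tow = data.frame(station = s, latitude = lat, net_diameter_m = 0.5,
                       flow_distance_m = flow_distance, max_depth_m = max_depth,
                       split_fraction = split),
      shells = cbind(station = rep(s, nrow(shells)), shells),
      forams = cbind(station = s, forams),
      filters = cbind(station = s, filters),
      fluor = data.frame(station = s, depth_m = fluor_z, fluorescence = fluor)
    )
    truth[[s]] <- list(
      station = s, latitude = lat,
      configured = as.list(targets),
      realized = list(coccolithophore = cocco_real, pteropod = ptero_real,
                      foraminifera = foram_real, heteropod = hetero_real),
      loose_coccolith_mg_m2 = loose_real,
      residence_days_true = cfg$residence_days_true,
      fluor_lower_bound_m = lb,
      volume_m3 = volume, split_fraction = split, max_depth_m = max_depth
    )
  }
  list(stations = stations, truth = truth)
}

#' Generate a basin biomass compilation with known truth
#'
#' Zero-inflated lognormal carbon biomass records (mg C m-3) with uniform
#' depths across the production layer (a small fraction deeper, to exercise
#' the depth filter) and optional planted outliers far above the 3-sigma
#' threshold.
#'
#' @param cfg a [synth_config()].
#' @return list with `records` (data.frame: latitude, longitude, depth_m,
#'   mg_C_m3, month) and `truth` (median, meanlog/sdlog, zero fraction,
#'   planted outlier values, realized skewness of the in-layer sample).
#' @export
gen_maredat_like <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stage_seed(cfg$seed, "maredat_like"))
  n <- cfg$maredat_n
  v <- stats::rlnorm(n, cfg$maredat_meanlog, cfg$maredat_sdlog)
  zero <- stats::runif(n) < cfg$zero_fraction
  v[zero] <- 0
  depth <- stats::runif(n, 5, 250)
  deep <- stats::runif(n) < 0.03
  depth[deep] <- stats::runif(sum(deep), 251, 1000)
  outlier_values <- numeric(0)
  if (cfg$n_outliers > 0) {
    in_layer <- v[depth <= 250]
    out_val <- mean(in_layer) + 8 * stats::sd(in_layer)
    idx <- sample(which(depth <= 250), cfg$n_outliers)
    v[idx] <- out_val
    outlier_values <- rep(out_val, cfg$n_outliers)
  }
  records <- data.frame(
    latitude = stats::runif(n, 20, 60), longitude = stats::runif(n, 140, 235),
    depth_m = depth, mg_C_m3 = v, month = sample.int(12, n, replace = TRUE))
  list(records = records,
       truth = list(median_carbon_mg_m3 = exp(cfg$maredat_meanlog),
                    meanlog = cfg$maredat_meanlog, sdlog = cfg$maredat_sdlog,
                    zero_fraction = cfg$zero_fraction,
                    outlier_values = outlier_values,
                    skewness_in_layer = sample_skewness(v[depth <= 250])))
}

#' Generate a synthetic satellite PIC climatology
#'
#' Monthly global PIC grids (mg CaCO3 m-3) with a low-PIC subtropical
#' regime, high-PIC polar bands and a high-PIC subpolar North Pacific bloom
#' patch covering the northernmost survey stations (so the station-level PIC
#' predictor varies, as in a real transect ending in a bloom region). The
#' low/high assignment is cell-exact: non-patch cells are filled low-first
#' by increasing |latitude| until the configured fraction of the ocean area
#' lies below the 10 mg m-3 threshold, so the realized fraction matches the
#' configured one to within a single grid cell. A seasonal cycle with an
#' August maximum grows poleward (its annual mean equals the base field),
#' and winter retrievals are missing poleward of 66 deg.
#'
#' @param cfg a [synth_config()].
#' @param station_lon longitude of the survey transect, deg E.
#' @return list with `grid` (a [pic_grid()]), `station_pic` (data.frame of
#'   per-station August and annual PIC and the implied seasonal bias
#'   factor), and `truth` (base field, realized low-PIC area fraction,
#'   configured fraction, patch bounds).
#' @export
gen_pic_climatology <- function(cfg = synth_config(), station_lon = -155) {
  stopifnot(inherits(cfg, "synth_config"))
  lat <- seq(-90 + cfg$grid_step / 2, 90 - cfg$grid_step / 2, by = cfg$grid_step)
  lon <- seq(-180 + cfg$grid_step / 2, 180 - cfg$grid_step / 2, by = cfg$grid_step)
  nlat <- length(lat); nlon <- length(lon)
  latm <- matrix(lat, nlat, nlon)
  lonm <- matrix(lon, nlat, nlon, byrow = TRUE)
  patch <- latm >= 45 & latm <= 62 & lonm >= -170 & lonm <= -145
  # cell-exact low/high assignment: fill low-first by |lat| until the
  # configured area fraction is reached (one-cell granularity)
  band <- sin(pmin(lat + cfg$grid_step / 2, 90) * pi / 180) -
    sin(pmax(lat - cfg$grid_step / 2, -90) * pi / 180)
  aream <- matrix(band / nlon, nlat, nlon)   # fraction of sphere per cell
  base <- matrix(cfg$pic_high, nlat, nlon)
  ord <- order(abs(latm[!patch]))
  free <- which(!patch)[ord]
  cum <- cumsum(aream[free]) / sum(aream)
  base[free[cum <= cfg$low_area_fraction]] <- cfg$pic_low
  amp <- cfg$seasonal_amp_high * pmax(0, (abs(lat) - 20) / 70)
  vals <- array(NA_real_, dim = c(nlat, nlon, 12))
  for (m in 1:12) {
    month_fac <- 1 + amp * cos(pi * (m - 8) / 6)
    vals[, , m] <- base * month_fac
  }
  for (m in c(12, 1, 2)) vals[lat > 66, , m] <- NA_real_
  for (m in c(6, 7, 8)) vals[lat < -66, , m] <- NA_real_
  grid <- pic_grid(lat, lon, vals)
  area <- cell_areas(grid)
  low <- grid$annual < 10 & grid$mask
  realized_fraction <- sum(area[low]) / sum(area[grid$mask])
  i_lat <- vapply(cfg$latitudes, function(la) which.min(abs(lat - la)), 0L)
  i_lon <- which.min(abs(lon - station_lon))
  august <- grid$values[cbind(i_lat, i_lon, 8L)]
  annual <- grid$annual[cbind(i_lat, i_lon)]
  station_pic <- data.frame(station = seq_len(cfg$n_stations),
                            latitude = cfg$latitudes,
                            august_pic = august, annual_pic = annual,
                            bias_factor = august / annual)
  list(grid = grid, station_pic = station_pic,
       truth = list(base = base,
                    low_fraction_realized = realized_fraction,
                    configured_low_fraction = cfg$low_area_fraction,
                    patch = c(lat_min = 45, lat_max = 62,
                              lon_min = -170, lon_max = -145)))
}

#' Generate synthetic sediment-trap fluxes
#'
#' Trap flux = production x export efficiency (x lognormal noise), with an
#' aragonite fraction decreasing linearly northwards.
#'
#' @param cfg a [synth_config()].
#' @param production_mol_m2_yr per-station annual production truth.
#' @param depth_m trap depth recorded in the table.
#' @return data.frame (station, depth_m, flux_mol_m2_yr, aragonite_fraction)
#'   plus attribute `efficiency_true`.
#' @export
gen_trap_fluxes <- function(cfg = synth_config(), production_mol_m2_yr,
                            depth_m = 200) {
  stopifnot(inherits(cfg, "synth_config"),
            length(production_mol_m2_yr) == cfg$n_stations)
  set.seed(stage_seed(cfg$seed, "trap_fluxes"))
  noise <- if (cfg$trap_noise_sd > 0) {
    exp(stats::rnorm(cfg$n_stations, 0, cfg$trap_noise_sd))
  } else rep(1, cfg$n_stations)
  arag <- stats::approx(c(22.75, 60), c(0.30, 0.05), xout = cfg$latitudes,
                        rule = 2)$y
  out <- data.frame(station = seq_len(cfg$n_stations), depth_m = depth_m,
                    flux_mol_m2_yr = production_mol_m2_yr *
                      cfg$export_efficiency_true * noise,
                    aragonite_fraction = arag)
  attr(out, "efficiency_true") <- cfg$export_efficiency_true
  out
}
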