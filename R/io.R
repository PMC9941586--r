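# delimited-text I/O, validation and end-to-end pipeline orchestration

#' @noRd
.read_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s (%s): missing required column(s) %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(sprintf("%s: ignoring unknown column(s) %s", what,
                    paste(extra, collapse = ", ")))
  }
  df[required]
}

#' Read pipeline input tables
#'
#' CSV readers with schema validation: a missing required column fails fast
#' naming the file and column; unknown columns are dropped with a warning.
#' Both LF and CRLF files are accepted.
#'
#' @param path path to a CSV file.
#' @return a validated data.frame.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_tow_table <- function(path) {
  .read_checked(path, c("station", "latitude", "net_diameter_m",
                        "flow_distance_m", "max_depth_m", "split_fraction"),
                "tow table")
}

#' @rdname read_tables
#' @export
read_shell_records <- function(path) {
  df <- .read_checked(path, c("station", "family", "length_mm", "count"),
                      "shell records")
  if (any(df$length_mm <= 0)) stop("shell records: length_mm must be > 0")
  df
}

#' @rdname read_tables
#' @export
read_filter_counts <- function(path) {
  df <- .read_checked(path, c("station", "depth_m", "F_mm2", "A_mm2", "V_L",
                              "species", "coccosphere_count",
                              "loose_coccolith_count"),
                      "filter counts")
  if (any(df$A_mm2 <= 0) || any(df$V_L <= 0)) {
    stop("filter counts: A_mm2 and V_L must be > 0")
  }
  df
}

#' @rdname read_tables
#' @export
read_foram_weighings <- function(path) {
  .read_checked(path, c("station", "size_class", "total_weight_mg", "count",
                        "split_fraction"), "foram weighings")
}

#' @rdname read_tables
#' @export
read_fluor_profiles <- function(path) {
  .read_checked(path, c("station", "depth_m", "fluorescence"),
                "fluorescence profiles")
}

#' @rdname read_tables
#' @export
read_trap_fluxes <- function(path) {
  .read_checked(path, c("station", "depth_m", "flux_mol_m2_yr",
                        "aragonite_fraction"), "trap fluxes")
}

#' @rdname read_tables
#' @export
read_biomass_records <- function(path) {
  .read_checked(path, c("latitude", "longitude", "depth_m", "mg_C_m3",
                        "month"), "biomass records")
}

#' Write a synthetic input bundle to a directory
#'
#' Runs the synthetic generators and writes every pipeline input as CSV
#' (tows, shells, forams, filters, fluorescence, biomass compilation, trap
#' fluxes, station satellite PIC) plus `truth.json` with the generator
#' ground truth. The satellite grid itself is regenerated from the config
#' at analysis time rather than serialized.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
simulate_bundle <- function(cfg = synth_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  survey <- gen_station_survey(cfg)
  clim <- gen_pic_climatology(cfg)
  mar <- gen_maredat_like(cfg)
  bind <- function(field) do.call(rbind, lapply(survey$stations, `[[`, field))
  utils::write.csv(bind("tow"), file.path(dir, "tows.csv"), row.names = FALSE)
  utils::write.csv(bind("shells"), file.path(dir, "shells.csv"), row.names = FALSE)
  utils::write.csv(bind("forams"), file.path(dir, "forams.csv"), row.names = FALSE)
  utils::write.csv(bind("filters"), file.path(dir, "filters.csv"), row.names = FALSE)
  utils::write.csv(bind("fluor"), file.path(dir, "fluorescence.csv"), row.names = FALSE)
  utils::write.csv(mar$records, file.path(dir, "biomass_records.csv"), row.names = FALSE)
  utils::write.csv(clim$station_pic, file.path(dir, "station_pic.csv"), row.names = FALSE)
  # trap fluxes scale from the expected annualized production truth:
  # E[1/tau] is ln(b/a)/(b-a) for flat turnover priors and (a+b)/2 for the
  # coccolithophore division-rate prior
  pp <- taxon_params()
  e_inv <- c(
    coccolithophore = mean(pp$coccolithophore$division_rate_range),
    pteropod = log(pp$pteropod$turnover_range[2] / pp$pteropod$turnover_range[1]) /
      diff(pp$pteropod$turnover_range),
    foraminifera = log(pp$foraminifera$turnover_range[2] /
                         pp$foraminifera$turnover_range[1]) /
      diff(pp$foraminifera$turnover_range),
    heteropod = log(pp$heteropod$turnover_range[2] / pp$heteropod$turnover_range[1]) /
      diff(pp$heteropod$turnover_range))
  prod_truth <- vapply(seq_along(survey$truth), function(s) {
    tr <- survey$truth[[s]]
    sp <- clim$station_pic[s, ]
    bias <- c(coccolithophore = sp$bias_factor, foraminifera = sp$bias_factor,
              pteropod = seasonal_bias("pteropod", latitude_deg = tr$latitude)$factor,
              heteropod = seasonal_bias("heteropod", latitude_deg = tr$latitude)$factor)
    daily <- unlist(tr$configured)[names(e_inv)] * e_inv
    sum(daily * 365 / bias[names(e_inv)]) / M_CACO3 / 1e3
  }, 0)
  traps <- gen_trap_fluxes(cfg, prod_truth)
  utils::write.csv(traps, file.path(dir, "trap_fluxes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config_seed = cfg$seed, stations = survey$truth,
         maredat = mar$truth, climatology = clim$truth,
         export_efficiency_true = cfg$export_efficiency_true),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Standing stocks for every station and taxon from input tables
#'
#' Applies the biomass-conversion and standing-stock stages: gastropod
#' shells through the length-allometry carbon chain and tow normalization,
#' foraminiferal weighings through split scaling, and coccolithophore
#' filter counts through the filter-geometry equation and trapezoidal depth
#' integration bounded by the 1%-of-fluorescence-peak depth.
#'
#' @param tows,shells,forams,filters,fluor validated input data.frames (see
#'   [read_tables]).
#' @param lith_table a [coccolith_mass_table()].
#' @return tidy data.frame: station, taxon, mineral, volumetric (mg m-3,
#'   tow mean or profile mean), areal (mg m-2).
#' @export
compute_stocks <- function(tows, shells, forams, filters, fluor,
                           lith_table = coccolith_mass_table()) {
  ptero_fams <- c("Cavoliniidae", "Cymbuliidae", "Limacinidae")
  hetero_fams <- c("Atlantidae", "Carinidae")
  out <- list()
  for (s in tows$station) {
    tw <- tows[tows$station == s, ]
    vol <- tow_volume(tw$net_diameter_m, tw$flow_distance_m)
    sh <- shells[shells$station == s, ]
    stock_of <- function(fams) {
      i <- sh$family %in% fams
      m <- if (any(i)) shell_caco3(sh$family[i], sh$length_mm[i]) else numeric(0)
      tow_standing_stock(m, sh$count[i], tw$split_fraction, vol, tw$max_depth_m)
    }
    pt <- stock_of(ptero_fams)
    ht <- stock_of(hetero_fams)
    fo <- forams[forams$station == s, ]
    fo_total <- foram_caco3(fo$total_weight_mg, fo$split_fraction)
    fo_vol <- fo_total / vol
    fl <- fluor[fluor$station == s, ]
    lb <- fluor_lower_bound(fl$depth_m, fl$fluorescence)
    fi <- filters[filters$station == s, ]
    fi <- fi[order(fi$depth_m), ]
    conc <- cocco_concentration(fi$coccosphere_count, fi$F_mm2, fi$A_mm2, fi$V_L)
    prof <- cocco_caco3(conc, fi$species, lith_table, "coccosphere")
    cocco_areal <- integrate_profile(fi$depth_m, prof, lower_bound_m = lb,
                                     station = s)
    loose_prof <- cocco_caco3(
      cocco_concentration(fi$loose_coccolith_count, fi$F_mm2, fi$A_mm2, fi$V_L),
      fi$species, lith_table, "loose_coccolith")
    loose_areal <- integrate_profile(fi$depth_m, loose_prof, lower_bound_m = lb,
                                     station = s)
    out[[length(out) + 1L]] <- data.frame(
      station = s,
      taxon = c("coccolithophore", "loose_coccolith", "foraminifera",
                "pteropod", "heteropod"),
      mineral = c("calcite", "calcite", "calcite", "aragonite", "aragonite"),
      volumetric = c(mean(prof), mean(loose_prof), fo_vol,
                     pt$volumetric, ht$volumetric),
      areal = c(cocco_areal, loose_areal, fo_vol * tw$max_depth_m,
                pt$areal, ht$areal),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Run the full accounting pipeline on an input bundle
#'
#' Orchestrates conversion -> standing stocks -> Monte-Carlo daily and
#' seasonally corrected annual production -> taxon/mineral shares ->
#' (optional) compilation statistics -> (optional) global extrapolation ->
#' (optional) export comparison, writing tidy CSV outputs and a JSON run
#' manifest (config, seed, package version) into `out_dir`. Identical
#' (inputs, config, seed) give identical outputs.
#'
#' @param input_dir directory written by [simulate_bundle()] (or holding
#'   equivalently named CSVs).
#' @param out_dir output directory.
#' @param n_draws Monte-Carlo draws per taxon and station.
#' @param seed integer run seed (mandatory).
#' @param cfg optional [synth_config()] used to regenerate the satellite
#'   grid for the global stage; `NULL` skips that stage with a message.
#' @param params [taxon_params()] variant.
#' @return list with the per-stage results, invisibly; files in `out_dir`.
#' @export
run_pipeline <- function(input_dir, out_dir, n_draws = 10000, seed,
                         cfg = NULL, params = taxon_params()) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tows <- read_tow_table(file.path(input_dir, "tows.csv"))
  shells <- read_shell_records(file.path(input_dir, "shells.csv"))
  forams <- read_foram_weighings(file.path(input_dir, "forams.csv"))
  filters <- read_filter_counts(file.path(input_dir, "filters.csv"))
  fluor <- read_fluor_profiles(file.path(input_dir, "fluorescence.csv"))
  station_pic <- utils::read.csv(file.path(input_dir, "station_pic.csv"))

  stocks <- compute_stocks(tows, shells, forams, filters, fluor)
  utils::write.csv(stocks, file.path(out_dir, "stocks.csv"), row.names = FALSE)

  taxa <- c("coccolithophore", "pteropod", "foraminifera", "heteropod")
  prod_rows <- list()
  annual_by_station <- numeric(nrow(tows))
  daily_dists <- list()
  annual_dists <- list()
  for (s in tows$station) {
    lat <- tows$latitude[tows$station == s]
    sp <- station_pic[station_pic$station == s, ]
    per_taxon_daily <- list()
    per_taxon_annual <- list()
    for (tx in taxa) {
      areal <- stocks$areal[stocks$station == s & stocks$taxon == tx]
      tau <- draw_turnover(tx, n_draws, seed = seed + s, params = params)
      daily <- production_distribution(areal, tau, taxon = tx, station = s)
      bias <- switch(tx,
        coccolithophore = seasonal_bias(tx, sp$august_pic, sp$annual_pic),
        foraminifera = seasonal_bias(tx, sp$august_pic, sp$annual_pic),
        seasonal_bias(tx, latitude_deg = lat))
      annual <- annualize(daily, bias)
      per_taxon_daily[[tx]] <- daily
      per_taxon_annual[[tx]] <- annual
      qd <- daily$summary$percentiles
      qa <- annual$summary$percentiles
      prod_rows[[length(prod_rows) + 1L]] <- data.frame(
        station = s, taxon = tx, bias_factor = bias$factor,
        daily_p50 = qd[["p50"]], daily_p16 = qd[["p16"]], daily_p84 = qd[["p84"]],
        annual_p50 = qa[["p50"]], annual_p2.5 = qa[["p2.5"]],
        annual_p97.5 = qa[["p97.5"]], stringsAsFactors = FALSE)
    }
    daily_dists[[as.character(s)]] <- per_taxon_daily
    annual_dists[[as.character(s)]] <- per_taxon_annual
    total_annual <- Reduce(`+`, lapply(per_taxon_annual, `[[`, "samples"))
    annual_by_station[s] <- stats::median(total_annual)
  }
  production <- do.call(rbind, prod_rows)
  utils::write.csv(production, file.path(out_dir, "production.csv"),
                   row.names = FALSE)

  shares <- lapply(daily_dists, taxon_fractions)

  global <- NULL
  if (!is.null(cfg)) {
    clim <- gen_pic_climatology(cfg)
    fit <- fit_pic_regression(annual_by_station, station_pic$annual_pic)
    global <- c(integrate_global(clim$grid, fit),
                list(fit = coef(fit),
                     low_pic = low_pic_minimum(clim$grid, 10,
                                               annual_by_station)))
    jsonlite::write_json(global[c("total_mol_yr", "total_pg_c_yr", "fit")],
                         file.path(out_dir, "global.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    message("no climatology config supplied; skipping the global stage")
  }

  comparison <- NULL
  trap_path <- file.path(input_dir, "trap_fluxes.csv")
  if (file.exists(trap_path)) {
    traps <- read_trap_fluxes(trap_path)
    comparison <- do.call(rbind, lapply(tows$station, function(s) {
      tr <- traps[traps$station == s, ]
      eff <- export_efficiency(annual_by_station[s], tr$flux_mol_m2_yr[1])
      data.frame(station = s, production_mol_m2_yr = annual_by_station[s],
                 trap_flux_mol_m2_yr = tr$flux_mol_m2_yr[1],
                 exported_pct = eff$exported_pct,
                 remineralised_pct = eff$remineralised_pct)
    }))
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  }

  manifest <- list(seed = seed, n_draws = n_draws,
                   package_version = as.character(utils::packageVersion("pelagicarb")),
                   inputs = basename(list.files(input_dir,
                                                pattern = "\\.(csv|json)$")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(stocks = stocks, production = production, shares = shares,
                 daily = daily_dists, annual = annual_dists,
                 annual_total_by_station = annual_by_station,
                 global = global, comparison = comparison))
}
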