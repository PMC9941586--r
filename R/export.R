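# production versus sediment-trap export fluxes

#' Export efficiency of pelagic CaCO3
#'
#' Fraction of the produced CaCO3 that is exported past a trap depth,
#' trap flux / production, with its complement (the fraction remineralised
#' in the photic zone) and the production/export ratio. Both inputs must be
#' in the same annual units (mol m-2 yr-1); daily trap fluxes can be
#' annualized with `x 365` beforehand.
#'
#' @param production_mol_m2_yr annual production.
#' @param trap_flux_mol_m2_yr annual trap flux at the reference depth.
#' @return list with `exported_pct`, `remineralised_pct`,
#'   `production_to_export_ratio`; all `NA` when production is zero.
#' @export
export_efficiency <- function(production_mol_m2_yr, trap_flux_mol_m2_yr) {
  if (any(trap_flux_mol_m2_yr < 0)) stop("trap flux must be >= 0", call. = FALSE)
  if (production_mol_m2_yr <= 0) {
    return(list(exported_pct = NA_real_, remineralised_pct = NA_real_,
                production_to_export_ratio = NA_real_))
  }
  frac <- trap_flux_mol_m2_yr / production_mol_m2_yr
  list(exported_pct = 100 * frac,
       remineralised_pct = 100 * (1 - frac),
       production_to_export_ratio = production_mol_m2_yr / trap_flux_mol_m2_yr)
}

#' Aragonite fraction of production versus export
#'
#' Produced aragonite fraction = (pteropod + heteropod) / total per matched
#' Monte-Carlo draw, summarized as median and 95% CI; the exported fraction
#' is passed through from trap mineralogy (XRD) unchanged.
#'
#' @param per_taxon named list of `production_dist` objects (or named
#'   numeric vector) for one station; aragonite taxa are `pteropod` and
#'   `heteropod`.
#' @param trap_aragonite_fraction aragonite fraction measured in the trap,
#'   in \[0, 1\] (optional).
#' @return list with `produced` (p2.5/p50/p97.5, as fractions in \[0, 1\])
#'   and `exported` (the trap value, or `NA`).
#' @export
aragonite_fractions <- function(per_taxon, trap_aragonite_fraction = NA_real_) {
  if (!is.na(trap_aragonite_fraction) &&
      (trap_aragonite_fraction < 0 || trap_aragonite_fraction > 1)) {
    stop("trap aragonite fraction must be in [0, 1]", call. = FALSE)
  }
  fr <- taxon_fractions(per_taxon)
  list(produced = fr$aragonite / 100,
       exported = trap_aragonite_fraction)
}

#' Residence time of loose coccoliths in the production layer
#'
#' Loose-coccolith standing stock divided by whole-coccosphere CaCO3
#' production. With a Monte-Carlo production distribution the division is
#' propagated over the draws.
#'
#' @param loose_stock_mg_m2 loose-coccolith standing stock, mg m-2.
#' @param coccosphere_production production, either a `production_dist`
#'   (mg m-2 d-1) or a positive scalar.
#' @return for scalar production, residence time in days; for a
#'   distribution, list with `samples` and `summary` (percentiles + mode).
#'   `NA` when production is zero.
#' @export
coccolith_residence_time <- function(loose_stock_mg_m2, coccosphere_production) {
  if (loose_stock_mg_m2 < 0) stop("loose stock must be >= 0", call. = FALSE)
  if (inherits(coccosphere_production, "production_dist")) {
    s <- coccosphere_production$samples
    if (all(s <= 0)) return(NA_real_)
    res <- loose_stock_mg_m2 / s
    return(list(samples = res, summary = dist_summary(res)))
  }
  if (coccosphere_production <= 0) return(NA_real_)
  loose_stock_mg_m2 / coccosphere_production
}
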