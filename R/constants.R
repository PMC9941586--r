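# molar masses (g mol-1) used at reporting boundaries
M_CACO3 <- 100.09
M_C <- 12.011

#' Carbon-chain conversion parameters
#'
#' Constants linking shell length regressions to CaCO3 mass: wet weight is
#' converted to dry weight (`ww_to_dw`), dry weight to particulate organic
#' carbon (`dw_to_poc`), POC to particulate inorganic carbon through the
#' PIC:POC ratio, and PIC to CaCO3 mass via the molar-mass ratio
#' M(CaCO3)/M(C) = 8.33.
#'
#' The default `pic_poc_ratio` treats the 0.27:0.73 PIC:POC partition as
#' fractions of total carbon, i.e. PIC = POC x (0.27/0.73). For heteropods
#' the published range is 0.28-0.45; `heteropod_chain()` uses its midpoint.
#'
#' @param ww_to_dw dry weight per wet weight (dimensionless).
#' @param dw_to_poc POC per dry weight (dimensionless).
#' @param pic_poc_ratio PIC mass per POC mass (dimensionless).
#' @param caco3_per_pic mg CaCO3 per mg PIC.
#' @return a list of class `caco3_chain`.
#' @export
caco3_chain <- function(ww_to_dw = 0.28, dw_to_poc = 0.25,
                        pic_poc_ratio = 0.27 / 0.73, caco3_per_pic = 8.33) {
  assert_positive(c(ww_to_dw, dw_to_poc, pic_poc_ratio, caco3_per_pic),
                  "carbon-chain factors")
  if (abs(caco3_per_pic - round(M_CACO3 / M_C, 2)) > 0.005) {
    warning("caco3_per_pic differs from the molar-mass ratio M(CaCO3)/M(C)")
  }
  structure(list(ww_to_dw = ww_to_dw, dw_to_poc = dw_to_poc,
                 pic_poc_ratio = pic_poc_ratio, caco3_per_pic = caco3_per_pic),
            class = "caco3_chain")
}

#' @rdname caco3_chain
#' @export
heteropod_chain <- function() caco3_chain(pic_poc_ratio = (0.28 + 0.45) / 2)

#' Per-taxon turnover and PIC:POC parameter ranges
#'
#' Flat-prior parameter ranges for the four calcifying groups: turnover time
#' (days) for pteropods, heteropods and foraminifera; cell-division rate
#' (d-1) for coccolithophores, whose turnover is the reciprocal of the rate;
#' and PIC:POC mass-ratio ranges used for carbon-to-CaCO3 conversion.
#'
#' Foraminiferal turnover defaults to 14-28 d; the alternative 10-30 d
#' variant is selected with `foram_turnover = "wide"`.
#'
#' @param foram_turnover `"narrow"` (14-28 d, default) or `"wide"` (10-30 d).
#' @return named list of per-taxon parameter lists.
#' @export
taxon_params <- function(foram_turnover = c("narrow", "wide")) {
  foram_turnover <- match.arg(foram_turnover)
  ft <- if (foram_turnover == "narrow") c(14, 28) else c(10, 30)
  list(
    coccolithophore = list(division_rate_range = c(0.1, 1.5),
                           pic_poc_range = c(0.19, 2.08)),
    pteropod        = list(turnover_range = c(5, 16),
                           pic_poc_range = c(0.20, 0.56)),
    heteropod       = list(turnover_range = c(5, 16),
                           pic_poc_range = c(0.28, 0.45)),
    foraminifera    = list(turnover_range = ft,
                           pic_poc_range = c(3, 6))
  )
}

#' Coccolith mass lookup table
#'
#' Per-species coccoliths-per-coccosphere counts and single-coccolith calcite
#' masses (pg CaCO3). These are configuration data, not constants of the
#' method: defaults are editable placeholders for a generic bloom-forming
#' species and should be replaced with literature values per assemblage.
#' A YAML file with the same structure can be supplied instead
#' (see [read_coccolith_table()]).
#'
#' @param species character vector of species names.
#' @param coccoliths_per_sphere integer coccoliths per intact coccosphere.
#' @param coccolith_mass_pg single coccolith mass, pg CaCO3.
#' @return data.frame with one row per species.
#' @export
coccolith_mass_table <- function(species = "Emiliania huxleyi",
                                 coccoliths_per_sphere = 20,
                                 coccolith_mass_pg = 2.5) {
  stopifnot(length(species) == length(coccoliths_per_sphere),
            length(species) == length(coccolith_mass_pg))
  assert_positive(coccoliths_per_sphere, "coccoliths_per_sphere")
  assert_positive(coccolith_mass_pg, "coccolith_mass_pg")
  data.frame(species = species,
             coccoliths_per_sphere = coccoliths_per_sphere,
             coccolith_mass_pg = coccolith_mass_pg,
             stringsAsFactors = FALSE)
}

#' Read a coccolith mass table from a YAML config file
#'
#' The file holds one section per species with keys `coccoliths_per_sphere`
#' and `coccolith_mass_pg`.
#'
#' @param path path to a YAML file.
#' @return data.frame as from [coccolith_mass_table()].
#' @export
read_coccolith_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  coccolith_mass_table(
    species = names(cfg),
    coccoliths_per_sphere = vapply(cfg, function(x) as.numeric(x$coccoliths_per_sphere), 0),
    coccolith_mass_pg = vapply(cfg, function(x) as.numeric(x$coccolith_mass_pg), 0)
  )
}
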