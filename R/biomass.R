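# shell-length allometry and per-individual CaCO3 conversion for
# aragonitic gastropods (pteropods + heteropods)

# one coefficient set per family; forms:
#   power_WW          WW = a * L^b  (mg wet weight), enters the carbon chain at WW
#   power_DW          DW = a * L^b  (mg dry weight), enters at DW
#   linear_DW         DW = a * L + c, enters at DW (clamped at 0)
#   exponential_CaCO3 CaCO3 = a * exp(b * L) directly (ash-weight fit), no chain
.allometry <- data.frame(
  family = c("Cavoliniidae", "Carinidae", "Limacinidae", "Cymbuliidae", "Atlantidae"),
  form   = c("power_WW", "power_WW", "power_DW", "linear_DW", "exponential_CaCO3"),
  a      = c(0.2152, 0.0888, 0.1365, 0.0392, 0.769),
  b      = c(2.293, 2.161, 1.501, NA, 0.0023),
  c      = c(NA, NA, NA, -0.003, NA),
  stringsAsFactors = FALSE
)

#' Allometric coefficients for shelled gastropod families
#'
#' Returns the length-to-biomass regression coefficients for one of the five
#' shelled gastropod families handled by the package. Pteropods are
#' Cavoliniidae (wet-weight power law), Limacinidae (dry-weight power law)
#' and Cymbuliidae (linear dry-weight fit); heteropods are Carinidae
#' (wet-weight power law) and Atlantidae (direct exponential CaCO3 fit on
#' ash weights).
#'
#' @param family one of `"Cavoliniidae"`, `"Carinidae"`, `"Limacinidae"`,
#'   `"Cymbuliidae"`, `"Atlantidae"`.
#' @return one-row data.frame with columns `family`, `form`, `a`, `b`, `c`.
#' @export
allometric_coeffs <- function(family) {
  i <- match(family, .allometry$family)
  if (anyNA(i)) {
    stop("unknown family: ", paste(family[is.na(i)], collapse = ", "),
         " (expected one of ", paste(.allometry$family, collapse = ", "), ")",
         call. = FALSE)
  }
  .allometry[i, , drop = FALSE]
}

#' Shell length to CaCO3 mass for pteropods and heteropods
#'
#' Converts shell length (mm) to CaCO3 mass per individual (mg). Power and
#' linear fits give wet or dry weight, which is carried through the carbon
#' chain WW -> DW (x0.28) -> POC (x0.25) -> PIC (xPIC:POC) -> CaCO3 (x8.33);
#' the Atlantidae exponential fit returns CaCO3 directly. Vectorized over
#' `family` and `length_mm`.
#'
#' @param family family name(s), see [allometric_coeffs()].
#' @param length_mm shell length(s), mm; must be > 0.
#' @param chain a [caco3_chain()]; if `NULL`, the pteropod default chain is
#'   used for pteropod families and [heteropod_chain()] for Carinidae.
#' @param atlantidae_length_scale multiplier applied to L inside the
#'   Atlantidae exponential, so lengths tabulated in other units can be used
#'   without editing the fit. Default 1 (length in mm, as published).
#' @return mg CaCO3 per individual, same length as the inputs. Negative
#'   linear dry weights (tiny Cymbuliidae juveniles) are clamped to zero with
#'   a warning.
#' @export
shell_caco3 <- function(family, length_mm, chain = NULL,
                        atlantidae_length_scale = 1) {
  if (any(!is.finite(length_mm)) || any(length_mm <= 0)) {
    stop("shell length must be finite and > 0 (mm)", call. = FALSE)
  }
  n <- max(length(family), length(length_mm))
  family <- rep_len(family, n)
  length_mm <- rep_len(length_mm, n)
  allometric_coeffs(unique(family))  # validate family names up front
  out <- numeric(n)
  clamped <- FALSE
  for (fam in unique(family)) {
    i <- which(family == fam)
    co <- allometric_coeffs(fam)
    ch <- chain %||% if (fam == "Carinidae") heteropod_chain() else caco3_chain()
    L <- length_mm[i]
    out[i] <- switch(co$form,
      power_WW = co$a * L^co$b *
        ch$ww_to_dw * ch$dw_to_poc * ch$pic_poc_ratio * ch$caco3_per_pic,
      power_DW = co$a * L^co$b *
        ch$dw_to_poc * ch$pic_poc_ratio * ch$caco3_per_pic,
      linear_DW = {
        dw <- co$a * L + co$c
        if (any(dw < 0)) {
          clamped <- TRUE
          dw <- pmax(dw, 0)
        }
        dw * ch$dw_to_poc * ch$pic_poc_ratio * ch$caco3_per_pic
      },
      exponential_CaCO3 = co$a * exp(co$b * L * atlantidae_length_scale)
    )
  }
  if (clamped) {
    warning("negative linear dry weight clamped to 0 (shell below fit support)")
  }
  out
}

#' Coccolithophore cell concentration from a filter count
#'
#' Concentration (cells per litre) from polarized-light microscopy counts:
#' `F * C / (A * V)` with `F` the effective filtration area (mm^2), `C` the
#' number of coccospheres (or loose coccoliths) counted, `A` the investigated
#' filter area (mm^2) and `V` the filtered seawater volume (L).
#'
#' @param count coccospheres (or coccoliths) counted on the investigated area.
#' @param effective_area_mm2 effective filtration area F, mm^2.
#' @param counted_area_mm2 investigated filter area A, mm^2; must satisfy
#'   `0 < A <= F`.
#' @param volume_l filtered seawater volume V, litres; must be > 0.
#' @return cells (or coccoliths) per litre.
#' @export
cocco_concentration <- function(count, effective_area_mm2, counted_area_mm2,
                                volume_l) {
  assert_positive(counted_area_mm2, "counted area A")
  assert_positive(volume_l, "filtered volume V")
  assert_positive(effective_area_mm2, "effective filtration area F")
  if (any(counted_area_mm2 > effective_area_mm2)) {
    stop("counted area A exceeds effective filtration area F", call. = FALSE)
  }
  if (any(count < 0)) stop("counts must be >= 0", call. = FALSE)
  as.numeric(effective_area_mm2) * as.numeric(count) /
    (counted_area_mm2 * volume_l)
}

#' Coccolithophore calcite concentration
#'
#' Converts a cell (coccosphere) or loose-coccolith concentration into mg
#' CaCO3 m-3 using a per-species coccolith mass table. In `"coccosphere"`
#' mode the cell concentration is multiplied by coccoliths-per-sphere and the
#' single-coccolith mass; in `"loose_coccolith"` mode the concentration is
#' already in coccoliths per litre and only the mass applies. Unit factors:
#' 1e3 L m-3 and 1e-9 mg pg-1.
#'
#' @param concentration_per_l cells/L (`"coccosphere"`) or coccoliths/L
#'   (`"loose_coccolith"`).
#' @param species species name, looked up in `table`.
#' @param table a [coccolith_mass_table()].
#' @param mode `"coccosphere"` or `"loose_coccolith"`.
#' @return mg CaCO3 m-3.
#' @export
cocco_caco3 <- function(concentration_per_l, species,
                        table = coccolith_mass_table(),
                        mode = c("coccosphere", "loose_coccolith")) {
  mode <- match.arg(mode)
  i <- match(species, table$species)
  if (anyNA(i)) {
    stop("species missing from coccolith mass table: ",
         paste(unique(species[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  per_lith <- table$coccolith_mass_pg[i]
  mult <- if (mode == "coccosphere") table$coccoliths_per_sphere[i] else 1
  concentration_per_l * mult * per_lith * 1e3 * 1e-9
}

#' Foraminiferal CaCO3 per tow from picked weights
#'
#' Total CaCO3 mass (mg) represented by a tow, from microbalance weights of
#' picked foraminifera in analysed splits. Test weight is taken as pure
#' CaCO3 (dry cytoplasm mass is negligible); each split's weight is scaled
#' by its split fraction.
#'
#' @param total_weight_mg weights of picked splits, mg; >= 0.
#' @param split_fraction fraction of the tow each weighing represents,
#'   in (0, 1].
#' @return total mg CaCO3 per tow (0 for no weighings).
#' @export
foram_caco3 <- function(total_weight_mg, split_fraction) {
  if (length(total_weight_mg) == 0L) return(0)
  if (any(split_fraction <= 0) || any(split_fraction > 1)) {
    stop("split_fraction must be in (0, 1]", call. = FALSE)
  }
  if (any(total_weight_mg < 0)) stop("weights must be >= 0", call. = FALSE)
  sum(total_weight_mg / split_fraction)
}
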