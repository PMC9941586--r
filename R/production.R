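# standing stock -> daily and annual CaCO3 production with flat-prior
# turnover-time uncertainty propagated by Monte-Carlo simulation

#' Draw turnover times from a flat prior
#'
#' Turnover time (typical individual lifespan, days) is sampled uniformly on
#' the per-taxon range. Coccolithophore turnover is sampled on the cell
#' division rate (uniform on `division_rate_range`, d-1) and inverted, so
#' the rate, not the lifespan, carries the flat prior.
#'
#' @param taxon one of `"coccolithophore"`, `"pteropod"`, `"heteropod"`,
#'   `"foraminifera"`.
#' @param n number of draws.
#' @param seed integer seed (mandatory, for reproducibility).
#' @param params parameter set from [taxon_params()].
#' @return numeric vector of `n` turnover times, days.
#' @export
draw_turnover <- function(taxon, n, seed, params = taxon_params()) {
  stopifnot(n >= 1, !missing(seed))
  p <- params[[taxon]]
  if (is.null(p)) stop("no parameters configured for taxon: ", taxon, call. = FALSE)
  set.seed(stage_seed(seed, paste0("turnover_", taxon)))
  if (!is.null(p$division_rate_range)) {
    r <- stats::runif(n, p$division_rate_range[1], p$division_rate_range[2])
    1 / r
  } else if (!is.null(p$turnover_range)) {
    stats::runif(n, p$turnover_range[1], p$turnover_range[2])
  } else {
    stop("no turnover or division-rate range for taxon: ", taxon, call. = FALSE)
  }
}

#' Monte-Carlo production distribution from a standing stock
#'
#' Daily CaCO3 production is standing stock divided by turnover time; the
#' flat-prior turnover samples propagate into a production sample set. For a
#' flat prior on \[a, b\] the expected production is
#' `stock * log(b/a) / (b - a)`.
#'
#' @param areal_stock_mg_m2 depth-integrated standing stock, mg CaCO3 m-2.
#' @param turnover_days turnover-time draws from [draw_turnover()].
#' @param taxon,station labels carried into the result.
#' @return object of class `production_dist` with elements `samples`
#'   (mg m-2 d-1), `summary` (percentiles 2.5/16/32/50/68/84/97.5 and mode),
#'   `taxon`, `station`, `n_draws`, `unit`.
#' @export
production_distribution <- function(areal_stock_mg_m2, turnover_days,
                                    taxon = NA_character_, station = NA) {
  if (areal_stock_mg_m2 < 0) stop("standing stock must be >= 0", call. = FALSE)
  assert_positive(turnover_days, "turnover time")
  samples <- areal_stock_mg_m2 / turnover_days
  structure(list(taxon = taxon, station = station, samples = samples,
                 n_draws = length(samples), summary = dist_summary(samples),
                 unit = "mg m-2 d-1"),
            class = "production_dist")
}

#' @export
print.production_dist <- function(x, ...) {
  cat(sprintf("Monte-Carlo CaCO3 production (%s)\n", x$unit))
  cat(sprintf("  taxon: %s  station: %s  draws: %d\n",
              x$taxon, as.character(x$station), x$n_draws))
  q <- x$summary$percentiles
  cat(sprintf("  median %.4g  (68%% CI %.4g-%.4g, 95%% CI %.4g-%.4g)\n",
              q[["p50"]], q[["p16"]], q[["p84"]], q[["p2.5"]], q[["p97.5"]]))
  invisible(x)
}

#' @export
summary.production_dist <- function(object, ...) {
  c(object$summary$percentiles, mode = object$summary$mode)
}

#' @export
plot.production_dist <- function(x, ...) {
  d <- stats::density(x$samples, from = max(0, min(x$samples)))
  graphics::plot(d, main = sprintf("CaCO3 production, %s", x$taxon),
                 xlab = x$unit, ...)
  graphics::abline(v = x$summary$percentiles[c("p16", "p50", "p84")],
                   lty = c(2, 1, 2), col = "grey40")
  invisible(x)
}

#' Seasonal bias factor for a sampling snapshot
#'
#' Ratio of conditions at the time of sampling to the annual mean, used to
#' deflate a snapshot production rate to an annual mean rate
#' (`annual = daily * 365 / factor`). Coccolithophores use satellite PIC
#' (sampling-month PIC over mean annual PIC), foraminifera satellite
#' chlorophyll, and pteropods/heteropods a zooplankton-seasonality factor
#' interpolated linearly in latitude between the subtropical (22.75 deg N,
#' summer/annual = 1.2) and subpolar (50.1 deg N, 2.0) time-series anchors,
#' clamped outside that range.
#'
#' @param taxon taxon name.
#' @param august_value proxy value at the time of sampling (PIC or
#'   chlorophyll, mg m-3); required for coccolithophores/foraminifera.
#' @param annual_mean_value annual-mean proxy value; must be > 0.
#' @param latitude_deg station latitude, deg N; required for
#'   pteropods/heteropods.
#' @return list with `taxon`, `factor`, `source`.
#' @export
seasonal_bias <- function(taxon, august_value = NULL, annual_mean_value = NULL,
                          latitude_deg = NULL) {
  if (taxon %in% c("pteropod", "heteropod")) {
    if (is.null(latitude_deg)) stop("latitude required for zooplankton seasonality")
    f <- stats::approx(x = c(22.75, 50.1), y = c(1.2, 2.0),
                       xout = latitude_deg, rule = 2)$y
    src <- "zooplankton_latitude"
  } else {
    if (is.null(august_value) || is.null(annual_mean_value)) {
      stop("sampling-time and annual-mean proxy values required for ", taxon)
    }
    if (annual_mean_value <= 0) stop("annual mean proxy must be > 0", call. = FALSE)
    f <- august_value / annual_mean_value
    src <- if (taxon == "coccolithophore") "satellite_PIC" else "satellite_chlorophyll"
  }
  if (any(f <= 0)) stop("seasonal bias factor must be > 0", call. = FALSE)
  list(taxon = taxon, factor = unname(f), source = src)
}

#' Annualize a daily production distribution
#'
#' Converts a daily production distribution (mg CaCO3 m-2 d-1) to annual
#' molar units: `annual = daily * 365 / bias_factor`, then mg CaCO3 -> mol
#' via the molar mass 100.09 g mol-1. The full sample set is annualized, not
#' just its summary.
#'
#' @param daily a `production_dist` in mg m-2 d-1.
#' @param bias a [seasonal_bias()] result (or a bare positive factor).
#' @return a `production_dist` in mol m-2 yr-1.
#' @export
annualize <- function(daily, bias = list(factor = 1)) {
  stopifnot(inherits(daily, "production_dist"))
  f <- if (is.list(bias)) bias$factor else bias
  assert_positive(f, "seasonal bias factor")
  samples <- daily$samples * 365 / f / M_CACO3 / 1e3
  structure(list(taxon = daily$taxon, station = daily$station,
                 samples = samples, n_draws = length(samples),
                 summary = dist_summary(samples), unit = "mol m-2 yr-1"),
            class = "production_dist")
}

#' Per-taxon shares of total stock or production
#'
#' Computes percentage shares per taxon from matched Monte-Carlo draws (one
#' draw per taxon per iteration, shared iteration index), so the share
#' distribution is coherent across taxa. Also returns the aragonite share
#' (pteropods + heteropods) versus calcite.
#'
#' @param per_taxon named list of `production_dist` objects (equal
#'   `n_draws`), or a named numeric vector of fixed values.
#' @return list with `draw_shares` (matrix, draws x taxa, percent),
#'   `summary` (median and 95% CI per taxon, percent), `aragonite`
#'   (median and 95% CI of the aragonite share, percent). Draws with zero
#'   total give `NA` shares and are excluded from summaries.
#' @export
taxon_fractions <- function(per_taxon) {
  if (is.numeric(per_taxon)) {
    per_taxon <- lapply(per_taxon, function(v)
      structure(list(samples = v, n_draws = 1L), class = "production_dist"))
  }
  stopifnot(length(names(per_taxon)) == length(per_taxon))
  mat <- vapply(per_taxon, function(p) p$samples,
                numeric(per_taxon[[1]]$n_draws))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, names(per_taxon)))
  tot <- rowSums(mat)
  shares <- 100 * mat / tot
  shares[tot == 0, ] <- NA_real_
  ok <- tot > 0
  summ <- apply(shares[ok, , drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.5, 0.975), names = FALSE)
  rownames(summ) <- c("p2.5", "p50", "p97.5")
  arag_taxa <- intersect(colnames(shares), c("pteropod", "heteropod"))
  arag <- rowSums(shares[, arag_taxa, drop = FALSE])
  arag_s <- stats::quantile(arag[ok], c(0.025, 0.5, 0.975), names = FALSE)
  list(draw_shares = shares,
       summary = summ,
       aragonite = c(p2.5 = arag_s[1], p50 = arag_s[2], p97.5 = arag_s[3]))
}
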