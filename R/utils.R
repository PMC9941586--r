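# internal helpers shared across stages

#' Derive a reproducible per-stage seed from a run seed
#'
#' Each pipeline stage draws from its own RNG stream keyed by (seed, stage),
#' so adding or reordering stages never perturbs another stage's draws.
#'
#' @param seed integer run seed.
#' @param stage character stage name.
#' @return an integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + 1000003 * h) %% .Machine$integer.max)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# percentile + mode summary used for Monte-Carlo sample sets;
# percentiles follow the reporting convention (68% CI = 16-84, 95% = 2.5-97.5,
# compilation-style 32/50/68)
#' @noRd
dist_summary <- function(samples) {
  probs <- c(0.025, 0.16, 0.32, 0.50, 0.68, 0.84, 0.975)
  q <- stats::quantile(samples, probs = probs, names = FALSE, type = 7)
  names(q) <- paste0("p", c("2.5", "16", "32", "50", "68", "84", "97.5"))
  if (length(unique(samples)) == 1L) {
    mode <- samples[1L]
  } else {
    d <- stats::density(samples, from = max(0, min(samples)), to = max(samples))
    mode <- d$x[which.max(d$y)]
  }
  list(percentiles = q, mode = unname(mode))
}

#' @noRd
assert_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("%s must be finite and > 0", what), call. = FALSE)
  }
  invisible(x)
}
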