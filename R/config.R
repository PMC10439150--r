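#' Pipeline configuration
#'
#' Collects the tunable settings of the continuous reference-interval
#' pipeline.  Defaults reproduce the published operating point: age groups of
#' at least 1000 members, base width growing by 1% of age in days, the seven
#' chart percentiles 2.5/10/25/50/75/90/97.5, 100 bootstrap replicates and
#' central 95% confidence bands, ages from birth to 18 years (6570 days).
#'
#' @param n_min Minimum number of (deduplicated) members per age group.
#' @param width_growth Base group width as a fraction of age in days.
#' @param percentile_probs Strictly increasing probabilities in (0, 1) for
#'   percentile tables.
#' @param bootstrap_B Number of bootstrap replicates.
#' @param ci_level Central coverage of the bootstrap confidence bands.
#' @param rng_seed Integer seed driving every random choice in the pipeline.
#' @param max_age_days Upper end of the modelled age range, in days.
#' @param families Candidate distribution families, a subset of
#'   `c("BCCG", "BCPE", "BCT")`.
#' @param bootstrap_refit_family If `TRUE`, each bootstrap replicate re-runs
#'   the BIC family selection; the default keeps the family selected on the
#'   full data, which is much cheaper and conditions the confidence bands on
#'   the selected model.
#' @return An object of class `ri_config` (a validated list).
#' @export
ri_config <- function(n_min = 1000,
                      width_growth = 0.01,
                      percentile_probs = c(0.025, 0.10, 0.25, 0.50,
                                           0.75, 0.90, 0.975),
                      bootstrap_B = 100,
                      ci_level = 0.95,
                      rng_seed = 1L,
                      max_age_days = 6570,
                      families = c("BCCG", "BCPE", "BCT"),
                      bootstrap_refit_family = FALSE) {
  stopifnot(n_min >= 1,
            width_growth > 0, width_growth < 1,
            all(percentile_probs > 0), all(percentile_probs < 1),
            !is.unsorted(percentile_probs, strictly = TRUE),
            bootstrap_B >= 1,
            ci_level > 0, ci_level < 1,
            max_age_days >= 1)
  families <- match.arg(families, c("BCCG", "BCPE", "BCT"),
                        several.ok = TRUE)
  structure(list(n_min = as.integer(n_min),
                 width_growth = width_growth,
                 percentile_probs = percentile_probs,
                 bootstrap_B = as.integer(bootstrap_B),
                 ci_level = ci_level,
                 rng_seed = as.integer(rng_seed),
                 max_age_days = as.integer(max_age_days),
                 families = families,
                 bootstrap_refit_family = isTRUE(bootstrap_refit_family)),
            class = "ri_config")
}

#' @export
print.ri_config <- function(x, ...) {
  cat("Continuous reference-interval pipeline configuration\n")
  cat(sprintf("  n_min: %d   width growth: %g   max age: %d days\n",
              x$n_min, x$width_growth, x$max_age_days))
  cat(sprintf("  families: %s\n", paste(x$families, collapse = ", ")))
  cat(sprintf("  percentiles: %s\n",
              paste(format(100 * x$percentile_probs), collapse = " ")))
  cat(sprintf("  bootstrap: B = %d, level = %g   seed: %d\n",
              x$bootstrap_B, x$ci_level, x$rng_seed))
  invisible(x)
}
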