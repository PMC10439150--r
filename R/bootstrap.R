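## Bootstrap confidence bands for the percentile curves.
##
## Measurement-level resampling with replacement; each replicate re-runs
## the pipeline (age partition, indirect fits, weighting -- with subject
## multiplicities recomputed inside the replicate -- and the weighted
## smooth-curve fit).  Cell-wise confidence bounds are the central
## `ci_level` region of the replicate percentile values, expanded where
## necessary to contain the point estimate from the full data.

#' Expand confidence bounds to contain the point estimate
#'
#' Bootstrap bands can be strongly asymmetric and occasionally exclude the
#' full-data estimate; each cell's bounds are widened to include it.
#'
#' @param ci_lower,ci_upper Bound matrices.
#' @param point_estimate Matrix of point estimates, same shape.
#' @return List with adjusted `ci_lower` and `ci_upper`.
#' @export
expand_ci_to_include <- function(ci_lower, ci_upper, point_estimate) {
  stopifnot(all(dim(ci_lower) == dim(point_estimate)),
            all(dim(ci_upper) == dim(point_estimate)))
  list(ci_lower = pmin(ci_lower, point_estimate),
       ci_upper = pmax(ci_upper, point_estimate))
}

## per-replicate seed: decoupled from replicate order so that replicate b
## always sees the same stream regardless of how many ran before it
.replicate_seed <- function(rng_seed, b)
  as.integer((as.numeric(rng_seed) + 1000003 * b) %% 2147483647)

#' Bootstrap confidence bands for percentile curves
#'
#' @param data The full `measurement_set`.
#' @param config An [ri_config()]; `bootstrap_B` replicates are drawn and
#'   the central `ci_level` region taken cell-wise.
#' @param point_model Optional fitted `ri_model` on the full data; fitted
#'   here if missing.  Its selected family (and smoothing, via warm start)
#'   is reused in the replicates unless `config$bootstrap_refit_family`.
#' @param ages Age grid for the confidence bands; defaults to 50
#'   log-spaced ages over the fitted range.
#' @param probs Percentile probabilities; default from `config`.
#' @param verbose Print replicate progress.
#' @return Object of class `ri_bootstrap`: `table` (a `percentile_table`
#'   with bands), `replicates` (array B x ages x probs with `NA` rows for
#'   failures), `n_failed`, `B`.
#' @export
bootstrap_percentile_ci <- function(data, config = ri_config(),
                                    point_model = NULL, ages = NULL,
                                    probs = NULL, verbose = FALSE) {
  stopifnot(config$bootstrap_B >= 2)
  if (is.null(point_model)) point_model <- ri_fit(data, config)
  if (is.null(probs)) probs <- config$percentile_probs
  rng <- point_model$model$age_range
  if (is.null(ages))
    ages <- unique(round(exp(seq(log(rng[1] + 1), log(rng[2] + 1),
                                 length.out = 50)) - 1))
  ages <- ages[ages >= rng[1] & ages <= rng[2]]
  point_tab <- predict_percentiles(point_model, ages, probs)

  B <- config$bootstrap_B
  reps <- array(NA_real_, dim = c(B, length(ages), length(probs)))
  n_failed <- 0L
  rep_cfg <- config
  if (!config$bootstrap_refit_family)
    rep_cfg$families <- point_model$model$family
  for (b in seq_len(B)) {
    set.seed(.replicate_seed(config$rng_seed, b))
    idx <- sample.int(nrow(data), replace = TRUE)
    bdat <- measurement_set(as.data.frame(data)[idx, , drop = FALSE],
                            analyte = attr(data, "analyte"),
                            unit = attr(data, "unit"))
    res <- tryCatch({
      groups <- build_age_groups(bdat, rep_cfg)
      models <- lapply(groups, function(g)
        tryCatch(fit_np_model(bdat$value[g$member_idx]),
                 error = function(e) NULL))
      w <- compute_weights(bdat, groups, models)
      fits <- lapply(rep_cfg$families, function(fam)
        tryCatch(fit_weighted_gamlss(
          bdat$age_days, bdat$value, w$p_corr, family = fam,
          init = if (fam == point_model$model$family)
            point_model$model else NULL,
          select_smoothing = rep_cfg$bootstrap_refit_family,
          rng_seed = .replicate_seed(config$rng_seed, b)),
          error = function(e) NULL))
      sel <- select_best_family(fits)
      ## clamp to the replicate's own fitted range; cells outside stay NA
      ok_age <- ages >= sel$age_range[1] & ages <= sel$age_range[2]
      out <- matrix(NA_real_, length(ages), length(probs))
      out[ok_age, ] <- predict_percentiles(sel, ages[ok_age], probs)$values
      out
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      if (verbose) message(sprintf("replicate %d/%d failed", b, B))
    } else {
      reps[b, , ] <- res
      if (verbose && b %% 10 == 0) message(sprintf("replicate %d/%d", b, B))
    }
  }
  if (n_failed > B / 2)
    stop(n_failed, " of ", B, " bootstrap replicates failed")

  alpha <- (1 - config$ci_level) / 2
  ci_lower <- apply(reps, c(2, 3), stats::quantile, probs = alpha,
                    na.rm = TRUE, names = FALSE)
  ci_upper <- apply(reps, c(2, 3), stats::quantile, probs = 1 - alpha,
                    na.rm = TRUE, names = FALSE)
  ex <- expand_ci_to_include(ci_lower, ci_upper, point_tab$values)
  tab <- percentile_table(ages, probs, point_tab$values,
                          ci_lower = ex$ci_lower, ci_upper = ex$ci_upper)
  structure(list(table = tab, replicates = reps, n_failed = n_failed,
                 B = B),
            class = "ri_bootstrap")
}

#' @export
print.ri_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap confidence bands: B = %d (%d failed)\n",
              x$B, x$n_failed))
  print(x$table)
  invisible(x)
}
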