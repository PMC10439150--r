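## The four-step pipeline: age partition -> per-group indirect fits ->
## density-ratio weights -> weighted smooth-curve estimation with family
## selection.

#' Fit a continuous reference-interval model
#'
#' Runs the full automated pipeline on a measurement set: (1) overlapping
#' high-resolution age groups, (2) a Box-Cox-normal indirect fit of the
#' non-pathological distribution per group, (3) one smoothed density-ratio
#' weight per measurement (corrected for repeated samples per subject),
#' and (4) weighted penalized estimation of smooth age-dependent
#' distribution parameters for each candidate family, with the final
#' family selected by BIC.
#'
#' @param data A `measurement_set` (see [read_measurements()] or
#'   [generate_dataset()]); the pipeline is intended to run on a single
#'   sex stratum.
#' @param config An [ri_config()].
#' @param verbose Print per-stage progress.
#' @return An object of class `ri_model`.
#' @export
ri_fit <- function(data, config = ri_config(), verbose = FALSE) {
  stopifnot(inherits(data, "data.frame"), nrow(data) > 0)
  if (!inherits(data, "measurement_set")) data <- measurement_set(data)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))
  timings <- c()

  say("step 1/4: building age groups ...")
  groups <- build_age_groups(data, config)
  timings["age_partition"] <- proc.time()[["elapsed"]] - t0

  say("step 2/4: indirect non-pathological fits for %d groups ...",
      length(groups))
  t1 <- proc.time()[["elapsed"]]
  models <- vector("list", length(groups))
  n_failed <- 0L
  for (k in seq_along(groups)) {
    vals <- data$value[groups[[k]]$member_idx]
    models[[k]] <- tryCatch(fit_np_model(vals), error = function(e) NULL)
    if (is.null(models[[k]])) n_failed <- n_failed + 1L
  }
  if (n_failed > 0L)
    say("  %d group fit(s) failed and will be skipped", n_failed)
  timings["indirect_fits"] <- proc.time()[["elapsed"]] - t1

  say("step 3/4: assigning probability weights ...")
  t2 <- proc.time()[["elapsed"]]
  weights <- compute_weights(data, groups, models)
  timings["weighting"] <- proc.time()[["elapsed"]] - t2

  say("step 4/4: weighted smooth-curve fits (%s) ...",
      paste(config$families, collapse = ", "))
  t3 <- proc.time()[["elapsed"]]
  fits <- list()
  for (fam in config$families) {
    fits[[fam]] <- tryCatch(
      fit_weighted_gamlss(data$age_days, data$value, weights$p_corr,
                          family = fam, rng_seed = config$rng_seed),
      error = function(e) {
        say("  %s fit failed: %s", fam, conditionMessage(e))
        NULL
      })
    if (!is.null(fits[[fam]]))
      say("  %s: BIC %.1f (edf %.1f)", fam, fits[[fam]]$bic,
          fits[[fam]]$edf_total)
  }
  selected <- select_best_family(fits)
  timings["continuous_fit"] <- proc.time()[["elapsed"]] - t3

  np_table <- do.call(rbind, lapply(seq_along(groups), function(k) {
    m <- models[[k]]
    if (is.null(m)) return(NULL)
    data.frame(center = groups[[k]]$center, lambda = m$lambda, mu = m$mu,
               sigma = m$sigma, np_fraction = m$np_fraction,
               n = length(groups[[k]]$member_idx))
  }))
  family_bic <- data.frame(
    family = names(fits),
    bic = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic, 1),
    edf = vapply(fits, function(f) if (is.null(f)) NA_real_ else
      f$edf_total, 1),
    converged = vapply(fits, function(f) if (is.null(f)) NA else
      f$converged, NA))
  rownames(family_bic) <- NULL

  structure(list(model = selected,
                 family_bic = family_bic,
                 data = data,
                 weights = weights,
                 groups = groups,
                 np_models = models,
                 np_table = np_table,
                 config = config,
                 analyte = attr(data, "analyte") %||% "",
                 unit = attr(data, "unit") %||% "",
                 n_measurements = nrow(data),
                 n_groups = length(groups),
                 n_group_fits_failed = n_failed,
                 timings = timings,
                 call = match.call()),
            class = "ri_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the pipeline end to end with file outputs
#'
#' Reads (or takes) a measurement set, fits the continuous model, and
#' writes the selected model (JSON), the percentile table, the per-
#' measurement weight audit table, and a run manifest to `output_dir`.
#' With `bootstrap = TRUE`, a confidence-band-augmented percentile table
#' is written as well.
#'
#' @param input A file path readable by [read_measurements()] or a
#'   `measurement_set`.
#' @param output_dir Output directory (created if needed).
#' @param config An [ri_config()].
#' @param column_map,sex_filter Passed to [read_measurements()] when
#'   `input` is a path.
#' @param bootstrap Also compute bootstrap confidence bands.
#' @param verbose Print stage progress.
#' @return Invisibly, the run manifest (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(input, output_dir, config = ri_config(),
                         column_map = c(value = "value",
                                        age_days = "age_days",
                                        sex = "sex",
                                        subject_id = "subject_id"),
                         sex_filter = NULL, bootstrap = FALSE,
                         verbose = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  data <- if (inherits(input, "data.frame")) {
    if (!inherits(input, "measurement_set")) measurement_set(input)
    else input
  } else {
    read_measurements(input, column_map = column_map,
                      sex_filter = sex_filter)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- ri_fit(data, config, verbose = verbose)

  model_path <- file.path(output_dir, "model.json")
  save_ri_model(fit, model_path)
  ages <- seq(max(0L, fit$model$age_range[1]), fit$model$age_range[2])
  tab <- predict_percentiles(fit, ages, config$percentile_probs)
  table_path <- file.path(output_dir, "percentiles.tsv")
  write_percentile_table(tab, table_path)
  audit_path <- file.path(output_dir, "weighted_data.tsv")
  audit <- data.frame(value = data$value, age_days = data$age_days,
                      subject_id = data$subject_id,
                      p_raw = fit$weights$p_raw,
                      p_corr = fit$weights$p_corr)
  utils::write.table(audit, audit_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outputs <- c(model = model_path, percentiles = table_path,
               weighted_data = audit_path)

  boot_failed <- NA_integer_
  if (bootstrap) {
    bs <- bootstrap_percentile_ci(data, config, point_model = fit,
                                  ages = ages, verbose = verbose)
    ci_path <- file.path(output_dir, "percentiles_ci.tsv")
    write_percentile_table(bs$table, ci_path)
    outputs["percentiles_ci"] <- ci_path
    boot_failed <- bs$n_failed
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("refcurve")),
    seed = config$rng_seed,
    config = unclass(config),
    n_measurements = fit$n_measurements,
    n_groups = fit$n_groups,
    n_group_fits_failed = fit$n_group_fits_failed,
    n_unweighted = sum(!is.finite(fit$weights$p_corr)),
    selected_family = fit$model$family,
    bic = fit$model$bic,
    bootstrap_failed_replicates = boot_failed,
    timings = as.list(fit$timings),
    total_seconds = proc.time()[["elapsed"]] - t0,
    outputs = as.list(outputs))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(output_dir, "manifest.json"))
  invisible(manifest)
}
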