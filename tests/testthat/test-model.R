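# end-to-end fit on a compact dataset, reused across the method tests
.model_env <- new.env(parent = emptyenv())
small_ri_model <- function() {
  if (is.null(.model_env$fit)) {
    sc <- ri_scenario("alp_like", n_total = 4000,
                      pathological_fraction = 0.1, seed = 81,
                      max_age_days = 2000)
    d <- generate_dataset(sc)
    cfg <- ri_config(n_min = 500, width_growth = 0.1, rng_seed = 81,
                     max_age_days = 2000, families = "BCCG")
    .model_env$fit <- quiet(ri_fit(d, cfg))
    .model_env$data <- d
  }
  .model_env$fit
}

test_that("the pipeline assigns exactly one weight per measurement", {
  fit <- small_ri_model()
  expect_equal(nrow(fit$weights), fit$n_measurements)
  expect_true(all(fit$weights$p_raw >= 0 & fit$weights$p_raw <= 1))
  expect_true(all(fit$weights$p_corr <= fit$weights$p_raw + 1e-12))
  expect_equal(fit$weights$p_corr,
               fit$weights$p_raw / fit$weights$n_subject)
})

test_that("model methods print, summarise, predict and simulate", {
  fit <- small_ri_model()
  expect_output(print(fit), "Continuous reference-interval model")
  expect_output(summary(fit), "Candidate families")
  cf <- coef(fit)
  expect_true(all(c("mu", "sigma", "lambda") %in% names(cf)))
  tab <- predict(fit, ages = c(10, 100, 1000))
  expect_s3_class(tab, "percentile_table")
  expect_equal(ncol(tab$values), 7)       # the default chart percentiles
  z <- residuals(fit)
  expect_length(z, fit$n_measurements)
  sim <- simulate(fit, nsim = 2, seed = 9, ages = c(50, 500))
  expect_equal(nrow(sim), 4)
  expect_true(all(sim$value > 0))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("high-weight residual z-scores are close to standard normal", {
  fit <- small_ri_model()
  z <- as.numeric(residuals(fit))
  keep <- fit$weights$p_raw > 0.9 & is.finite(z)
  expect_lt(abs(mean(z[keep])), 0.2)
  expect_lt(abs(sd(z[keep]) - 1), 0.2)
})

test_that("serialized models reload and predict identically", {
  fit <- small_ri_model()
  path <- tempfile(fileext = ".json")
  save_ri_model(fit, path)
  back <- load_ri_model(path)
  ages <- c(5, 50, 500, 1500)
  expect_equal(predict_percentiles(back, ages)$values,
               predict_percentiles(fit, ages)$values, tolerance = 1e-12)
  expect_equal(back$bic, fit$model$bic)
})

test_that("run_pipeline writes the four stage outputs and a manifest", {
  out <- tempfile("run")
  d <- .model_env$data
  cfg <- ri_config(n_min = 500, width_growth = 0.1, rng_seed = 81,
                   max_age_days = 2000, families = "BCCG")
  man <- quiet(run_pipeline(d, out, cfg, verbose = FALSE))
  expect_true(all(file.exists(file.path(out, c("model.json",
                                               "percentiles.tsv",
                                               "weighted_data.tsv",
                                               "manifest.json")))))
  expect_equal(man$n_unweighted, 0)
  # determinism: a second run yields a byte-identical percentile table
  out2 <- tempfile("run")
  quiet(run_pipeline(d, out2, cfg, verbose = FALSE))
  expect_identical(readLines(file.path(out, "percentiles.tsv")),
                   readLines(file.path(out2, "percentiles.tsv")))
  expect_error(run_pipeline(tempfile(), tempfile()), "not found")
})
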