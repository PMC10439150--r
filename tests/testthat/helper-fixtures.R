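# Shared fixtures built in code; everything is seeded.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# a small clean alp-like fit, cached for tests that need any valid model
.fixture_env <- new.env(parent = emptyenv())

small_curve_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    sc <- ri_scenario("alp_like", n_total = 4000,
                      pathological_fraction = 0, seed = 101)
    d <- generate_dataset(sc)
    .fixture_env$scenario <- sc
    .fixture_env$data <- d
    .fixture_env$fit <- quiet(fit_weighted_gamlss(
      d$age_days, d$value, family = "BCCG", rng_seed = 101))
  }
  .fixture_env$fit
}

small_dataset <- function() {
  small_curve_fit()
  .fixture_env$data
}

small_scenario <- function() {
  small_curve_fit()
  .fixture_env$scenario
}

# write a tiny delimited measurement file and return its path
write_toy_file <- function(lines, sep = ",") {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# random valid BCCG-family parameter draws for property-style loops
random_params <- function(n, seed, family = "BCCG") {
  set.seed(seed)
  data.frame(mu = runif(n, 10, 200),
             sigma = runif(n, 0.05, 0.35),
             lambda = runif(n, -1, 1.5),
             tau = if (family == "BCT") runif(n, 3, 30) else
               runif(n, 1, 5))
}
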