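test_that("zero-weighted contaminants leave the fit identical to clean data", {
  set.seed(51)
  n <- 2000
  age <- sample(0:3000, n, replace = TRUE)
  mu <- 100 + 0.01 * age
  clean <- qbccg(runif(n), mu, 0.12, 0.8)
  contam_age <- sample(0:3000, 300, replace = TRUE)
  contam <- qbccg(runif(300), 350, 0.1, 0.8)
  f_clean <- quiet(fit_weighted_gamlss(age, clean, family = "BCCG",
                                       select_smoothing = FALSE))
  f_w <- quiet(fit_weighted_gamlss(c(age, contam_age), c(clean, contam),
                                   weights = c(rep(1, n), rep(0, 300)),
                                   family = "BCCG",
                                   select_smoothing = FALSE))
  ages <- seq(max(f_clean$age_range[1], f_w$age_range[1]),
              min(f_clean$age_range[2], f_w$age_range[2]), by = 100)
  expect_equal(predict_percentiles(f_w, ages)$values,
               predict_percentiles(f_clean, ages)$values,
               tolerance = 1e-8)
})

test_that("constant-age data collapse to a one-dimensional ML fit", {
  set.seed(52)
  y <- qbccg(runif(1500), 80, 0.2, 0.5)
  f <- quiet(fit_weighted_gamlss(rep(365, 1500), y, family = "BCCG"))
  th <- curve_params(f, 365)
  # independent 1-D maximum likelihood oracle
  nll <- function(p) -sum(family_log_density("BCCG", y, exp(p[1]),
                                             exp(p[2]), p[3]))
  ml <- optim(c(log(80), log(0.2), 0.5), nll)
  expect_equal(th$mu, exp(ml$par[1]), tolerance = 0.01)
  expect_equal(th$sigma, exp(ml$par[2]), tolerance = 0.05)
  expect_equal(th$lambda, ml$par[3], tolerance = 0.25)
})

test_that("fitted percentile curves recover smooth truth on clean data", {
  sc <- small_scenario()
  f <- small_curve_fit()
  ages <- unique(pmax(0, round(exp(seq(log(1), log(6571),
                                       length.out = 40)) - 1)))
  ages <- ages[ages >= f$age_range[1] & ages <= f$age_range[2]]
  tr <- truth_percentiles(sc, ages, c(0.025, 0.5, 0.975))
  est <- predict_percentiles(f, ages, c(0.025, 0.5, 0.975))
  rel <- abs(est$values - tr$values) / tr$values
  # n = 4000: generous regression bounds; tightened at scale in the
  # acceptance suite
  expect_lt(max(rel[, 2]), 0.10)
  expect_lt(max(rel[, c(1, 3)]), 0.20)
})

test_that("family selection returns the BIC argmin with stated tie-breaks", {
  mk <- function(fam, bic, edf) structure(
    list(family = fam, bic = bic, edf_total = edf), class = "ri_curves")
  ms <- list(mk("BCCG", 1000, 10), mk("BCPE", 999, 12),
             mk("BCT", 1001, 9))
  expect_equal(select_best_family(ms)$family, "BCPE")
  expect_equal(select_best_family(ms[1])$family, "BCCG")
  # tie on BIC -> fewer edf; tie on both -> family order
  ms2 <- list(mk("BCT", 500, 8), mk("BCCG", 500, 9))
  expect_equal(select_best_family(ms2)$family, "BCT")
  ms3 <- list(mk("BCPE", 500, 8), mk("BCCG", 500, 8))
  expect_equal(select_best_family(ms3)$family, "BCCG")
  expect_error(select_best_family(list(NULL)), "failed")
})

test_that("heavy-tailed data steer the BIC towards the t-family", {
  picks <- vapply(1:2, function(seed) {
    set.seed(seed)
    n <- 8000
    age <- sample(0:6570, n, replace = TRUE)
    y <- family_quantile("BCT", runif(n), 100 + 0.005 * age, 0.15, 0.5, 4)
    fits <- lapply(c("BCCG", "BCPE", "BCT"), function(fam)
      tryCatch(quiet(fit_weighted_gamlss(age, y, family = fam,
                                         rng_seed = seed)),
               error = function(e) NULL))
    select_best_family(fits)$family
  }, "")
  expect_gte(sum(picks == "BCT"), 1)
})

test_that("globally rescaled weights leave the fitted curves unchanged", {
  set.seed(54)
  n <- 1500
  age <- sample(0:2000, n, replace = TRUE)
  y <- qbccg(runif(n), 60 + 0.02 * age, 0.15, 1)
  w <- runif(n, 0.5, 1)
  f1 <- quiet(fit_weighted_gamlss(age, y, w, family = "BCCG",
                                  select_smoothing = FALSE))
  f2 <- quiet(fit_weighted_gamlss(age, y, 0.5 * w, family = "BCCG",
                                  select_smoothing = FALSE))
  ages <- seq(f1$age_range[1], f1$age_range[2], by = 100)
  expect_equal(predict_percentiles(f2, ages)$values,
               predict_percentiles(f1, ages)$values, tolerance = 0.01)
})

test_that("percentiles never cross and match direct quantile evaluation", {
  f <- small_curve_fit()
  ages <- seq(f$age_range[1], f$age_range[2], by = 13)
  probs <- c(0.01, 0.025, 0.1, 0.25, 0.5, 0.75, 0.9, 0.975, 0.99)
  tab <- predict_percentiles(f, ages, probs)
  expect_true(all(apply(tab$values, 1, function(r)
    !is.unsorted(r, strictly = TRUE))))
  # re-evaluation oracle at a few grid ages
  pick <- ages[c(2, 25, 120)]
  th <- curve_params(f, pick)
  direct <- vapply(probs, function(p)
    family_quantile(f$family, p, th$mu, th$sigma, th$lambda), numeric(3))
  expect_equal(tab$values[match(pick, ages), ], direct, tolerance = 1e-12)
})

test_that("z-scores invert the percentile mapping", {
  f <- small_curve_fit()
  p_grid <- c(0.025, 0.2, 0.5, 0.8, 0.975)
  for (a in c(5, 300, 4000)) {
    q <- predict_percentiles(f, a, p_grid)$values[1, ]
    z <- value_to_zscore(f, q, rep(a, length(p_grid)))
    expect_equal(pnorm(as.numeric(z)), p_grid, tolerance = 1e-8)
  }
  # median maps to z = 0
  med <- predict_percentiles(f, 100, 0.5)$values[1, 1]
  expect_equal(as.numeric(value_to_zscore(f, med, 100)), 0,
               tolerance = 1e-8)
})

test_that("prediction refuses to extrapolate beyond the fitted age range", {
  f <- small_curve_fit()
  expect_error(predict_percentiles(f, 1e5), "fitted range")
})
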