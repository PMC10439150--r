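test_that("boxcox transform handles the power, log and identity points", {
  expect_equal(boxcox(1, 0.7), 0)
  expect_equal(boxcox(1, 0), 0)
  expect_equal(boxcox(exp(1), 0), 1)
  expect_equal(boxcox(4, 0.5), 2)
  # continuity in lambda at 0
  expect_equal(boxcox(3, 1e-9), log(3), tolerance = 1e-6)
  expect_error(boxcox(-1, 0.5), "positive")
})

test_that("BCCG reduces to the lognormal at lambda = 0", {
  y <- c(0.5, 1, 2)
  expect_equal(dbccg(y, 1, 1, 0), dlnorm(y, 0, 1), tolerance = 1e-12)
  # closed-form density at the median, lambda = 0
  mu <- 40; sg <- 0.25
  expect_equal(dbccg(mu, mu, sg, 0), 1 / (mu * sg * sqrt(2 * pi)),
               tolerance = 1e-12)
  # lognormal closed-form upper reference limit
  expect_equal(qbccg(0.975, 100, 0.1, 0), 100 * exp(0.1 * qnorm(0.975)),
               tolerance = 1e-12)
})

test_that("family densities integrate to 1 over the positive axis", {
  cases <- list(list("BCCG", 100, 0.1, 0.5, 2),
                list("BCCG", 100, 0.3, -0.8, 2),
                list("BCPE", 100, 0.3, 1, 1.5),
                list("BCPE", 50, 0.2, -0.5, 4),
                list("BCT", 100, 0.2, -0.5, 5),
                list("BCT", 20, 0.15, 0.8, 8))
  for (cs in cases) {
    f <- function(y) exp(family_log_density(cs[[1]], y, cs[[2]], cs[[3]],
                                            cs[[4]], cs[[5]]))
    mode_y <- cs[[2]]
    mass <- integrate(f, 1e-9, mode_y, rel.tol = 1e-9)$value +
      integrate(f, mode_y, Inf, rel.tol = 1e-9)$value
    expect_equal(mass, 1, tolerance = 1e-6,
                 label = paste("mass", cs[[1]], cs[[4]]))
  }
})

test_that("BCPE at tau = 2 equals BCCG; BCT approaches BCCG as tau grows", {
  y <- c(50, 100, 150)
  expect_equal(dbcpe(y, 100, 0.15, 0.7, 2, log = TRUE),
               dbccg(y, 100, 0.15, 0.7, log = TRUE), tolerance = 1e-8)
  expect_equal(dbct(y, 100, 0.15, 0.7, 1e6, log = TRUE),
               dbccg(y, 100, 0.15, 0.7, log = TRUE), tolerance = 1e-4)
  # also on the quantile side
  p <- c(0.025, 0.5, 0.975)
  expect_equal(qbcpe(p, 100, 0.15, 0.7, 2), qbccg(p, 100, 0.15, 0.7),
               tolerance = 1e-8)
})

test_that("cdf and quantile are mutually inverse across random models", {
  p_grid <- seq(0.01, 0.99, by = 0.01)
  for (fam in c("BCCG", "BCPE", "BCT")) {
    pars <- random_params(10, seed = 20, family = fam)
    for (i in seq_len(nrow(pars))) {
      q <- family_quantile(fam, p_grid, pars$mu[i], pars$sigma[i],
                           pars$lambda[i], pars$tau[i])
      expect_false(is.unsorted(q, strictly = TRUE))
      expect_equal(family_cdf(fam, q, pars$mu[i], pars$sigma[i],
                              pars$lambda[i], pars$tau[i]),
                   p_grid, tolerance = 1e-8)
    }
  }
})

test_that("mu is the median up to the positive-support truncation", {
  # exact when lambda = 0 (no truncation)
  for (fam in c("BCCG", "BCPE", "BCT"))
    expect_equal(family_quantile(fam, 0.5, 123, 0.2, 0, 4), 123,
                 tolerance = 1e-12)
  # with lambda != 0 the truncation mass 1 - C is tiny, so mu is the
  # median only to that order
  for (fam in c("BCCG", "BCPE", "BCT"))
    expect_equal(family_quantile(fam, 0.5, 123, 0.2, 0.6, 4), 123,
                 tolerance = 1e-3)
})

test_that("domain violations are rejected", {
  expect_error(dbccg(-5, 100, 0.1, 1), "positive")
  expect_error(family_quantile("BCCG", 1.5, 100, 0.1, 1), "strictly")
  expect_error(family_log_density("XXX", 1, 1, 1, 1), "family")
})
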