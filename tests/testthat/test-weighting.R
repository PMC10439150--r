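test_that("the kernel density estimate matches analytic and brute force", {
  set.seed(19)
  v <- runif(10000)
  expect_equal(empirical_density(v, 0.5), 1, tolerance = 0.1)
  # far outside the data range the density vanishes
  expect_lt(empirical_density(v, 50), 1e-6)
  # exact equality with an independently coded kernel sum
  pts <- c(0.2, 0.5, 0.9)
  bw <- stats::bw.nrd0(v)
  brute <- vapply(pts, function(x0)
    sum(exp(-0.5 * ((x0 - v) / bw)^2) / sqrt(2 * pi)) / (length(v) * bw),
    1)
  expect_equal(empirical_density(v, pts), brute, tolerance = 1e-10)
  # the estimate integrates to ~1 over a covering grid
  g <- seq(-0.5, 1.5, length.out = 2001)
  expect_equal(sum(empirical_density(v, g)) * diff(g)[1], 1,
               tolerance = 0.02)
  expect_error(empirical_density(rep(1, 10), 1), "zero variance")
})

test_that("grid ratio equals a direct density-ratio oracle before smoothing", {
  set.seed(23)
  v <- qbccg(runif(2000), 100, 0.15, 0.5)
  m <- fit_np_model(v)
  dr <- density_ratio_weights(v, m)
  d_total <- empirical_density(v, dr$grid)
  oracle <- ifelse(d_total > 0,
                   m$np_fraction * bcn_pdf(dr$grid, m) / d_total, 0)
  expect_equal(dr$ratio_raw, oracle, tolerance = 1e-10)
})

test_that("smoothing equals an explicitly coded Gaussian convolution", {
  set.seed(24)
  x <- runif(64)
  sd_steps <- 2
  half <- ceiling(4 * sd_steps)
  k <- dnorm(seq(-half, half), sd = sd_steps)
  conv <- function(sig) {
    n <- length(sig)
    out <- numeric(n)
    for (i in seq_len(n)) {
      js <- max(1, i - half):min(n, i + half)
      w <- k[js - i + half + 1]
      out[i] <- sum(sig[js] * w) / sum(w)
    }
    out
  }
  expect_equal(refcurve:::.gauss_smooth(x, sd_steps), conv(x),
               tolerance = 1e-12)
})

test_that("weights are 1 at an over-dense model peak and ~0 in the far tail", {
  set.seed(25)
  v <- qbccg(runif(3000), 100, 0.1, 1)
  m <- fit_np_model(c(v, qbccg(runif(300), 250, 0.1, 1)))
  all_v <- c(v, qbccg(runif(300), 250, 0.1, 1))
  dr <- density_ratio_weights(all_v, m, eval_at = c(m$mu, 250))
  expect_true(all(dr$weights >= 0 & dr$weights <= 1))
  expect_gt(dr$weights[1], 0.8)
  expect_lt(dr$weights[2], 0.2)
})

test_that("each measurement takes one weight from its nearest group centre", {
  set.seed(26)
  n <- 3000
  d <- measurement_set(data.frame(
    value = qbccg(runif(n), 100, 0.15, 0.5),
    age_days = sample(0:200, n, replace = TRUE),
    sex = "M", subject_id = as.character(seq_len(n))))
  cfg <- ri_config(n_min = 500, max_age_days = 200, width_growth = 0.2)
  groups <- build_age_groups(d, cfg)
  models <- lapply(groups, function(g)
    fit_np_model(d$value[g$member_idx]))
  p_raw <- assign_single_weight(d, groups, models)
  expect_length(p_raw, nrow(d))               # exactly one weight each
  expect_true(all(p_raw >= 0 & p_raw <= 1))

  # nearest-centre rule with younger-centre tie-break, via direct check
  centers <- vapply(groups, `[[`, 1L, "center")
  for (i in sample(n, 25)) {
    dist <- abs(centers - d$age_days[i])
    j <- which(dist == min(dist))[1]           # first = youngest on ties
    g <- groups[[j]]
    in_grp <- d$age_days >= g$lower & d$age_days <= g$upper
    dr <- density_ratio_weights(d$value[in_grp], models[[j]],
                                eval_at = d$value[i])
    expect_equal(p_raw[i], dr$weights, tolerance = 1e-12)
  }
})

test_that("a pathological point mass far outside the bulk is down-weighted", {
  set.seed(27)
  n <- 2000
  vals <- c(qbccg(runif(n * 0.9), 100, 0.1, 0.8),
            rnorm(n * 0.1, 300, 5))
  d <- measurement_set(data.frame(
    value = vals, age_days = sample(0:60, n, replace = TRUE), sex = "M",
    subject_id = as.character(seq_len(n))))
  cfg <- ri_config(n_min = 1000, max_age_days = 60)
  groups <- build_age_groups(d, cfg)
  models <- lapply(groups, function(g) fit_np_model(d$value[g$member_idx]))
  p_raw <- assign_single_weight(d, groups, models)
  expect_lt(mean(p_raw[d$value > 250]), 0.05)
})

test_that("subject correction divides by whole-dataset sample counts", {
  p_raw <- c(0.9, 0.8, 0.7, 0.5, 1.0)
  ids <- c("a", "a", "a", "b", "c")
  p_corr <- subject_correction(p_raw, ids)
  expect_equal(p_corr, c(0.3, 0.8 / 3, 0.7 / 3, 0.5, 1.0))
  # single-sample subject is unchanged; correction never increases
  expect_true(all(p_corr <= p_raw))
  # enumeration property: per-subject sum of p_corr <= max p_raw
  set.seed(28)
  for (rep in 1:20) {
    ids <- sample(letters[1:5], 30, replace = TRUE)
    p <- runif(30)
    pc <- subject_correction(p, ids)
    for (s in unique(ids))
      expect_lte(sum(pc[ids == s]), max(p[ids == s]) + 1e-12)
  }
})
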