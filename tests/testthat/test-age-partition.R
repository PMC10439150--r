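# brute-force recursion oracle for the centre-thinning rule
.oracle_centers <- function(max_age, wg) {
  h <- function(c) max(0.5, wg * c / 2)
  cs <- integer(0); c1 <- 1
  while (c1 <= max_age) {
    cs <- c(cs, c1)
    if (h(c1 + 1) <= 0.5) { c1 <- c1 + 1; next }
    up <- c1 + h(c1); n <- c1 + 1
    while (n - h(n) <= up) n <- n + 1
    c1 <- n
  }
  if (floor(cs[length(cs)] + h(cs[length(cs)])) < max_age)
    cs <- c(cs, max_age)
  as.integer(cs)
}

test_that("the 1% width rule reproduces the 995-1005 range at day 1000", {
  h <- base_halfwidth(1000, 0.01)
  expect_equal(c(1000 - h, 1000 + h), c(995, 1005))
})

test_that("daily candidate centres for 18 years number 6570 before thinning", {
  expect_identical(candidate_centers(6570, 0.01, thin = FALSE), 1:6570)
})

test_that("thinned centres match a step-by-step recursion oracle", {
  for (wg in c(0.01, 0.05)) {
    cc <- candidate_centers(6570, wg)
    expect_identical(cc, .oracle_centers(6570, wg))
    expect_false(is.unsorted(cc, strictly = TRUE))
    # base widths non-decreasing in centre age
    expect_false(is.unsorted(base_halfwidth(cc, wg)))
  }
})

test_that("base ranges cover every day of the age axis without gaps", {
  cc <- candidate_centers(6570, 0.01)
  h <- base_halfwidth(cc, 0.01)
  lo <- ifelse(cc <= 1, 0, pmax(0, floor(cc - h)))
  up <- pmin(6570, ceiling(cc + h))
  covered <- rep(FALSE, 6571)
  for (k in seq_along(cc)) covered[(lo[k]:up[k]) + 1] <- TRUE
  expect_true(all(covered))
})

test_that("group expansion is minimal under the alternating schedule", {
  set.seed(5)
  ages <- sort(sample(0:100, 2000, replace = TRUE))
  subj <- seq_along(ages)        # one sample per subject
  rng <- expand_group_to_min_n(50, 0.5, ages, subj, n_min = 1000)
  n_in <- function(lo, up) sum(ages >= lo & ages <= up)
  expect_gte(n_in(rng$lower, rng$upper), 1000)
  # linear-scan oracle: replay the schedule step by step
  lo <- 50L; up <- 50L; left <- TRUE
  while (n_in(lo, up) < 1000) {
    if (left) { if (lo > 0) lo <- lo - 1L else up <- up + 1L }
    else { if (up < 100) up <- up + 1L else lo <- lo - 1L }
    left <- !left
  }
  expect_equal(c(rng$lower, rng$upper), c(lo, up))
})

test_that("expansion exhausts gracefully when the data are too small", {
  ages <- sort(sample(0:50, 500, replace = TRUE))
  rng <- expand_group_to_min_n(25, 0.5, ages, seq_along(ages),
                               n_min = 1000)
  expect_true(rng$exhausted)
  expect_equal(c(rng$lower, rng$upper), range(ages))
  d <- measurement_set(data.frame(value = rexp(500) + 1, age_days = ages,
                                  sex = "M",
                                  subject_id = as.character(seq_len(500))))
  expect_warning(build_age_groups(d, ri_config(max_age_days = 50)),
                 "fewer than n_min")
})

test_that("a group already at n_min keeps its base range", {
  ages <- rep(50L, 1000)
  rng <- expand_group_to_min_n(50, 0.5, ages, seq_along(ages),
                               n_min = 1000)
  expect_equal(c(rng$lower, rng$upper), c(50L, 50L))
})

test_that("per-subject deduplication keeps the most central sample", {
  # |990 - 1000| = 10 > |1004 - 1000| = 4 -> keep 1004
  idx <- select_central_sample_per_subject(1000, c(990, 1004), c(1, 1),
                                           c(11L, 12L))
  expect_identical(idx, 12L)
  # single sample kept
  expect_identical(select_central_sample_per_subject(1000, 995, 1, 5L), 5L)
  # tie at equal distance -> younger age
  idx <- select_central_sample_per_subject(1000, c(995, 1005), c(1, 1),
                                           c(3L, 4L))
  expect_identical(idx, 3L)
})

test_that("built groups respect dedup, membership and n_min invariants", {
  set.seed(8)
  n <- 6000
  d <- measurement_set(data.frame(
    value = rlnorm(n, 3, 0.3),
    age_days = sample(0:800, n, replace = TRUE),
    sex = "M",
    subject_id = sprintf("S%04d", sample(2500, n, replace = TRUE))))
  cfg <- ri_config(n_min = 400, max_age_days = 800)
  groups <- build_age_groups(d, cfg)
  for (g in groups) {
    sid <- d$subject_id[g$member_idx]
    expect_false(any(duplicated(sid)))
    expect_true(all(d$age_days[g$member_idx] >= g$lower &
                      d$age_days[g$member_idx] <= g$upper))
    expect_gte(length(g$member_idx), 400)
  }
  # raising n_min never shrinks any group range
  groups2 <- build_age_groups(d, ri_config(n_min = 800, max_age_days = 800))
  for (k in seq_along(groups)) {
    expect_lte(groups2[[k]]$lower, groups[[k]]$lower)
    expect_gte(groups2[[k]]$upper, groups[[k]]$upper)
  }
})
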