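## Seeded synthetic routine-measurement generator with closed-form truth.
##
## Scenarios emulate pediatric laboratory analytes: an age-dependent
## non-pathological distribution (Box-Cox family with smooth parameter
## curves in log-age), a one-sided pathological admixture (multiplicatively
## shifted location with inflated scale), repeated samples per subject, and
## an age sampler overrepresenting the first year of life.  The shapes are
## qualitative emulations of well-known analyte dynamics -- an alkaline-
## phosphatase-like infancy peak plus pubertal peak, a creatinine-like
## neonatal fall and slow rise, a hemoglobin-like day-one rise, fall to a
## nadir around day 50 and pubertal rise -- not reproductions of any
## measured population.

#' Define a synthetic measurement scenario
#'
#' @param name One of `"alp_like"`, `"crea_like"`, `"hb_like"`.
#' @param n_total Total number of measurements to generate.
#' @param pathological_fraction Fraction of pathological samples: a single
#'   number in \[0, 0.4\] or a function of age in days.
#' @param pathological_shift Multiplicative displacement of the
#'   pathological location.
#' @param pathological_sigma_factor Scale inflation of the pathological
#'   component.
#' @param samples_per_subject Probability vector over 1, 2, 3, ... samples
#'   per subject.
#' @param max_age_days Age range upper end.
#' @param neonatal_mix Weight of the log-uniform component of the age
#'   sampler (the remainder is uniform over the age range).
#' @param seed RNG seed; the generator is fully reproducible from it.
#' @return An object of class `ri_scenario` with closed-form truth curves
#'   `mu(a)`, `sigma(a)`, `lambda(a)` and the sampling settings.
#' @export
ri_scenario <- function(name = c("alp_like", "crea_like", "hb_like"),
                        n_total = 50000,
                        pathological_fraction = 0.10,
                        pathological_shift = 1.8,
                        pathological_sigma_factor = 1.5,
                        samples_per_subject = c(0.60, 0.25, 0.10, 0.05),
                        max_age_days = 6570,
                        neonatal_mix = 0.7,
                        seed = 1L) {
  name <- match.arg(name)
  v <- function(a) log(a + 1)
  curves <- switch(name,
    alp_like = list(
      mu = function(a) 120 + 180 * exp(-0.5 * ((v(a) - 4.7) / 1.2)^2) +
        90 * exp(-0.5 * ((v(a) - 8.45) / 0.30)^2),
      sigma = function(a) 0.16 + 0.05 * exp(-0.5 * ((v(a) - 4.7) / 1.5)^2),
      lambda = function(a) rep(0.4, length(a)),
      unit = "U/L"),
    crea_like = list(
      mu = function(a) 0.30 + 0.75 * exp(-v(a) / 1.1) +
        0.35 * (v(a) / v(6570))^2.5,
      sigma = function(a) rep(0.13, length(a)),
      lambda = function(a) rep(0.2, length(a)),
      unit = "mg/dL"),
    hb_like = list(
      mu = function(a) 11.2 + 5.8 * exp(-a / 35) +
        1.6 * stats::plogis((v(a) - 8.2) / 0.25) + 0.8 * v(a) / v(6570),
      sigma = function(a) rep(0.075, length(a)),
      lambda = function(a) rep(1.2, length(a)),
      unit = "g/dL"))
  pf <- if (is.function(pathological_fraction)) pathological_fraction
  else {
    stopifnot(pathological_fraction >= 0, pathological_fraction <= 0.4)
    local({
      p0 <- pathological_fraction
      function(a) rep(p0, length(a))
    })
  }
  stopifnot(abs(sum(samples_per_subject) - 1) < 1e-8,
            all(samples_per_subject >= 0))
  structure(list(name = name, family = "BCCG",
                 mu = curves$mu, sigma = curves$sigma,
                 lambda = curves$lambda, unit = curves$unit,
                 pathological_fraction = pf,
                 pathological_shift = pathological_shift,
                 pathological_sigma_factor = pathological_sigma_factor,
                 samples_per_subject = samples_per_subject,
                 max_age_days = as.integer(max_age_days),
                 neonatal_mix = neonatal_mix,
                 n_total = as.integer(n_total),
                 seed = as.integer(seed)),
            class = "ri_scenario")
}

#' @export
print.ri_scenario <- function(x, ...) {
  cat(sprintf("Synthetic scenario '%s': n = %d, ages 0-%d days, seed %d\n",
              x$name, x$n_total, x$max_age_days, x$seed))
  cat(sprintf("  pathological: fraction %.2f at age 365, shift x%.2f\n",
              x$pathological_fraction(365), x$pathological_shift))
  invisible(x)
}

.sample_ages <- function(n, max_age_days, neonatal_mix) {
  take_log <- stats::runif(n) < neonatal_mix
  a <- integer(n)
  a[take_log] <- pmin(max_age_days,
                      floor(exp(stats::runif(sum(take_log), 0,
                                             log(max_age_days + 2))) - 1))
  a[!take_log] <- sample.int(max_age_days + 1L, sum(!take_log),
                             replace = TRUE) - 1L
  a
}

#' Generate a synthetic routine-measurement dataset
#'
#' Draws subjects, per-subject sample counts, ages (log-uniform/uniform
#' mixture overrepresenting early life), then values: non-pathological
#' values from the scenario's Box-Cox family at the truth curves,
#' pathological values from the multiplicatively shifted component.  Fully
#' reproducible from the scenario seed.
#'
#' @param scenario An [ri_scenario()].
#' @return A `measurement_set` with an extra column `truth` labelling each
#'   row `"np"` or `"path"`.
#' @export
generate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "ri_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_total
  ## subjects and per-subject sample counts
  kmax <- length(scenario$samples_per_subject)
  n_subj_guess <- ceiling(n / sum(seq_len(kmax) *
                                    scenario$samples_per_subject)) + 64L
  counts <- sample.int(kmax, n_subj_guess, replace = TRUE,
                       prob = scenario$samples_per_subject)
  while (sum(counts) < n)
    counts <- c(counts, sample.int(kmax, 64L, replace = TRUE,
                                   prob = scenario$samples_per_subject))
  cum <- cumsum(counts)
  n_subj <- which(cum >= n)[1]
  counts <- counts[seq_len(n_subj)]
  counts[n_subj] <- counts[n_subj] - (cum[n_subj] - n)
  subject_id <- rep(sprintf("S%06d", seq_len(n_subj)), times = counts)

  age <- .sample_ages(n, scenario$max_age_days, scenario$neonatal_mix)
  mu <- scenario$mu(age)
  sg <- scenario$sigma(age)
  lam <- scenario$lambda(age)
  is_path <- stats::runif(n) < scenario$pathological_fraction(age)
  mu[is_path] <- mu[is_path] * scenario$pathological_shift
  sg[is_path] <- sg[is_path] * scenario$pathological_sigma_factor
  value <- family_quantile(scenario$family, stats::runif(n), mu, sg, lam)
  out <- data.frame(value = value, age_days = age, sex = "A",
                    subject_id = subject_id,
                    truth = ifelse(is_path, "path", "np"),
                    stringsAsFactors = FALSE)
  out <- measurement_set(out, analyte = scenario$name, unit = scenario$unit)
  out
}

#' Closed-form truth percentiles of a scenario
#'
#' Quantiles of the clean (non-pathological) distribution at the truth
#' curves; the oracle for all recovery tests.
#'
#' @param scenario An [ri_scenario()].
#' @param ages Ages in days.
#' @param probs Strictly increasing probabilities.
#' @return A `percentile_table`.
#' @export
truth_percentiles <- function(scenario, ages,
                              probs = c(0.025, 0.10, 0.25, 0.50,
                                        0.75, 0.90, 0.975)) {
  stopifnot(inherits(scenario, "ri_scenario"))
  mu <- scenario$mu(ages); sg <- scenario$sigma(ages)
  lam <- scenario$lambda(ages)
  vals <- vapply(probs, function(p)
    family_quantile(scenario$family, p, mu, sg, lam),
    numeric(length(ages)))
  percentile_table(ages = ages, probs = probs,
                   values = matrix(vals, nrow = length(ages)))
}
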