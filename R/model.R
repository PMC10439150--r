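## The fitted continuous reference-interval model and its methods.

.as_curves <- function(object) {
  if (inherits(object, "ri_curves")) return(object)
  if (inherits(object, "ri_model")) return(object$model)
  stop("expected an ri_model or ri_curves object")
}

#' Predict percentile curves from a fitted model
#'
#' @param model An `ri_model` or `ri_curves` object.
#' @param ages Ages in days (within the fitted range).
#' @param probs Strictly increasing probabilities; default the chart set
#'   2.5/10/25/50/75/90/97.5.
#' @return A `percentile_table` (ages x probs).
#' @export
predict_percentiles <- function(model, ages,
                                probs = c(0.025, 0.10, 0.25, 0.50,
                                          0.75, 0.90, 0.975)) {
  cm <- .as_curves(model)
  th <- curve_params(cm, ages)
  tau <- if (is.null(th$tau)) 2 else th$tau
  vals <- vapply(probs, function(p)
    family_quantile(cm$family, p, th$mu, th$sigma, th$lambda, tau),
    numeric(length(ages)))
  percentile_table(ages = ages, probs = probs,
                   values = matrix(vals, nrow = length(ages)))
}

#' Convert a test result into an age-specific z-score
#'
#' The z-score is the standard-normal quantile of the model CDF of the
#' value at its age: \eqn{z = \Phi^{-1}(F(y \mid \theta(u(age))))}.  A
#' value at the model's 97.5th percentile maps to z = 1.96 at any age.
#' Values whose CDF reaches 0 or 1 to machine precision yield -Inf/+Inf
#' with a `censored` attribute flagging them.
#'
#' @param model An `ri_model` or `ri_curves` object.
#' @param y Positive test results.
#' @param age Ages in days, recycled against `y`.
#' @return Numeric z-scores with attribute `censored` (logical vector).
#' @export
value_to_zscore <- function(model, y, age) {
  cm <- .as_curves(model)
  nn <- max(length(y), length(age))
  y <- rep_len(y, nn); age <- rep_len(age, nn)
  th <- curve_params(cm, age)
  tau <- if (is.null(th$tau)) 2 else th$tau
  FF <- family_cdf(cm$family, y, th$mu, th$sigma, th$lambda, tau)
  cens <- FF <= 0 | FF >= 1
  z <- stats::qnorm(FF)
  attr(z, "censored") <- cens
  z
}

#' @export
print.ri_curves <- function(x, ...) {
  cat(sprintf("Smooth %s model over age (u = log(age + 1))\n", x$family))
  for (cv in x$curves)
    cat(sprintf("  %-6s %-9s edf %.2f\n", cv$name, cv$type, cv$edf))
  cat(sprintf("  weighted log-lik %.2f, BIC %.2f, n_eff %.1f, n %d\n",
              x$loglik, x$bic, x$n_eff, x$n))
  if (!x$converged) cat("  (fit did not formally converge)\n")
  invisible(x)
}

#' @export
print.ri_model <- function(x, ...) {
  cat("Continuous reference-interval model")
  if (nzchar(x$analyte)) cat(" for ", x$analyte, sep = "")
  cat("\n")
  cat(sprintf("  %d measurements, %d age groups, family %s (BIC %.1f)\n",
              x$n_measurements, x$n_groups, x$model$family, x$model$bic))
  cat(sprintf("  age range %d-%d days\n",
              x$model$age_range[1], x$model$age_range[2]))
  invisible(x)
}

#' @export
summary.ri_model <- function(object, ...) {
  x <- object
  cat("Continuous reference-interval model")
  if (nzchar(x$analyte))
    cat(sprintf(" for %s [%s]", x$analyte, x$unit))
  cat("\n\n")
  cat("Candidate families (BIC):\n")
  print(x$family_bic)
  cat("\nSelected model:\n")
  print(x$model)
  cat(sprintf("\nWeights: mean p_raw %.3f, mean p_corr %.3f, sum %.1f\n",
              mean(x$weights$p_raw), mean(x$weights$p_corr),
              sum(x$weights$p_corr)))
  show_ages <- c(30, 365, 3650, x$model$age_range[2])
  show_ages <- unique(pmin(pmax(show_ages, x$model$age_range[1]),
                           x$model$age_range[2]))
  ri <- predict_percentiles(x, show_ages, probs = c(0.025, 0.5, 0.975))
  cat("\nReference intervals at selected ages (2.5th / 50th / 97.5th):\n")
  df <- data.frame(age_days = ri$ages,
                   lower = signif(ri$values[, 1], 4),
                   median = signif(ri$values[, 2], 4),
                   upper = signif(ri$values[, 3], 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ri_model <- function(object, ...) {
  lapply(object$model$curves, function(cv)
    list(type = cv$type, coef = cv$coef, edf = cv$edf))
}

#' Predicted percentiles for an `ri_model`
#'
#' @param object An `ri_model`.
#' @param ages Ages in days; default a daily grid over the fitted range.
#' @param probs Probabilities; default the configured percentile set.
#' @param ... Unused.
#' @return A `percentile_table`.
#' @export
predict.ri_model <- function(object, ages = NULL, probs = NULL, ...) {
  if (is.null(ages))
    ages <- seq(object$model$age_range[1], object$model$age_range[2])
  if (is.null(probs)) probs <- object$config$percentile_probs
  predict_percentiles(object, ages, probs)
}

#' Z-score residuals of the training data
#'
#' @param object An `ri_model`.
#' @param ... Unused.
#' @return Z-scores of every training measurement under the fitted model;
#'   if the weights suppressed pathological samples correctly, the
#'   high-weight residuals are approximately standard normal.
#' @export
residuals.ri_model <- function(object, ...) {
  value_to_zscore(object, object$data$value, object$data$age_days)
}

#' Simulate measurements from a fitted model
#'
#' Draws values from the fitted age-dependent distribution at the given
#' ages (non-pathological component only).
#'
#' @param object An `ri_model`.
#' @param nsim Number of values per age.
#' @param seed RNG seed.
#' @param ages Ages in days at which to simulate; default 100 random
#'   training ages.
#' @param ... Unused.
#' @return Data frame with `age_days` and `value`.
#' @export
simulate.ri_model <- function(object, nsim = 1, seed = NULL,
                              ages = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ages))
    ages <- sample(object$data$age_days, 100, replace = TRUE)
  ages <- rep(ages, each = nsim)
  cm <- .as_curves(object)
  th <- curve_params(cm, ages)
  tau <- if (is.null(th$tau)) 2 else th$tau
  val <- family_quantile(cm$family, stats::runif(length(ages)),
                         th$mu, th$sigma, th$lambda, tau)
  data.frame(age_days = ages, value = val)
}

#' Plot the percentile chart of a fitted model
#'
#' @param x An `ri_model`.
#' @param probs Percentile probabilities to draw.
#' @param log_age Draw the age axis on `log(age + 1)` scale.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ri_model <- function(x, probs = c(0.025, 0.10, 0.25, 0.50,
                                       0.75, 0.90, 0.975),
                          log_age = TRUE, ...) {
  ages <- unique(round(exp(seq(log(1 + x$model$age_range[1]),
                               log(1 + x$model$age_range[2]),
                               length.out = 200)) - 1))
  ages <- pmax(x$model$age_range[1], pmin(x$model$age_range[2], ages))
  tab <- predict_percentiles(x, ages, probs)
  xv <- if (log_age) log(ages + 1) else ages
  graphics::matplot(xv, tab$values, type = "l", lty = 1,
                    col = grDevices::hcl.colors(length(probs), "Zissou 1"),
                    xlab = if (log_age) "log(age in days + 1)" else
                      "age (days)",
                    ylab = paste0(x$analyte,
                                  if (nzchar(x$unit))
                                    paste0(" [", x$unit, "]") else ""),
                    ...)
  invisible(tab)
}

#' Serialize a fitted model to self-describing JSON text
#'
#' The file holds the family, basis knots, coefficients, links and age
#' transform -- everything needed to reload and predict identically.
#'
#' @param model An `ri_model` or `ri_curves`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
save_ri_model <- function(model, path) {
  cm <- .as_curves(model)
  obj <- list(class = "ri_curves",
              family = cm$family,
              age_transform = "log(age_days + 1)",
              basis = cm$basis,
              curves = lapply(cm$curves, function(cv)
                cv[c("name", "type", "coef", "lam_pen", "edf")]),
              links = as.list(.par_links[.par_names(cm$family)]),
              loglik = cm$loglik, bic = cm$bic, n_eff = cm$n_eff,
              n = cm$n, edf_total = cm$edf_total,
              age_range = cm$age_range, converged = cm$converged)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' Reload a model serialized with [save_ri_model()]
#'
#' @param path Path to the JSON file.
#' @return An `ri_curves` object.
#' @export
load_ri_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  bas <- obj$basis
  bas$p <- as.integer(bas$p)
  curves <- lapply(obj$curves, function(cv) {
    cv$coef <- as.numeric(cv$coef)
    cv
  })
  structure(list(family = obj$family, basis = bas, curves = curves,
                 loglik = obj$loglik, edf_total = obj$edf_total,
                 bic = obj$bic, n_eff = obj$n_eff, n = obj$n,
                 age_range = as.numeric(obj$age_range),
                 converged = isTRUE(obj$converged)),
            class = "ri_curves")
}
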