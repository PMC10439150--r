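## Step 2: indirect estimation of the non-pathological distribution within
## one age group.
##
## The group's measurements are a mixture of a non-pathological majority and
## pathological admixture.  The non-pathological bulk is modelled with a
## one-parameter Box-Cox transformed normal (the BCCG distribution) scaled
## by a non-pathological fraction.  The model is found by a multi-level grid
## search over (lambda, mu, sigma, fraction) against the histogram of the
## raw values: the discrepancy is measured on variance-stabilised (square
## root) bin counts inside a central concentration region around the
## histogram mode, plus a one-sided penalty wherever the model predicts
## more counts than observed outside that region -- this keeps the model
## inside the data and makes it ignore one-sided pathological tails.
##
## This is a self-contained, documented indirect method with the same
## interface contract as any other: a pluggable routine mapping a value
## sample to an `np_model`.

.hist_breaks <- function(values) {
  ## Freedman-Diaconis with a floor of 30 bins
  n <- length(values)
  iqr <- stats::IQR(values)
  h <- 2 * iqr / n^(1 / 3)
  nb <- if (h <= 0) 30L else max(30L, ceiling(diff(range(values)) / h))
  seq(min(values), max(values), length.out = nb + 1L)
}

#' Locate the central concentration region of a sample
#'
#' Pre-processing for the indirect fit: finds the widest interval around
#' the modal histogram bin in which smoothed bin counts stay above a
#' fraction `theta` of the modal count.  This region is presumed to hold
#' the non-pathological bulk.
#'
#' @param values Positive measurement values (at least 100).
#' @param theta Count threshold as a fraction of the modal count.
#' @return List with `lo` and `hi` concentration bounds.
#' @export
estimate_central_region <- function(values, theta = 0.10) {
  if (length(values) < 100) stop("need at least 100 values for indirect fit")
  if (stats::sd(values) == 0) stop("degenerate input: zero variance")
  breaks <- .hist_breaks(values)
  cnt <- .bincount(values, breaks)
  ## light smoothing so a ragged peak does not fragment the region
  kern <- c(1, 2, 3, 2, 1) / 9
  sm <- stats::filter(cnt, kern, sides = 2)
  sm[is.na(sm)] <- cnt[is.na(sm)]
  sm <- as.numeric(sm)
  mode_bin <- which.max(sm)
  thr <- theta * sm[mode_bin]
  lo_bin <- mode_bin
  while (lo_bin > 1 && sm[lo_bin - 1] >= thr) lo_bin <- lo_bin - 1
  hi_bin <- mode_bin
  while (hi_bin < length(sm) && sm[hi_bin + 1] >= thr) hi_bin <- hi_bin + 1
  list(lo = breaks[lo_bin], hi = breaks[hi_bin + 1])
}

.bincount <- function(values, breaks) {
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  tabulate(idx, nbins = length(breaks) - 1L)
}

## BCCG cdf evaluated for a grid of parameter combinations at fixed edges:
## returns a G x E matrix
.grid_pbccg <- function(edges, lam, mu, sig) {
  G <- length(lam); E <- length(edges)
  le <- matrix(log(edges), G, E, byrow = TRUE) - log(mu)
  z <- matrix(0, G, E)
  nz <- abs(lam) > 1e-8
  if (any(nz))
    z[nz, ] <- (exp(le[nz, , drop = FALSE] * lam[nz]) - 1) / (lam[nz] * sig[nz])
  if (any(!nz))
    z[!nz, ] <- le[!nz, , drop = FALSE] / sig[!nz]
  Fz <- stats::pnorm(z)
  C <- rep(1, G)
  C[nz] <- stats::pnorm(1 / (sig[nz] * abs(lam[nz])))
  out <- Fz
  pos <- lam > 1e-8
  neg <- lam < -1e-8
  if (any(pos)) out[pos, ] <- (Fz[pos, , drop = FALSE] - (1 - C[pos])) / C[pos]
  if (any(neg)) out[neg, ] <- Fz[neg, , drop = FALSE] / C[neg]
  pmin(pmax(out, 0), 1)
}

#' Fit the non-pathological Box-Cox-normal model of an age group
#'
#' Multi-level grid search (coarse to refined) over skewness `lambda`,
#' location `mu`, scale `sigma` and the non-pathological fraction, against
#' the histogram of the raw values.  The search is fully deterministic
#' given the data and settings.
#'
#' @param values Positive measurement values of one age group (>= 100).
#' @param lambda_range Search range for the Box-Cox power.
#' @param frac_range Search range for the non-pathological fraction.
#' @param levels Number of refinement levels (>= 2).
#' @param shrink Range-shrink factor applied per refinement level.
#' @param penalty Weight of the one-sided exceedance penalty outside the
#'   central region.
#' @param theta Central-region threshold passed to
#'   [estimate_central_region()].
#' @return An object of class `np_model` with elements `lambda`, `mu`,
#'   `sigma`, `np_fraction`, `fit_cost`, `n` and `central_region`.
#' @export
fit_np_model <- function(values,
                         lambda_range = c(-1, 1.5),
                         frac_range = c(0.5, 1),
                         levels = 3L,
                         shrink = 0.3,
                         penalty = 4,
                         theta = 0.10) {
  if (length(values) < 100) stop("need at least 100 values for indirect fit")
  if (stats::sd(values) == 0) stop("degenerate input: zero variance")
  region <- estimate_central_region(values, theta)
  breaks <- .hist_breaks(values)
  obs <- .bincount(values, breaks)
  sobs <- sqrt(obs)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  inside <- mids >= region$lo & mids <= region$hi
  N <- length(values)

  mid <- (region$lo + region$hi) / 2
  sig0 <- max(1e-3, (region$hi - region$lo) / (4 * mid))
  lam_rng <- lambda_range
  mu_rng <- c(max(min(values), region$lo), region$hi)
  sig_rng <- log(sig0) + c(-log(4), log(4))
  f_rng <- frac_range

  best <- NULL
  for (lev in seq_len(levels)) {
    lam_g <- seq(lam_rng[1], lam_rng[2], length.out = 11)
    mu_g <- seq(mu_rng[1], mu_rng[2], length.out = 13)
    sig_g <- exp(seq(sig_rng[1], sig_rng[2], length.out = 11))
    f_g <- seq(f_rng[1], f_rng[2], length.out = 11)
    grid <- expand.grid(lam = lam_g, mu = mu_g, sig = sig_g,
                        KEEP.OUT.ATTRS = FALSE)
    P <- .grid_pbccg(breaks, grid$lam, grid$mu, grid$sig)
    binp <- P[, -1, drop = FALSE] - P[, -ncol(P), drop = FALSE]
    binp[binp < 0] <- 0
    sNP <- sqrt(N * binp)
    cost_f <- vapply(f_g, function(f) {
      d <- sqrt(f) * sNP
      inside_cost <- rowSums((sNP[, inside, drop = FALSE] * sqrt(f) -
                                rep(sobs[inside], each = nrow(sNP)))^2)
      exc <- d[, !inside, drop = FALSE] -
        rep(sobs[!inside], each = nrow(d))
      exc[exc < 0] <- 0
      inside_cost + penalty * rowSums(exc^2)
    }, numeric(nrow(grid)))
    hit <- arrayInd(which.min(cost_f), dim(cost_f))
    g <- hit[1]; fi <- hit[2]
    best <- list(lambda = grid$lam[g], mu = grid$mu[g], sigma = grid$sig[g],
                 np_fraction = f_g[fi], fit_cost = cost_f[g, fi])
    ## refine around the optimum
    w <- function(rng) diff(range(rng)) * shrink / 2
    lam_rng <- best$lambda + c(-1, 1) * w(lam_g)
    mu_rng <- pmax(min(values) * 0.5, best$mu + c(-1, 1) * w(mu_g))
    sig_rng <- log(best$sigma) + c(-1, 1) * w(log(sig_g))
    f_rng <- pmin(1, pmax(0.05, best$np_fraction + c(-1, 1) * w(f_g)))
  }
  structure(c(best, list(n = N, central_region = region)),
            class = "np_model")
}

#' @export
print.np_model <- function(x, ...) {
  cat(sprintf(paste0("Box-Cox-normal non-pathological model: lambda = %.3f,",
                     " mu = %.4g, sigma = %.4g\n"),
              x$lambda, x$mu, x$sigma)
      )
  cat(sprintf("  non-pathological fraction = %.3f (n = %d, cost = %.3g)\n",
              x$np_fraction, x$n, x$fit_cost))
  invisible(x)
}

#' Density of a fitted non-pathological model
#'
#' @param y Positive values.
#' @param model An `np_model`.
#' @return Density values of the Box-Cox-normal component (unscaled by the
#'   non-pathological fraction).
#' @export
bcn_pdf <- function(y, model) {
  dbccg(y, model$mu, model$sigma, model$lambda)
}

#' Reference limits of a fitted non-pathological model
#'
#' Quantile inversion of the Box-Cox-normal model; the 2.5th and 97.5th
#' percentiles are the age-group-specific reference limits.
#'
#' @param model An `np_model`.
#' @param probs Probabilities in (0, 1).
#' @return Named vector of quantiles, strictly increasing in `probs`.
#' @export
np_reference_limits <- function(model, probs = c(0.025, 0.975)) {
  stats::setNames(qbccg(probs, model$mu, model$sigma, model$lambda),
                  paste0("p", format(100 * probs)))
}
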