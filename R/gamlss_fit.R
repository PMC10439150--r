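## Step 4: weighted estimation of smooth age-dependent distribution
## parameters.
##
## Each distribution parameter (mu, sigma, lambda, and tau for the
## four-parameter families) is a smooth function of the transformed age
## u = log(age_days + 1), represented as a cubic B-spline with equally
## spaced interior knots and a second-order difference penalty (a
## P-spline).  The spline coefficients of all curves maximise the weighted
## penalized log-likelihood
##
##     sum_i w_i log f(y_i | theta(u_i))  -  0.5 sum_k lam_k b_k' P b_k
##
## by cyclic (backfitting-style) penalized iteratively reweighted least
## squares: per curve, first and second derivatives of the log-likelihood
## with respect to the curve's predictor are obtained by central
## differences, giving a working response and working weights for a
## penalized weighted least-squares update.  Smoothing strengths are not
## free knobs: per curve, the penalty is solved (by root finding) to hit a
## target effective df from a small grid, and the target is chosen by the
## same BIC later used to select the distribution family.  Parameterising
## the grid by effective df rather than raw penalty makes the fitted
## curves invariant to a global rescaling of the weights.

.par_links <- c(mu = "log", sigma = "log", lambda = "identity", tau = "log")

.par_names <- function(family)
  if (family == "BCCG") c("mu", "sigma", "lambda") else
    c("mu", "sigma", "lambda", "tau")

.link_inv <- function(eta, link)
  if (link == "log") exp(pmin(50, eta)) else eta

## default per-curve grids of target effective df (1 = constant in age)
.default_edf_grid <- function() list(
  mu     = c(2, 3, 4, 6, 9, 12, 16),
  sigma  = c(2, 3, 4, 6, 8, 10, 12),
  lambda = c(1, 2, 3, 4, 6, 8, 10),
  tau    = c(1, 2, 3, 4, 6, 8, 10))

## weighted quantile (type-7-like linear interpolation)
.wquantile <- function(x, w, p) {
  if (length(x) == 1L) return(rep(x, length(p)))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  stats::approx(cw, x, xout = p, rule = 2, ties = "ordered")$y
}

## linear solve with escalating ridge; near-flat likelihood directions
## (e.g. a kurtosis curve the data barely inform) otherwise break the
## penalized system
.safe_solve <- function(A, b) {
  sc <- mean(abs(diag(A)))
  if (!is.finite(sc) || sc <= 0) sc <- 1
  for (r in c(0, 1e-8, 1e-5, 1e-2)) {
    out <- tryCatch(solve(A + diag(r * sc, nrow(A)), b),
                    error = function(e) NULL)
    if (!is.null(out) && all(is.finite(out))) return(out)
  }
  NULL
}

.make_basis <- function(u, n_knots = 20) {
  ur <- range(u)
  nu <- length(unique(u))
  if (nu <= 5 || diff(ur) == 0)
    return(list(type = "constant_only", p = 1L, range = ur))
  k <- min(n_knots, max(2L, nu - 4L))
  interior <- seq(ur[1], ur[2], length.out = k + 2L)[-c(1L, k + 2L)]
  knots <- c(rep(ur[1], 4), interior, rep(ur[2], 4))
  list(type = "spline", knots = knots, p = k + 4L, range = ur)
}

.basis_matrix <- function(bas, u) {
  if (bas$type == "constant_only")
    return(matrix(1, length(u), 1L))
  if (any(u < bas$range[1] - 1e-9) || any(u > bas$range[2] + 1e-9))
    stop("age outside the fitted range; no extrapolation is performed")
  u <- pmin(bas$range[2], pmax(bas$range[1], u))
  splines::splineDesign(bas$knots, u, ord = 4L)
}

.pen_matrix <- function(p) {
  if (p < 3) return(diag(0, p))
  D <- diff(diag(p), differences = 2)
  crossprod(D)
}

## evaluate all parameter curves at the (cached) basis matrix
.curves_theta <- function(curves, B, n, replace = NULL) {
  th <- list()
  for (nm in names(curves)) {
    cv <- curves[[nm]]
    eta <- if (!is.null(replace) && replace$name == nm) replace$eta
    else if (cv$type == "constant") rep(cv$coef, n)
    else as.vector(B %*% cv$coef)
    if (nm == "lambda") eta <- pmax(-4, pmin(4, eta))
    th[[nm]] <- .link_inv(eta, .par_links[[nm]])
  }
  th
}

.curve_eta <- function(cv, B, n)
  if (cv$type == "constant") rep(cv$coef, n) else as.vector(B %*% cv$coef)

#' Fit smooth age-dependent distribution parameters by weighted penalized
#' maximum likelihood
#'
#' Fits a BCCG, BCPE or BCT distribution whose parameters vary smoothly
#' with age (P-spline curves in `log(age_days + 1)`), maximising the
#' weighted penalized log-likelihood.  Per-curve smoothing strength is
#' selected by BIC over a grid of target effective degrees of freedom; a
#' target of 1 collapses the curve to a constant.
#'
#' @param age Ages in days.
#' @param value Positive measurement values.
#' @param weights Probability weights in \[0, 1\] (one per measurement);
#'   `NULL` means unweighted.
#' @param family `"BCCG"`, `"BCPE"` or `"BCT"`.
#' @param n_knots Number of interior knots of each parameter curve.
#' @param edf_grid Named list of candidate effective-df targets per curve;
#'   see Details of the package vignette.  `NULL` uses the built-in grid.
#' @param select_smoothing If `FALSE`, skip the BIC smoothing search and
#'   use mid-grid defaults (used for warm-started refits).
#' @param init Optional fitted model of the same family used as a warm
#'   start (its curves and smoothing are reused).
#' @param max_cycles Maximum backfitting cycles.
#' @param tol Relative penalized log-likelihood convergence tolerance.
#' @param rng_seed Seed for the jittered restarts used on non-convergence.
#' @return Object of class `ri_curves`: family, basis, per-curve
#'   coefficients/penalties/edf, `loglik`, `bic`, `n_eff`, `converged`.
#' @export
fit_weighted_gamlss <- function(age, value, weights = NULL,
                                family = c("BCCG", "BCPE", "BCT"),
                                n_knots = 20, edf_grid = NULL,
                                select_smoothing = TRUE, init = NULL,
                                max_cycles = 200, tol = 1e-7,
                                rng_seed = 1L) {
  family <- match.arg(family)
  stopifnot(length(age) == length(value))
  if (is.null(weights)) weights <- rep(1, length(value))
  keep <- is.finite(value) & value > 0 & weights > 0
  if (sum(keep) < 50) stop("too few positively weighted points to fit")
  if (sum(keep) < 500)
    warning("fewer than 500 positively weighted points; fit may be unstable")
  y <- value[keep]; w <- weights[keep]; a <- age[keep]
  u <- log(a + 1)
  n <- length(y)
  bas <- .make_basis(u, n_knots)
  B <- .basis_matrix(bas, u)
  p <- ncol(B)
  P <- .pen_matrix(p)
  grids <- .default_edf_grid()
  if (!is.null(edf_grid)) grids[names(edf_grid)] <- edf_grid
  pars <- .par_names(family)

  loglik_vec <- function(th)
    tryCatch(family_log_density(family, y, th$mu, th$sigma, th$lambda,
                                if (is.null(th$tau)) 2 else th$tau),
             error = function(e) rep(-Inf, n))
  wll <- function(th) {
    ld <- loglik_vec(th)
    if (any(!is.finite(ld))) return(-Inf)
    sum(w * ld)
  }
  pen_of <- function(curves) {
    s <- 0
    for (cv in curves)
      if (cv$type == "spline")
        s <- s + 0.5 * cv$lam_pen * drop(crossprod(cv$coef, P %*% cv$coef))
    s
  }
  pll_of <- function(curves)
    wll(.curves_theta(curves, B, n)) - pen_of(curves)

  ## ---- initialization ------------------------------------------------
  init_curves <- function() {
    mw <- sum(w * y) / sum(w)
    sdw <- sqrt(sum(w * (y - mw)^2) / sum(w))
    skw <- sum(w * (y - mw)^3) / sum(w) / sdw^3
    lambda0 <- if (is.finite(skw) && skw > 2) 0 else 1
    ls_fit <- NULL
    if (p > 1) {
      nb <- min(40L, max(5L, length(unique(u)) %/% 2L))
      br <- seq(min(u), max(u), length.out = nb + 1L)
      bi <- findInterval(u, br, rightmost.closed = TRUE, all.inside = TRUE)
      mid <- (br[-1] + br[-length(br)]) / 2
      med <- mad <- rep(NA_real_, nb)
      for (b in seq_len(nb)) {
        s <- bi == b
        if (any(s) && sum(w[s]) > 0) {
          med[b] <- .wquantile(y[s], w[s], 0.5)
          mad[b] <- .wquantile(abs(y[s] - med[b]), w[s], 0.5)
        }
      }
      okb <- !is.na(med) & med > 0
      if (sum(okb) < 2) {
        mu_i <- rep(max(mw, 1e-6), n)
        sg_i <- rep(max(0.01, sdw / mw), n)
      } else {
        mu_i <- stats::approx(mid[okb], med[okb], xout = u, rule = 2,
                              ties = "ordered")$y
        sg <- pmax(0.01, 1.4826 * mad[okb] / med[okb])
        sg_i <- stats::approx(mid[okb], sg, xout = u, rule = 2,
                              ties = "ordered")$y
      }
      ridge <- diag(1e-8, p)
      ls_fit <- function(target) {
        A <- crossprod(B) + P + ridge
        drop(solve(A, crossprod(B, target)))
      }
    }
    curves <- list()
    curves$mu <- list(name = "mu", type = if (p == 1) "constant" else "spline",
                      coef = if (p == 1) log(mw) else ls_fit(log(mu_i)),
                      lam_pen = 1, edf_target = 6, edf = NA_real_)
    curves$sigma <- list(name = "sigma",
                         type = if (p == 1) "constant" else "spline",
                         coef = if (p == 1) log(max(0.01, sdw / mw))
                         else ls_fit(log(sg_i)),
                         lam_pen = 10, edf_target = 4, edf = NA_real_)
    curves$lambda <- list(name = "lambda", type = "constant", coef = lambda0,
                          lam_pen = 0, edf_target = 1, edf = 1)
    if ("tau" %in% pars)
      curves$tau <- list(name = "tau", type = "constant",
                         coef = log(if (family == "BCPE") 2 else 10),
                         lam_pen = 0, edf_target = 1, edf = 1)
    curves
  }

  ## ---- per-curve penalized IRLS update -------------------------------
  h_eps <- 1e-4
  deriv_eta <- function(curves, k) {
    cv <- curves[[k]]
    eta0 <- .curve_eta(cv, B, n)
    th_p <- .curves_theta(curves, B, n,
                          replace = list(name = k, eta = eta0 + h_eps))
    th_m <- .curves_theta(curves, B, n,
                          replace = list(name = k, eta = eta0 - h_eps))
    th_0 <- .curves_theta(curves, B, n)
    ldp <- loglik_vec(th_p); ldm <- loglik_vec(th_m); ld0 <- loglik_vec(th_0)
    bad <- !is.finite(ldp) | !is.finite(ldm) | !is.finite(ld0)
    l1 <- (ldp - ldm) / (2 * h_eps)
    l2 <- (ldp - 2 * ld0 + ldm) / h_eps^2
    l1[bad] <- 0; l2[bad] <- -1
    list(eta = eta0, l1 = l1, l2 = l2)
  }

  update_curve <- function(curves, k) {
    d <- deriv_eta(curves, k)
    curv <- -d$l2
    posc <- curv[curv > 0]
    floor_c <- if (length(posc)) max(1e-8, 1e-3 * stats::median(posc)) else 1e-3
    curv <- pmax(curv, floor_c)
    Wk <- w * curv
    zk <- d$eta + d$l1 / curv
    cv <- curves[[k]]
    old_pll <- pll_of(curves)
    if (cv$type == "constant") {
      step <- sum(w * d$l1) / sum(Wk)
      new_coef <- cv$coef + step
    } else {
      A <- crossprod(B, Wk * B) + cv$lam_pen * P
      sol <- .safe_solve(A, crossprod(B, Wk * zk))
      new_coef <- if (is.null(sol)) cv$coef else drop(sol)
    }
    ## step halving toward the old coefficients if the objective drops
    frac <- 1
    for (it in 1:6) {
      cand <- curves
      cand[[k]]$coef <- (1 - frac) * cv$coef + frac * new_coef
      new_pll <- pll_of(cand)
      if (is.finite(new_pll) && new_pll >= old_pll - 1e-10)
        return(cand)
      frac <- frac / 2
    }
    curves
  }

  edf_of_curve <- function(curves, k, lam = NULL) {
    cv <- curves[[k]]
    if (cv$type == "constant") return(1)
    if (is.null(lam)) lam <- cv$lam_pen
    d <- deriv_eta(curves, k)
    curv <- pmax(-d$l2, 1e-8)
    Wk <- w * curv
    BtWB <- crossprod(B, Wk * B)
    A <- BtWB + lam * P + diag(1e-9 * mean(diag(BtWB)), p)
    H <- .safe_solve(A, BtWB)
    if (is.null(H)) return(1)
    sum(diag(H))
  }

  lam_for_edf <- function(curves, k, target) {
    d <- deriv_eta(curves, k)
    curv <- pmax(-d$l2, 1e-8)
    Wk <- w * curv
    BtWB <- crossprod(B, Wk * B)
    ridge <- diag(1e-9 * mean(diag(BtWB)), p)
    edf_at <- function(loglam) {
      A <- BtWB + 10^loglam * P + ridge
      H <- .safe_solve(A, BtWB)
      if (is.null(H)) return(-target)
      sum(diag(H)) - target
    }
    lo <- -8; hi <- 14
    if (edf_at(lo) <= 0) return(10^lo)   # even no penalty is below target
    if (edf_at(hi) >= 0) return(10^hi)
    10^stats::uniroot(edf_at, c(lo, hi), tol = 1e-3)$root
  }

  run_cycles <- function(curves, which_k, cycles, tol_run) {
    pll <- pll_of(curves)
    for (cy in seq_len(cycles)) {
      for (k in which_k) curves <- update_curve(curves, k)
      new_pll <- pll_of(curves)
      if (is.finite(pll) && is.finite(new_pll) &&
          abs(new_pll - pll) < tol_run * (abs(pll) + 0.1)) {
        attr(curves, "converged") <- TRUE
        attr(curves, "pll") <- new_pll
        return(curves)
      }
      pll <- new_pll
    }
    attr(curves, "converged") <- FALSE
    attr(curves, "pll") <- pll
    curves
  }

  bic_of <- function(curves) {
    ll <- wll(.curves_theta(curves, B, n))
    edfs <- vapply(curves, function(cv) if (is.na(cv$edf)) 2 else cv$edf, 1)
    -2 * ll + sum(edfs) * log(sum(w))
  }

  ## ---- main fit ------------------------------------------------------
  if (!is.null(init) && inherits(init, "ri_curves") &&
      init$family == family) {
    curves <- init$curves
  } else {
    curves <- init_curves()
  }
  curves <- run_cycles(curves, pars, min(40, max_cycles), tol * 10)

  if (select_smoothing && p > 1) {
    for (k in pars) {
      cand_grid <- grids[[k]]
      best_bic <- Inf; best_curves <- curves
      for (target in cand_grid) {
        cand <- curves
        if (target <= 1) {
          eta_now <- .curve_eta(cand[[k]], B, n)
          cand[[k]] <- list(name = k, type = "constant",
                            coef = stats::weighted.mean(eta_now, w),
                            lam_pen = 0, edf_target = 1, edf = 1)
        } else {
          if (cand[[k]]$type == "constant") {
            cand[[k]] <- list(name = k, type = "spline",
                              coef = rep(cand[[k]]$coef, p),
                              lam_pen = 1, edf_target = target,
                              edf = NA_real_)
          }
          lam <- lam_for_edf(cand, k, target)
          cand[[k]]$lam_pen <- lam
          cand[[k]]$edf_target <- target
        }
        cand <- run_cycles(cand, k, 8, tol * 100)
        cand[[k]]$edf <- if (cand[[k]]$type == "constant") 1 else
          edf_of_curve(cand, k)
        bb <- bic_of(cand)
        if (is.finite(bb) && bb < best_bic - 1e-9) {
          best_bic <- bb; best_curves <- cand
        }
      }
      curves <- best_curves
      ## settle the other curves briefly after changing this one
      curves <- run_cycles(curves, pars, 5, tol * 100)
    }
  }

  curves <- run_cycles(curves, pars, max_cycles, tol)
  converged <- isTRUE(attr(curves, "converged"))
  if (!converged || !is.finite(attr(curves, "pll"))) {
    ## jittered restarts
    for (r in 1:2) {
      set.seed(rng_seed + 7919L * r)
      cand <- curves
      for (k in pars)
        cand[[k]]$coef <- cand[[k]]$coef +
          stats::rnorm(length(cand[[k]]$coef), sd = 0.02)
      cand <- run_cycles(cand, pars, max_cycles, tol)
      if (isTRUE(attr(cand, "converged")) &&
          is.finite(attr(cand, "pll")) &&
          attr(cand, "pll") >= attr(curves, "pll")) {
        curves <- cand
        converged <- TRUE
        break
      }
    }
  }
  if (!is.finite(attr(curves, "pll")))
    stop("weighted GAMLSS fit failed to reach a finite objective (family ",
         family, ")")

  for (k in pars)
    curves[[k]]$edf <- if (curves[[k]]$type == "constant") 1 else
      edf_of_curve(curves, k)
  ll <- wll(.curves_theta(curves, B, n))
  n_eff <- sum(w)
  edf_total <- sum(vapply(curves, `[[`, 1, "edf"))
  structure(list(family = family,
                 basis = bas,
                 curves = curves[pars],
                 loglik = ll,
                 edf_total = edf_total,
                 bic = -2 * ll + edf_total * log(n_eff),
                 n_eff = n_eff,
                 n = n,
                 age_range = range(a),
                 converged = converged),
            class = "ri_curves")
}

#' Evaluate the fitted parameter curves at given ages
#'
#' @param object An `ri_curves` fit.
#' @param age Ages in days, within the fitted range.
#' @return Data frame with columns `mu`, `sigma`, `lambda` (and `tau` for
#'   four-parameter families), one row per age.
#' @export
curve_params <- function(object, age) {
  stopifnot(inherits(object, "ri_curves"))
  if (any(age < object$age_range[1]) || any(age > object$age_range[2]))
    stop("age outside the fitted range [", object$age_range[1], ", ",
         object$age_range[2], "] days; no extrapolation is performed")
  u <- log(age + 1)
  B <- .basis_matrix(object$basis, u)
  th <- .curves_theta(object$curves, B, length(u))
  as.data.frame(th)
}

#' Select the distribution family by BIC
#'
#' @param models List of fitted `ri_curves` models (different families on
#'   the same data/weights).
#' @return The model with minimal BIC; ties go to fewer effective df, then
#'   to the family order BCCG, BCPE, BCT.
#' @export
select_best_family <- function(models) {
  models <- Filter(function(m) inherits(m, "ri_curves") &&
                     is.finite(m$bic), models)
  if (length(models) == 0) stop("all family fits failed")
  fam_rank <- match(vapply(models, `[[`, "", "family"),
                    c("BCCG", "BCPE", "BCT"))
  o <- order(vapply(models, `[[`, 1, "bic"),
             vapply(models, `[[`, 1, "edf_total"),
             fam_rank)
  models[[o[1]]]
}
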