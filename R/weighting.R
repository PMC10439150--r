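## Step 3: convert the per-group non-pathological models into exactly one
## probability-of-being-non-pathological weight per measurement.
##
## Within a group, the weight of a concentration c is the clipped ratio of
## the (absolutely scaled) non-pathological density to the total density of
## the raw data, lightly Gaussian-smoothed along the concentration axis:
##   P(c) = min(1, max(0, D_np(c) / D_total(c)))
## D_np is the fitted Box-Cox-normal density times the estimated
## non-pathological fraction; D_total is a Gaussian kernel density estimate
## of the group's raw values.  Because groups overlap, each measurement
## takes its weight only from the group whose centre is nearest its age.
## Finally the weight is divided by the subject's total number of samples
## in the whole dataset, down-weighting subjects represented many times.

#' Gaussian kernel density estimate at arbitrary points
#'
#' Exact (direct-sum) Gaussian KDE with Silverman's rule-of-thumb
#' bandwidth, evaluated at `eval_points`.  Used as the total-density
#' denominator of the weighting ratio.
#'
#' @param values Sample values (at least 2 distinct).
#' @param eval_points Points at which to evaluate the density.
#' @param bw Bandwidth; default Silverman's rule ([stats::bw.nrd0()]).
#' @return Density values at `eval_points`.
#' @export
empirical_density <- function(values, eval_points,
                              bw = stats::bw.nrd0(values)) {
  if (length(unique(values)) < 2) stop("degenerate input: zero variance")
  n <- length(values)
  ## chunk the evaluation grid to bound memory at ~1e6 doubles
  chunk <- max(1L, floor(1e6 / n))
  out <- numeric(length(eval_points))
  for (s in seq(1L, length(eval_points), by = chunk)) {
    e <- seq(s, min(s + chunk - 1L, length(eval_points)))
    out[e] <- colMeans(matrix(stats::dnorm(outer(values, eval_points[e],
                                                 "-") / bw),
                              nrow = n)) / bw
  }
  out
}

## discrete Gaussian convolution along a grid, kernel sd in grid steps;
## renormalised at the edges so a constant signal stays constant
.gauss_smooth <- function(x, sd_steps = 2) {
  half <- ceiling(4 * sd_steps)
  k <- stats::dnorm(seq(-half, half), sd = sd_steps)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  num <- vapply(seq_len(n), function(i) sum(xp[i:(i + 2 * half)] * rev(k)),
                numeric(1))
  ones <- c(rep(0, half), rep(1, n), rep(0, half))
  den <- vapply(seq_len(n), function(i) sum(ones[i:(i + 2 * half)] * rev(k)),
                numeric(1))
  num / den
}

#' Density-ratio weights for one age group
#'
#' Computes the probability of being non-pathological for each value in a
#' group: the ratio of the scaled model density to the kernel density of
#' the raw values, evaluated on a regular concentration grid, Gaussian-
#' smoothed, clipped to \[0, 1\] and linearly interpolated to the values.
#'
#' @param values The group's raw measurement values (the KDE sample for the
#'   total-density denominator).
#' @param model The group's fitted `np_model`.
#' @param eval_at Concentrations at which weights are wanted; defaults to
#'   `values`.
#' @param grid_n Number of grid points spanning the group's value range.
#' @param smooth_sd Smoothing kernel standard deviation in grid steps.
#' @return List with `weights` (one per `eval_at`, in \[0,1\]), and the
#'   diagnostic grid (`grid`, `ratio_raw`, `ratio`).
#' @export
density_ratio_weights <- function(values, model, eval_at = values,
                                  grid_n = 512, smooth_sd = 2) {
  rng <- range(values)
  if (rng[1] <= 0) stop("values must be positive")
  grid <- seq(rng[1], rng[2], length.out = grid_n)
  d_total <- empirical_density(values, grid)
  d_np <- model$np_fraction * bcn_pdf(grid, model)
  ratio_raw <- ifelse(d_total > 0, d_np / d_total, 0)
  ratio <- pmin(1, pmax(0, .gauss_smooth(ratio_raw, smooth_sd)))
  w <- stats::approx(grid, ratio, xout = eval_at, rule = 2)$y
  list(weights = pmin(1, pmax(0, w)), grid = grid,
       ratio_raw = ratio_raw, ratio = ratio)
}

#' Assign exactly one raw weight to every measurement
#'
#' Each measurement takes its weight from the group whose centre is nearest
#' its age (ties broken toward the younger centre), using that group's
#' fitted model.  Groups without a usable model are skipped, and their
#' would-be assignees fall to the nearest remaining group.
#'
#' @param data A `measurement_set`.
#' @param groups An `age_groups` object.
#' @param models List of `np_model` (or `NULL` for failed fits) aligned
#'   with `groups`.
#' @return Numeric vector `p_raw`, one weight in \[0,1\] per measurement.
#' @export
assign_single_weight <- function(data, groups, models) {
  stopifnot(length(groups) == length(models))
  ok <- !vapply(models, is.null, logical(1))
  if (!any(ok)) stop("no age group has a usable non-pathological model")
  if (any(!ok))
    message(sum(!ok), " age group(s) without a usable model; their ",
            "measurements fall to the nearest fitted group")
  centers <- vapply(groups, `[[`, 1L, "center")[ok]
  gidx <- which(ok)
  ages <- data$age_days
  ## nearest centre, ties toward the younger centre: centres are sorted, so
  ## findInterval + comparison with strict inequality on the right
  pos <- findInterval(ages, centers)
  lo <- pmax(1L, pos); hi <- pmin(length(centers), pos + 1L)
  pick_hi <- abs(centers[hi] - ages) < abs(ages - centers[lo])
  nearest <- ifelse(pick_hi, hi, lo)
  p_raw <- rep(NA_real_, nrow(data))
  for (j in sort(unique(nearest))) {
    g <- groups[[gidx[j]]]
    m <- models[[gidx[j]]]
    sel <- which(nearest == j)
    in_grp <- ages >= g$lower & ages <= g$upper
    grp_vals <- data$value[in_grp]
    if (length(unique(grp_vals)) < 2) grp_vals <- data$value
    dr <- density_ratio_weights(grp_vals, m, eval_at = data$value[sel])
    p_raw[sel] <- dr$weights
  }
  if (anyNA(p_raw))
    stop("measurements not covered by any fitted age group at ages: ",
         paste(utils::head(unique(ages[is.na(p_raw)])), collapse = ", "))
  p_raw
}

#' Down-weight subjects with multiple samples
#'
#' Divides each raw weight by the subject's total number of samples in the
#' whole dataset, so a subject contributes comparably no matter how often
#' it was sampled.
#'
#' @param p_raw Raw weights in \[0,1\].
#' @param subject_ids Subject identifiers aligned with `p_raw`.
#' @return Corrected weights `p_corr = p_raw / n_subject`.
#' @export
subject_correction <- function(p_raw, subject_ids) {
  stopifnot(length(p_raw) == length(subject_ids))
  n_subject <- stats::ave(rep(1, length(subject_ids)), subject_ids,
                          FUN = sum)
  p_raw / n_subject
}

#' Compute the full weight table for a measurement set
#'
#' Runs weight assignment and subject correction, returning one record per
#' measurement.
#'
#' @inheritParams assign_single_weight
#' @return Data frame with `p_raw`, `p_corr` and `n_subject`, one row per
#'   measurement.
#' @export
compute_weights <- function(data, groups, models) {
  p_raw <- assign_single_weight(data, groups, models)
  n_subject <- as.integer(stats::ave(rep(1, nrow(data)), data$subject_id,
                                     FUN = sum))
  data.frame(p_raw = p_raw, p_corr = p_raw / n_subject,
             n_subject = n_subject)
}
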