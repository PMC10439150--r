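## Step 1: overlapping age groups with high temporal resolution.
##
## Groups are centred on days of life.  The base half-width of a group grows
## with age (default 1% of the age in days), so neonatal groups have daily
## resolution while groups in late childhood are wider; consecutive centres
## are thinned so that base ranges tile the age axis without gaps.  Each
## group is then expanded symmetrically until it holds at least n_min
## members, where members are counted after keeping only one sample (the
## most age-central one) per subject.

#' Base half-width of an age group
#'
#' @param center Centre day(s).
#' @param width_growth Width growth fraction (default 1% of age in days).
#' @return Half-width in days, floored at 0.5 so the base group always
#'   covers at least its centre day.
#' @export
base_halfwidth <- function(center, width_growth = 0.01) {
  pmax(0.5, width_growth * center / 2)
}

#' Candidate age-group centres
#'
#' Daily candidate centres from day 1 to `max_age_days`, optionally thinned
#' so that consecutive base ranges are edge-to-edge: after the daily-
#' resolution regime (ages up to `1/width_growth` days), the next centre is
#' the smallest integer whose base lower edge lies beyond the previous base
#' upper edge.
#'
#' @param max_age_days Last modelled day of life.
#' @param width_growth Width growth fraction.
#' @param thin If `FALSE`, return all daily centres `1:max_age_days` (the
#'   resolution before width-based thinning).
#' @return Integer vector of centre days.
#' @export
candidate_centers <- function(max_age_days, width_growth = 0.01,
                              thin = TRUE) {
  stopifnot(max_age_days >= 1, width_growth > 0, width_growth < 1)
  if (!thin) return(seq_len(max_age_days))
  centers <- integer(0)
  c_cur <- 1
  while (c_cur <= max_age_days) {
    centers <- c(centers, as.integer(c_cur))
    if (base_halfwidth(c_cur + 1, width_growth) <= 0.5) {
      c_cur <- c_cur + 1   # daily resolution while widths are at the floor
      next
    }
    upper <- c_cur + base_halfwidth(c_cur, width_growth)
    ## smallest integer c' with c' - h(c') > upper
    nxt <- c_cur + 1
    cand <- floor(upper / (1 - width_growth / 2)) + 1
    if (cand > nxt && (cand - 1) - base_halfwidth(cand - 1, width_growth) > upper)
      cand <- cand - 1   # guard against rounding overshoot
    nxt <- max(nxt, cand)
    while (nxt - base_halfwidth(nxt, width_growth) <= upper)
      nxt <- nxt + 1
    c_cur <- nxt
  }
  ## clamp: a final group centred on the last day keeps the age axis covered
  last_upper <- centers[length(centers)] +
    base_halfwidth(centers[length(centers)], width_growth)
  if (floor(last_upper) < max_age_days)
    centers <- c(centers, as.integer(max_age_days))
  centers
}

## cumulative sample counts per day: cum_le(d) = #samples with age <= d,
## as a lookup vector indexed by day + 2 (so day -1 maps to index 1)
.day_cum <- function(ord_age) {
  amax <- ord_age[length(ord_age)]
  c(0L, cumsum(tabulate(ord_age + 1L, nbins = amax + 1L)))
}

.cum_le <- function(day_cum, d) {
  d <- max(-1L, min(length(day_cum) - 2L, d))
  day_cum[d + 2L]
}

## distinct subjects with >= 1 sample in the day window [lo, up]
.distinct_in_window <- function(lo, up, day_cum, ord_subj) {
  i1 <- .cum_le(day_cum, lo - 1L) + 1L
  i2 <- .cum_le(day_cum, up)
  if (i2 < i1) return(0L)
  length(unique(ord_subj[i1:i2]))
}

#' Expand an age group until it reaches the minimum member count
#'
#' Starting from the base range `[center - h, center + h]`, the bounds are
#' extended alternately by one day (lower bound first) until the group holds
#' at least `n_min` members after per-subject deduplication, or the range
#' covers the whole data.  At a data boundary all further extension goes to
#' the open side.  Members are counted as distinct subjects, since
#' deduplication retains exactly one sample per subject.
#'
#' @param center Centre day.
#' @param base_halfwidth Base half-width in days.
#' @param ages Integer ages of all measurements, sorted ascending.
#' @param subjects Integer subject codes aligned with `ages`.
#' @param n_min Minimum member count.
#' @param day_cum Optional precomputed per-day cumulative counts from the
#'   sorted ages (internal speed-up; computed when `NULL`).
#' @return List with integer `lower`, `upper` and logical `exhausted`
#'   (`TRUE` when the whole data range was reached without `n_min`
#'   members).
#' @export
expand_group_to_min_n <- function(center, base_halfwidth, ages, subjects,
                                  n_min, day_cum = NULL) {
  stopifnot(length(ages) > 0, !is.unsorted(ages))
  if (is.null(day_cum)) day_cum <- .day_cum(ages)
  amin <- ages[1L]; amax <- ages[length(ages)]
  lower <- max(amin, as.integer(floor(center - base_halfwidth)))
  upper <- min(amax, as.integer(ceiling(center + base_halfwidth)))
  if (center <= 1) lower <- min(lower, amin)   # day-0 samples join day-1 group
  nsamp <- function(lo, up)
    .cum_le(day_cum, up) - .cum_le(day_cum, lo - 1L)
  turn_left <- TRUE
  step <- function() {
    if (turn_left) {
      if (lower > amin) lower <<- lower - 1L else upper <<- upper + 1L
    } else {
      if (upper < amax) upper <<- upper + 1L else lower <<- lower - 1L
    }
    turn_left <<- !turn_left
  }
  ## phase 1: raw sample counts bound the distinct-subject count from above,
  ## and both grow monotonely along the schedule, so this fast-forwards to a
  ## state no later than the final one
  while (nsamp(lower, upper) < n_min && (lower > amin || upper < amax))
    step()
  ## phase 2: exact distinct-subject (post-deduplication) count
  cnt <- .distinct_in_window(lower, upper, day_cum, subjects)
  while (cnt < n_min && (lower > amin || upper < amax)) {
    step()
    cnt <- .distinct_in_window(lower, upper, day_cum, subjects)
  }
  list(lower = lower, upper = upper, exhausted = cnt < n_min)
}

#' Keep the most age-central sample per subject
#'
#' Within one age group, each subject contributes at most one sample: the
#' one whose age is closest to the group centre.  Ties are broken toward
#' the younger age, then toward the first occurrence.
#'
#' @param center Group centre day.
#' @param member_age Ages of the candidate member samples.
#' @param member_subject Subject codes aligned with `member_age`.
#' @param member_idx Indices (into the full dataset) aligned with
#'   `member_age`.
#' @return The subset of `member_idx` retained after deduplication.
#' @export
select_central_sample_per_subject <- function(center, member_age,
                                              member_subject, member_idx) {
  if (length(member_idx) == 0L) return(integer(0))
  dist <- abs(member_age - center)
  ## order by subject, then |age - center|, then age (younger first), then
  ## position: the first row per subject is the retained one
  o <- order(member_subject, dist, member_age, seq_along(member_idx))
  keep <- o[!duplicated(member_subject[o])]
  sort(member_idx[keep])
}

#' Build all age groups for a measurement set
#'
#' Runs the full first pipeline step: thinned candidate centres, expansion
#' of every group to at least `n_min` members, and per-subject
#' deduplication.
#'
#' @param data A `measurement_set` (or data frame with `age_days` and
#'   `subject_id`).
#' @param config An [ri_config()].
#' @return A list of class `age_groups`; each element has `center`,
#'   `base_lower`, `base_upper`, `lower`, `upper` and `member_idx` (indices
#'   into `data` after deduplication).
#' @export
build_age_groups <- function(data, config = ri_config()) {
  ages <- as.integer(data$age_days)
  subj <- match(data$subject_id, unique(data$subject_id))
  ord <- order(ages)
  ord_age <- ages[ord]; ord_subj <- subj[ord]
  day_cum <- .day_cum(ord_age)
  centers <- candidate_centers(config$max_age_days, config$width_growth)
  groups <- vector("list", length(centers))
  n_exhausted <- 0L
  for (k in seq_along(centers)) {
    cc <- centers[k]
    h <- base_halfwidth(cc, config$width_growth)
    rng <- expand_group_to_min_n(cc, h, ord_age, ord_subj, config$n_min,
                                 day_cum = day_cum)
    if (rng$exhausted) n_exhausted <- n_exhausted + 1L
    i1 <- .cum_le(day_cum, rng$lower - 1L) + 1L
    i2 <- .cum_le(day_cum, rng$upper)
    mem <- if (i2 >= i1) ord[i1:i2] else integer(0)
    midx <- select_central_sample_per_subject(cc, ages[mem], subj[mem], mem)
    groups[[k]] <- list(center = cc,
                        base_lower = if (cc <= 1) 0L else
                          max(0L, as.integer(floor(cc - h))),
                        base_upper = as.integer(ceiling(cc + h)),
                        lower = rng$lower, upper = rng$upper,
                        member_idx = midx)
  }
  if (n_exhausted > 0L)
    warning(n_exhausted, " age group(s) span the whole data range but ",
            "still hold fewer than n_min members")
  structure(groups, class = "age_groups")
}

#' @export
print.age_groups <- function(x, ...) {
  n <- vapply(x, function(g) length(g$member_idx), 1L)
  cat(sprintf("%d age groups, centres %d-%d days, members %d-%d\n",
              length(x), x[[1]]$center, x[[length(x)]]$center,
              min(n), max(n)))
  invisible(x)
}

#' Export an age-group table for diagnostics
#'
#' @param groups An `age_groups` object.
#' @return Data frame with one row per group: centre, base and expanded
#'   ranges, and member count.
#' @export
age_group_table <- function(groups) {
  data.frame(center = vapply(groups, `[[`, 1L, "center"),
             base_lower = vapply(groups, `[[`, 1L, "base_lower"),
             base_upper = vapply(groups, `[[`, 1L, "base_upper"),
             lower = vapply(groups, `[[`, 1L, "lower"),
             upper = vapply(groups, `[[`, 1L, "upper"),
             n = vapply(groups, function(g) length(g$member_idx), 1L))
}
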