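#' Validate a time division
#'
#' A time division partitions the simulation horizon `[0, T]` into intervals
#' over which enzyme activity coefficients are treated as constant.
#'
#' @param breakpoints Strictly increasing numeric vector of times (hr); the
#'   first must be 0 and there must be at least two.
#' @return The breakpoints, invisibly validated.
#' @export
time_division <- function(breakpoints) {
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) < 2L)
    abort("a time division needs at least two breakpoints")
  if (any(diff(breakpoints) <= 0))
    abort("time-division breakpoints must be strictly increasing")
  if (breakpoints[1] != 0)
    abort("a time division must start at 0")
  breakpoints
}

#' Build a time division from enzyme-activity profiles
#'
#' Breakpoints are placed at the change-points of the supplied activity
#' profiles: every sample time at which a profile's activity differs from its
#' previous sample (beyond a tiny relative tolerance). The union of all
#' change-points is completed with 0 and the horizon `T`.
#'
#' @param profiles Tibble of activity samples with columns `enzyme`,
#'   `time_hr`, `activity` (see [make_activity_profiles()]).
#' @param horizon Simulation horizon `T` in hr (> 0).
#' @param tol Relative tolerance below which two consecutive samples are
#'   considered equal.
#' @return Numeric vector of breakpoints spanning `[0, T]`.
#' @examples
#' prof <- make_activity_profiles(fixture_config())
#' build_time_division(prof, horizon = 24)
#' @export
build_time_division <- function(profiles, horizon, tol = 1e-12) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    abort("`horizon` must be a single positive time in hr")
  profiles <- .check_profiles(profiles)
  cps <- profiles |>
    dplyr::group_by(.data$enzyme) |>
    dplyr::arrange(.data$time_hr, .by_group = TRUE) |>
    dplyr::mutate(changed = c(FALSE, abs(diff(.data$activity)) >
                                tol * pmax(abs(.data$activity[-1]),
                                           abs(.data$activity[-dplyr::n()]), 1))) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$changed) |>
    dplyr::pull(.data$time_hr)
  bp <- sort(unique(c(0, cps[cps > 0 & cps < horizon], horizon)))
  time_division(bp)
}

# validate the tidy activity-profile layout
.check_profiles <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  need <- c("enzyme", "time_hr", "activity")
  if (!all(need %in% names(profiles)))
    abort("profiles need columns enzyme, time_hr, activity")
  if (any(profiles$activity < 0))
    abort("activities must be non-negative")
  dup <- profiles |>
    dplyr::count(.data$enzyme, .data$time_hr) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup))
    abort("each enzyme must have strictly increasing, unique sample times")
  profiles
}

# exact integral of the piecewise-linear interpolant of (tx, ax) over [a, b],
# with constant extension beyond the sampled range
.interp_integral <- function(tx, ax, a, b) {
  knots <- sort(unique(c(a, b, tx[tx > a & tx < b])))
  vals <- stats::approx(tx, ax, xout = knots, rule = 2)$y
  sum(diff(knots) * (head(vals, -1) + tail(vals, -1)) / 2)
}

#' Compute per-interval enzyme activity coefficients
#'
#' For each interval of the division, the coefficient is the average activity
#' over the interval divided by the profile's global maximum activity, so a
#' constant profile yields 1 everywhere and no coefficient exceeds 1.
#' Averages integrate the piecewise-linear interpolant of the samples
#' (trapezoid rule, exact on the interpolant). The samples must span the
#' division; an interval reaching outside the sampled time range is an error.
#'
#' @param profile Tibble with columns `time_hr`, `activity` (one enzyme).
#' @param division Breakpoints from [time_division()] or
#'   [build_time_division()].
#' @return Numeric vector of coefficients in `(0, 1]`, one per interval.
#' @examples
#' prof <- tibble::tibble(time_hr = c(0, 10, 20), activity = c(2, 8, 8))
#' compute_eac(prof, time_division(c(0, 10, 20)))
#' @export
compute_eac <- function(profile, division) {
  division <- time_division(division)
  profile <- tibble::as_tibble(profile)
  if (!all(c("time_hr", "activity") %in% names(profile)))
    abort("`profile` needs columns time_hr and activity")
  profile <- dplyr::arrange(profile, .data$time_hr)
  tx <- profile$time_hr
  ax <- profile$activity
  if (any(ax < 0)) abort("activities must be non-negative")
  amax <- max(ax)
  if (amax <= 0)
    abort("all-zero activity profile: enzyme activity coefficients are undefined")
  n_int <- length(division) - 1L
  out <- numeric(n_int)
  for (i in seq_len(n_int)) {
    a <- division[i]; b <- division[i + 1L]
    # the profile must span the division: an interval reaching outside the
    # sampled time range would be averaged from pure extrapolation
    if (a < min(tx) - 1e-9 || b > max(tx) + 1e-9)
      abort(sprintf("interval [%g, %g] has no profile coverage", a, b))
    out[i] <- .interp_integral(tx, ax, a, b) / (b - a) / amax
  }
  if (any(out <= 0))
    abort(sprintf("interval [%g, %g] has zero average activity",
                  division[which(out <= 0)[1]], division[which(out <= 0)[1] + 1L]))
  pmin(out, 1)
}

#' Build the full EAC schedule for a model
#'
#' Computes one piecewise-constant enzyme activity coefficient track per
#' reaction, on a shared time division: the diagonal of the regulation matrix
#' `E(t)`. Regulated reactions take the coefficients of their enzyme's
#' activity profile; reactions with constant activity (unregulated, or with no
#' profile supplied) get coefficient 1 in every interval.
#'
#' @param model An `abe_model`.
#' @param profiles Tidy activity samples (`enzyme`, `time_hr`, `activity`);
#'   the `enzyme` key is matched against reaction enzyme labels.
#' @param horizon Simulation horizon (hr); required unless `division` is given.
#' @param division Optional explicit breakpoints; defaults to
#'   [build_time_division()] of the profiles.
#' @return An `abe_eac_schedule`: breakpoints plus a reactions-by-intervals
#'   coefficient matrix. Convert with [tidy()] for the audit layout
#'   (reaction, interval_start, interval_end, eac).
#' @examples
#' m <- abe_model()
#' sched <- eac_schedule(m, make_activity_profiles(fixture_config()), horizon = 24)
#' tidy(sched)
#' @export
eac_schedule <- function(model, profiles, horizon = NULL, division = NULL) {
  stopifnot(inherits(model, "abe_model"))
  profiles <- .check_profiles(profiles)
  if (is.null(division)) {
    if (is.null(horizon)) abort("supply `horizon` or an explicit `division`")
    division <- build_time_division(profiles, horizon)
  } else {
    division <- time_division(division)
    if (!is.null(horizon) && abs(division[length(division)] - horizon) > 1e-12)
      abort("`division` must end at `horizon`")
  }
  n_int <- length(division) - 1L
  rids <- names(model$reactions)
  values <- matrix(1, nrow = length(rids), ncol = n_int,
                   dimnames = list(rids, NULL))
  by_enzyme <- split(profiles, profiles$enzyme)
  for (r in model$reactions) {
    if (r$regulated && r$enzyme %in% names(by_enzyme))
      values[r$id, ] <- compute_eac(by_enzyme[[r$enzyme]], division)
  }
  structure(list(breakpoints = division, values = values),
            class = "abe_eac_schedule")
}

#' A schedule with every coefficient fixed at 1 (unregulated dynamics)
#'
#' @param model An `abe_model`.
#' @param horizon Simulation horizon (hr).
#' @return An `abe_eac_schedule` with a single interval of coefficient 1 for
#'   every reaction; `dY/dt` reduces to `A v(Y; P)`.
#' @export
constant_schedule <- function(model, horizon) {
  stopifnot(inherits(model, "abe_model"))
  division <- time_division(c(0, horizon))
  rids <- names(model$reactions)
  structure(list(breakpoints = division,
                 values = matrix(1, length(rids), 1,
                                 dimnames = list(rids, NULL))),
            class = "abe_eac_schedule")
}

#' Look up an enzyme activity coefficient at a time point
#'
#' Interval membership uses the half-open convention `[t_i, t_{i+1})`; the
#' last interval is closed so the horizon itself is covered.
#'
#' @param schedule An `abe_eac_schedule`.
#' @param reaction Reaction id (e.g. `"R19"`).
#' @param t Time in hr, within `[0, T]`.
#' @return Coefficient in `(0, 1]`.
#' @export
eac_at <- function(schedule, reaction, t) {
  stopifnot(inherits(schedule, "abe_eac_schedule"))
  bp <- schedule$breakpoints
  if (!reaction %in% rownames(schedule$values))
    abort(sprintf("unknown reaction '%s'", reaction))
  if (any(t < bp[1] | t > bp[length(bp)]))
    abort(sprintf("t outside the schedule span [%g, %g]", bp[1], bp[length(bp)]))
  idx <- .interval_index(bp, t)
  unname(schedule$values[reaction, idx])
}

# half-open interval lookup [t_i, t_{i+1}), last interval closed
.interval_index <- function(bp, t) {
  idx <- findInterval(t, bp, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), length(bp) - 1L)
}

#' @export
print.abe_eac_schedule <- function(x, ...) {
  cat(sprintf("<abe_eac_schedule> %d reactions x %d interval(s); breakpoints: %s hr\n",
              nrow(x$values), ncol(x$values),
              paste(signif(x$breakpoints, 4), collapse = ", ")))
  invisible(x)
}

#' @describeIn eac_schedule Audit layout: one row per reaction and interval.
#' @param x An `abe_eac_schedule`.
#' @param ... Unused.
#' @export
tidy.abe_eac_schedule <- function(x, ...) {
  bp <- x$breakpoints
  n_int <- length(bp) - 1L
  tidyr::expand_grid(reaction = rownames(x$values), k = seq_len(n_int)) |>
    dplyr::mutate(
      interval_start = bp[.data$k],
      interval_end = bp[.data$k + 1L],
      eac = x$values[cbind(match(.data$reaction, rownames(x$values)), .data$k)]
    ) |>
    dplyr::select(-"k")
}
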