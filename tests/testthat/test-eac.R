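test_that("constant profiles give coefficient 1 in every interval", {
  prof <- tibble::tibble(time_hr = seq(0, 24, 4), activity = 3.7)
  expect_equal(compute_eac(prof, c(0, 6, 13, 24)), c(1, 1, 1))
})

test_that("interval averages are ratios to the global maximum", {
  # two intervals with averages 2 and 8, global maximum 8
  prof <- tibble::tibble(time_hr = c(0, 10, 10 + 1e-9, 20),
                         activity = c(2, 2, 8, 8))
  expect_equal(compute_eac(prof, c(0, 10, 20)), c(0.25, 1), tolerance = 1e-6)
})

test_that("irregularly sampled profiles match a dense-resampling oracle", {
  set.seed(7)
  for (rep in 1:5) {
    tx <- sort(c(0, runif(8, 0, 24), 24))
    ax <- runif(length(tx), 0.2, 5)
    prof <- tibble::tibble(time_hr = tx, activity = ax)
    division <- c(0, sort(runif(3, 1, 23)), 24)
    got <- compute_eac(prof, division)
    # oracle: trapezoid average of the linear interpolant on a dense grid
    # that includes the sample knots (exact for piecewise-linear curves)
    oracle <- vapply(seq_len(length(division) - 1L), function(i) {
      a <- division[i]; b <- division[i + 1L]
      grid <- sort(unique(c(seq(a, b, length.out = 4001), tx[tx > a & tx < b])))
      vals <- approx(tx, ax, xout = grid, rule = 2)$y
      avg <- sum(diff(grid) * (head(vals, -1) + tail(vals, -1)) / 2) / (b - a)
      avg / max(ax)
    }, numeric(1))
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("EAC is scale-invariant and never exceeds 1", {
  set.seed(11)
  tx <- seq(0, 24, 2)
  ax <- runif(length(tx), 0.1, 4)
  prof <- tibble::tibble(time_hr = tx, activity = ax)
  division <- c(0, 5, 9, 16, 24)
  e1 <- compute_eac(prof, division)
  e2 <- compute_eac(dplyr::mutate(prof, activity = activity * 37.5), division)
  expect_equal(e1, e2)
  expect_true(all(e1 <= 1 & e1 > 0))
})

test_that("degenerate profiles are rejected", {
  expect_error(compute_eac(tibble::tibble(time_hr = c(0, 10), activity = c(0, 0)),
                           c(0, 10)), "all-zero")
  # interval entirely outside the sampled span
  expect_error(compute_eac(tibble::tibble(time_hr = c(0, 5), activity = c(1, 2)),
                           c(0, 5, 20)), "coverage")
})

test_that("time divisions are built from profile change-points", {
  expect_error(build_time_division(make_activity_profiles(fixture_config()), -1),
               "positive")

  # single constant profile: no interior change-points
  const <- tibble::tibble(enzyme = "E", time_hr = 0:24, activity = 1)
  expect_equal(build_time_division(const, 24), c(0, 24))

  # two profiles changing at 4 and 9 hr
  p1 <- tibble::tibble(enzyme = "E1", time_hr = 0:12,
                       activity = ifelse(0:12 < 4, 1, 0.5))
  p2 <- tibble::tibble(enzyme = "E2", time_hr = 0:12,
                       activity = ifelse(0:12 < 9, 0.2, 1))
  expect_equal(build_time_division(dplyr::bind_rows(p1, p2), 12),
               c(0, 4, 9, 12))

  # randomized step profiles: breakpoints recover the true step locations
  set.seed(3)
  for (rep in 1:5) {
    steps <- sort(sample(1:23, 4))
    lv <- runif(5, 0.2, 2)
    tt <- 0:24
    val <- lv[findInterval(tt, steps) + 1L]
    prof <- tibble::tibble(enzyme = "E", time_hr = tt, activity = val)
    expect_equal(build_time_division(prof, 24), c(0, steps, 24))
  }
})

test_that("eac_at uses half-open intervals and matches a linear scan", {
  m <- abe_model()
  prof <- make_activity_profiles(fixture_config())
  sched <- eac_schedule(m, prof, horizon = 24)

  # unregulated reaction: always 1
  expect_equal(eac_at(sched, "R2", 3), 1)
  expect_equal(eac_at(sched, "R2", 23), 1)

  # value at an interior breakpoint belongs to the right interval
  bp <- sched$breakpoints[2]
  left <- eac_at(sched, "R19", bp - 1e-9)
  right <- eac_at(sched, "R19", bp)
  expect_false(isTRUE(all.equal(left, right)))
  expect_equal(right, eac_at(sched, "R19", bp + 1e-9))

  # horizon itself is covered (last interval closed)
  expect_no_error(eac_at(sched, "R19", 24))
  expect_error(eac_at(sched, "R19", 24.01), "outside")
  expect_error(eac_at(sched, "R19", -0.1), "outside")

  # random queries agree with a linear scan over intervals
  set.seed(5)
  rids <- rownames(sched$values)
  for (i in 1:50) {
    rid <- sample(rids, 1)
    t <- runif(1, 0, 24)
    k <- max(which(sched$breakpoints <= t + 1e-15))
    k <- min(k, ncol(sched$values))
    expect_equal(eac_at(sched, rid, t), unname(sched$values[rid, k]))
  }
})

test_that("eac_at is constant inside each interval", {
  sched <- eac_schedule(abe_model(), make_activity_profiles(fixture_config()),
                        horizon = 24)
  bp <- sched$breakpoints
  for (k in seq_len(length(bp) - 1L)) {
    tt <- seq(bp[k], bp[k + 1L] - 1e-6, length.out = 25)
    vals <- vapply(tt, function(t) eac_at(sched, "R19", t), numeric(1))
    expect_equal(vals, rep(vals[1], length(vals)))
  }
})

test_that("refining the division never changes a constant-profile schedule", {
  prof <- tibble::tibble(time_hr = 0:24, activity = 2)
  coarse <- compute_eac(prof, c(0, 12, 24))
  fine <- compute_eac(prof, c(0, 3, 7, 12, 18, 24))
  expect_true(all(coarse == 1) && all(fine == 1))

  # step profile: refinement is inert where the interpolated profile is
  # constant (the sampled ramp between 7 and 8 hr makes [0,8] non-constant,
  # so only truly constant stretches are compared)
  prof2 <- tibble::tibble(time_hr = 0:24,
                          activity = ifelse(0:24 < 8, 1, 0.4))
  base <- compute_eac(prof2, c(0, 8, 24))
  refined <- compute_eac(prof2, c(0, 4, 8, 16, 24))
  expect_equal(refined[1], 1)                      # constant at the maximum
  expect_equal(refined[3:4], c(base[2], base[2]))  # constant post-step
})

test_that("regulated reactions carry their enzyme profile, others get 1", {
  m <- abe_model()
  sched <- eac_schedule(m, make_activity_profiles(fixture_config()),
                        horizon = 24)
  td <- tidy(sched)
  expect_named(td, c("reaction", "interval_start", "interval_end", "eac"))
  unregulated <- names(Filter(function(r) !r$regulated, m$reactions))
  expect_true(all(td$eac[td$reaction %in% unregulated] == 1))
  expect_true(all(td$eac > 0 & td$eac <= 1))
  # solventogenic BDH is suppressed pre-switch
  expect_lt(td$eac[td$reaction == "R19" & td$interval_start == 0], 0.2)
})
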