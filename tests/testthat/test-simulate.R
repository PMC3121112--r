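test_that("the assembled derivative vanishes at the empty state", {
  setup <- default_setup_cached()
  ode <- assemble_ode(setup$model, setup$params, setup$schedule)
  y0 <- setNames(rep(0, 17), species_order(setup$model))
  expect_equal(unname(ode(1, y0)), rep(0, 17))
})

test_that("an EAC of 0.5 halves the unregulated derivative", {
  m <- toy_decay_model()
  p <- c(kdec = 0.3)
  half <- structure(list(breakpoints = c(0, 10),
                         values = matrix(0.5, 1, 1, dimnames = list("R1", NULL))),
                    class = "abe_eac_schedule")
  ode_full <- assemble_ode(m, p, NULL)
  ode_half <- assemble_ode(m, p, half)
  y <- c(A = 2, B = 0)
  expect_equal(ode_half(1, y), ode_full(1, y) / 2)
})

test_that("derivatives match an independent triple-loop oracle", {
  setup <- default_setup_cached()
  m <- setup$model
  A <- stoich_matrix(m)
  sched <- setup$schedule
  ode <- assemble_ode(m, setup$params, sched)
  sp <- species_order(m)
  set.seed(19)
  for (rep in 1:5) {
    y <- setNames(runif(length(sp), 0, 40), sp)
    t <- runif(1, 0, 24)
    v <- rate_vector(m, y, setup$params)
    k <- min(max(which(sched$breakpoints <= t)), ncol(sched$values))
    dy <- numeric(length(sp))
    for (i in seq_along(sp))
      for (j in seq_along(v))
        dy[i] <- dy[i] + A[i, j] * sched$values[j, k] * v[j]
    expect_equal(unname(ode(t, y)), dy, tolerance = 1e-12)
  }
})

test_that("dimension mismatch between schedule and model is an error", {
  m <- abe_model()
  sched_toy <- constant_schedule(toy_decay_model(), 24)
  expect_error(assemble_ode(m, default_parameters(), sched_toy),
               "dimension mismatch|do not agree")
  expect_error(abe_setup(m, default_parameters(), c(Glc = 1),
                         schedule = sched_toy), "do not agree")
})

test_that("an all-zero initial state stays at the fixed point", {
  setup <- abe_setup(abe_model(), default_parameters(),
                     c(Glc = 0), horizon = 5)
  traj <- simulate_abe(setup)
  expect_true(all(as.matrix(traj[, -1]) == 0))
})

test_that("mass-action decay matches the closed form", {
  m <- toy_decay_model()
  setup <- abe_setup(m, c(kdec = 0.3), c(A = 2), horizon = 10, dt = 0.5)
  for (engine in c("compiled", "r")) {
    traj <- simulate_abe(setup, engine = engine)
    expect_equal(traj$A, 2 * exp(-0.3 * traj$time_hr), tolerance = 1e-6)
    expect_equal(traj$B, 2 - traj$A, tolerance = 1e-6)
  }
})

test_that("a two-step MM chain matches a fine-grid RK4 oracle", {
  m <- toy_chain_model()
  p <- toy_chain_params()
  setup <- abe_setup(m, p, c(A = 3), horizon = 10, dt = 1)
  traj <- simulate_abe(setup)
  f <- function(t, y) {
    v1 <- p["VmaxA"] * max(y[1], 0) / (p["KmA"] + max(y[1], 0))
    v2 <- p["VmaxB"] * max(y[2], 0) / (p["KmB"] + max(y[2], 0))
    c(-v1, v1 - v2, v2)
  }
  oracle <- rk4(f, c(3, 0, 0), traj$time_hr, h = 1e-3)
  got <- as.matrix(traj[, c("A", "B", "C")])
  expect_equal(unname(got), unname(oracle), tolerance = 1e-5)
})

test_that("compiled and pure-R engines agree on the default scenario", {
  setup <- abe_default_setup(dt = 1)
  tc <- simulate_abe(setup, engine = "compiled")
  tr <- simulate_abe(setup, engine = "r")
  expect_equal(as.matrix(tc[, -1]), as.matrix(tr[, -1]), tolerance = 1e-6)
})

test_that("all-ones schedules reduce the dynamics to A v", {
  m <- abe_model()
  p <- default_parameters()
  # refined all-ones schedule vs no regulation at all
  ones <- structure(list(
    breakpoints = c(0, 5, 11, 18, 24),
    values = matrix(1, length(m$reactions), 4,
                    dimnames = list(names(m$reactions), NULL))),
    class = "abe_eac_schedule")
  s1 <- abe_setup(m, p, c(Glc = 300), schedule = ones, horizon = 24, dt = 2)
  s2 <- abe_setup(m, p, c(Glc = 300), schedule = NULL, horizon = 24, dt = 2)
  t1 <- simulate_abe(s1)
  t2 <- simulate_abe(s2)
  expect_equal(as.matrix(t1[, -1]), as.matrix(t2[, -1]), tolerance = 1e-7)

  # and matches an independent straight A %*% v integration
  A <- stoich_matrix(m)
  pv <- as_param_vector(p)
  f <- function(t, y, parms) {
    names(y) <- rownames(A)
    list(as.numeric(A %*% rate_vector(m, y, pv)))
  }
  y0 <- setNames(rep(0, 17), rownames(A)); y0["Glc"] <- 300
  ref <- deSolve::lsoda(y0, t2$time_hr, f, NULL, rtol = 1e-8, atol = 1e-10)
  expect_equal(as.matrix(t2[, rownames(A)]), unname(ref[, -1]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("trajectories are invariant to the output grid", {
  setup <- default_setup_cached()
  base <- default_control_cached()
  shared <- c(0, 2.5, 8, 13.7, 24)
  sparse <- simulate_abe(setup, times = shared)
  dense_at_shared <- simulate_abe(setup,
                                  times = sort(unique(c(shared, seq(0, 24, 0.37)))))
  i <- match(shared, sparse$time_hr)
  j <- vapply(shared, function(t) which.min(abs(dense_at_shared$time_hr - t)), 1L)
  expect_equal(as.matrix(sparse[i, -1]), as.matrix(dense_at_shared[j, -1]),
               tolerance = 1e-6)
  # grid times present in the default run agree too
  k <- match(c(8, 16, 24), base$time_hr)
  l <- match(c(8, 16, 24), sparse$time_hr)
  expect_equal(as.matrix(base[k[!is.na(l)], -1]),
               as.matrix(sparse[l[!is.na(l)], -1]), tolerance = 1e-6)
})

test_that("halving solver tolerances barely moves the solution", {
  tight <- simulate_abe(abe_default_setup(dt = 2, rtol = 5e-9, atol = 5e-11))
  base <- simulate_abe(abe_default_setup(dt = 2))
  delta <- max(abs(as.matrix(tight[, -1]) - as.matrix(base[, -1])))
  expect_lt(delta, 10 * 1e-8 * 300)  # 10 x rtol x concentration scale
})

test_that("the default run shows the two-phase fermentation pattern", {
  traj <- default_control_cached()
  final <- function(sp) traj[[sp]][nrow(traj)]
  peak_t <- function(sp) traj$time_hr[which.max(traj[[sp]])]

  # acids rise then fall
  for (acid in c("Ace", "But")) {
    expect_gt(peak_t(acid), 1)
    expect_lt(peak_t(acid), 20)
    expect_lt(final(acid), 0.95 * max(traj[[acid]]))
  }
  # solvents accumulate late: most of the final stock is made post-switch
  for (solvent in c("BuOH", "Actn", "EtOH")) {
    at_switch <- traj[[solvent]][traj$time_hr == 8]
    expect_lt(at_switch, 0.25 * final(solvent))
    expect_gt(final(solvent), 1)
  }
  # the early BuP peak occurs at/before the onset of butanol accumulation
  # (time of maximal butanol production rate)
  rate <- diff(traj$BuOH) / diff(traj$time_hr)
  onset <- traj$time_hr[which.max(rate)]
  expect_lte(peak_t("BuP"), onset)
  expect_lt(peak_t("BuP"), 12)  # an *early* peak

  expect_equal(attr(traj, "n_clipped"), 0L)
  expect_true(all(as.matrix(traj[, -1]) >= 0))
})

test_that("setup validation catches bad inputs", {
  m <- abe_model()
  p <- default_parameters()
  expect_error(abe_setup(m, p, c(Glc = -1)), "non-negative")
  expect_error(abe_setup(m, p, c(Xyz = 1)), "named vector over model species")
  expect_error(abe_setup(m, p[-1, ], c(Glc = 1)), "missing model parameter")
  expect_error(abe_setup(m, p, c(Glc = 1), horizon = 0), "positive")
  setup <- abe_setup(m, p, c(Glc = 1), horizon = 2)
  expect_error(simulate_abe(setup, times = c(0, 3)), "within")
})
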