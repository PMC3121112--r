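test_that("default ABE model has the documented structure", {
  m <- abe_model()
  g <- glance(m)
  expect_equal(g$n_species, 17L)
  expect_equal(g$n_reactions, 21L)
  expect_equal(g$n_parameters, 50L)
  expect_equal(anyDuplicated(m$species$id), 0L)
  expect_equal(anyDuplicated(parameter_names(m)), 0L)

  # BuP participates in exactly the PTB- and BK-mediated reactions
  touching <- Filter(function(r) "BuP" %in% names(r$stoich), m$reactions)
  expect_setequal(vapply(touching, `[[`, "", "id"),
                  c("R17", "R18", "R20", "R21"))
  expect_setequal(unique(vapply(touching, `[[`, "", "enzyme")),
                  c("BK", "PTB"))
  producers <- Filter(function(r) r$stoich[["BuP"]] > 0, touching)
  consumers <- Filter(function(r) r$stoich[["BuP"]] < 0, touching)
  expect_setequal(vapply(producers, `[[`, "", "id"), c("R17", "R18"))
  expect_setequal(vapply(consumers, `[[`, "", "id"), c("R20", "R21"))
})

test_that("model construction is deterministic", {
  expect_identical(tidy(abe_model()), tidy(abe_model()))
  expect_identical(stoich_matrix(abe_model()), stoich_matrix(abe_model()))
})

test_that("splitting the lumped butyrate branch adds BuP and 5 parameters", {
  pre <- abe_model(bup = FALSE)
  expect_equal(nrow(pre$species), 16L)
  expect_equal(length(pre$reactions), 19L)

  post <- split_lumped_butyrate_branch(pre)
  expect_equal(nrow(post$species), nrow(pre$species) + 1L)
  new_par <- setdiff(parameter_names(post), parameter_names(pre))
  expect_length(new_par, 5L)
  expect_setequal(new_par, attr(post, "new_parameters"))

  # all reactions outside the branch untouched
  unchanged <- setdiff(names(pre$reactions), c("R17", "R18"))
  for (id in unchanged)
    expect_identical(pre$reactions[[id]], post$reactions[[id]])

  # the split model is the bundled default
  expect_identical(tidy(post), tidy(abe_model()))

  # applying twice violates the precondition
  expect_error(split_lumped_butyrate_branch(post), "lumped")
})

test_that("rate laws obey their closed forms", {
  p <- c(V = 10, K = 1, KI = 4, KA = 2, kk = 0.7)
  mk <- function(kind, params, effector = NULL)
    abe_reaction("R1", "E", c(S = -1, P = 1), kind, "S", params,
                 effector = effector)

  mm <- mk("michaelis_menten", list(Vmax = "V", Km = "K"))
  expect_equal(evaluate_rate(mm, c(S = 0), p), 0)           # zero substrate
  expect_equal(evaluate_rate(mm, c(S = 1), p), 5)           # S = Km -> Vmax/2

  ma <- mk("mass_action", list(k = "kk"))
  expect_equal(evaluate_rate(ma, c(S = 3), p), 2.1)

  # substrate inhibition at S=2, Km=1, Ki=4: 10*2/(1+2+4/4) = 5
  si <- mk("substrate_inhibition", list(Vmax = "V", Km = "K", Ki = "KI"))
  expect_equal(evaluate_rate(si, c(S = 2), p), 5)

  # noncompetitive product inhibition: MM * 1/(1 + P/Ki)
  pi_ <- mk("product_inhibition", list(Vmax = "V", Km = "K", Ki = "KI"),
            effector = "P")
  expect_equal(evaluate_rate(pi_, c(S = 1, P = 4), p), 5 / 2)
  expect_equal(evaluate_rate(pi_, c(S = 1, P = 0), p), 5)

  # essential activation: MM * A/(Ka + A); zero without activator
  ac <- abe_reaction("R1", "E", c(S = -1, P = 1), "activation", "S",
                     list(Vmax = "V", Km = "K", Ka = "KA"), effector = "A")
  expect_equal(evaluate_rate(ac, c(S = 1, A = 2), p), 5 * 0.5)
  expect_equal(evaluate_rate(ac, c(S = 1, A = 0), p), 0)

  # two-substrate MM multiplies saturation terms
  mm2 <- abe_reaction("R1", "E", c(S = -1, S2 = -1, P = 1),
                      "michaelis_menten", c("S", "S2"),
                      list(Vmax = "V", Km = c("K", "KA")))
  expect_equal(evaluate_rate(mm2, c(S = 1, S2 = 2), p), 10 * 0.5 * 0.5)
})

test_that("missing parameters raise an error naming the slot", {
  r <- abe_model()$reactions$R19
  expect_error(evaluate_rate(r, c(BCoA = 1, But = 1), c(Vmax19 = 1, Km19 = 1)),
               "Ka19")
})

test_that("rates are finite, non-negative, and monotone where expected", {
  m <- abe_model()
  p <- default_parameters()
  set.seed(101)
  sp <- species_order(m)
  for (i in 1:20) {
    y <- setNames(runif(length(sp), 0, 50), sp)
    v <- rate_vector(m, y, p)
    expect_true(all(is.finite(v)))
    expect_true(all(v >= 0))
  }
  # monotone non-decreasing in substrate for MM forms without
  # substrate inhibition
  mono <- Filter(function(r) r$kind %in%
                   c("michaelis_menten", "product_inhibition", "activation",
                     "mass_action"), m$reactions)
  y <- setNames(rep(5, length(sp)), sp)
  for (r in mono) {
    s <- r$substrates[1]
    grid <- c(0, 0.5, 2, 10, 80)
    vals <- vapply(grid, function(conc) {
      y2 <- y; y2[s] <- conc
      evaluate_rate(r, y2, p)
    }, numeric(1))
    expect_true(all(diff(vals) >= -1e-12), label = r$id)
  }
})

test_that("stoichiometric matrix reproduces hand-written balances", {
  m <- abe_model()
  A <- stoich_matrix(m)
  expect_equal(dim(A), c(17L, 21L))
  expect_identical(rownames(A), sort(m$species$id, method = "radix"))

  # column support equals the participating species
  for (r in m$reactions) {
    nz <- rownames(A)[A[, r$id] != 0]
    expect_setequal(nz, names(r$stoich))
  }

  # toy single reaction: one column (-1, +1)
  Ad <- stoich_matrix(toy_decay_model())
  expect_equal(unname(Ad[, 1]), c(-1L, 1L))

  # 3-species chain: A v equals the hand-written per-species balance
  Ac <- stoich_matrix(toy_chain_model())
  set.seed(42)
  for (i in 1:10) {
    v <- runif(2)
    balance <- c(A = -v[1], B = v[1] - v[2], C = v[2])
    expect_equal(as.numeric(Ac %*% v), unname(balance[rownames(Ac)]))
  }
})

test_that("model validation rejects unknown species and duplicate bindings", {
  sp <- tibble::tibble(id = "A", name = "a", role = "intermediate")
  bad <- abe_reaction("R1", "E", c(A = -1, Z = 1), "mass_action", "A",
                      params = list(k = "k1"))
  expect_error(new_abe_model(sp, list(bad)), "unknown species")

  sp2 <- tibble::tibble(id = c("A", "B"), name = c("a", "b"),
                        role = rep("intermediate", 2))
  r1 <- abe_reaction("R1", "E", c(A = -1, B = 1), "mass_action", "A",
                     params = list(k = "k1"))
  r2 <- abe_reaction("R2", "E", c(B = -1, A = 1), "mass_action", "B",
                     params = list(k = "k1"))
  expect_error(new_abe_model(sp2, list(r1, r2)), "more than one slot")
})
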