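# small toy models and lazily cached default objects shared across tests

# one-reaction decay toy: A -> B, first-order mass action
toy_decay_model <- function() {
  new_abe_model(
    species = tibble::tibble(id = c("A", "B"), name = c("a", "b"),
                             role = c("external-substrate", "end-product")),
    reactions = list(
      abe_reaction("R1", "ENZ", c(A = -1, B = 1), "mass_action", "A",
                   params = list(k = "kdec"))
    )
  )
}

# two-step irreversible MM chain: A -> B -> C
toy_chain_model <- function() {
  new_abe_model(
    species = tibble::tibble(id = c("A", "B", "C"), name = c("a", "b", "c"),
                             role = c("external-substrate", "intermediate",
                                      "end-product")),
    reactions = list(
      abe_reaction("R1", "E1", c(A = -1, B = 1), "michaelis_menten", "A",
                   params = list(Vmax = "VmaxA", Km = "KmA")),
      abe_reaction("R2", "E2", c(B = -1, C = 1), "michaelis_menten", "B",
                   params = list(Vmax = "VmaxB", Km = "KmB"))
    )
  )
}

toy_chain_params <- function() c(VmaxA = 2, KmA = 0.5, VmaxB = 1.5, KmB = 0.8)

# classic fixed-step RK4 for small systems, used as an independent
# integration oracle
rk4 <- function(f, y0, times, h) {
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y0))
  y <- y0
  t <- times[1]
  out[1, ] <- y
  for (i in 2:length(times)) {
    while (t < times[i] - 1e-12) {
      step <- min(h, times[i] - t)
      k1 <- f(t, y)
      k2 <- f(t + step / 2, y + step / 2 * k1)
      k3 <- f(t + step / 2, y + step / 2 * k2)
      k4 <- f(t + step, y + step * k3)
      y <- y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + step
    }
    out[i, ] <- y
  }
  out
}

# lazy cache so expensive default-scenario objects are built once per run
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

default_setup_cached <- function() cached("setup", abe_default_setup())

default_control_cached <- function()
  cached("control", simulate_abe(default_setup_cached()))

# full +5% / -5% single-parameter sweeps, shared by several acceptance checks
sweep_up_cached <- function()
  cached("sweep_up", sweep_single(default_setup_cached(), 0.05, 1))

sweep_down_cached <- function()
  cached("sweep_down", sweep_single(default_setup_cached(), 0.05, -1))

rd_of <- function(spec) {
  setup <- default_setup_cached()
  pert <- simulate_abe(setup, params = apply_perturbation(setup$params, spec))
  compute_rd(pert, default_control_cached())$rd
}
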