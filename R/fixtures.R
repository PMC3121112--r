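#' Configuration of the synthetic fixture generator
#'
#' @param seed Integer seed driving every random draw of the generator.
#' @param noise_sd Multiplicative lognormal noise (standard deviation of the
#'   log) applied to reference observations; default 0.05.
#' @param obs_times Observation grid in hr (default hourly over 24 hr).
#' @param switch_time Acidogenic-to-solventogenic shift time in hr used to
#'   shape the synthetic enzyme-activity profiles (default 8 hr).
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 42L, noise_sd = 0.05,
                           obs_times = seq(0, 24, by = 1), switch_time = 8) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  if (switch_time < 0) abort("`switch_time` must be non-negative")
  structure(list(seed = as.integer(seed), noise_sd = noise_sd,
                 obs_times = as.numeric(obs_times),
                 switch_time = switch_time),
            class = "fixture_config")
}

#' Bundled kinetic parameter values for the default ABE model
#'
#' The 50 parameter values of the bundled parameterization, in the canonical
#' three-column layout (reaction index, parameter name, value; Vmax in
#' mM/hr, Km/Ki/Ka in mM). These are order-of-magnitude plausible values for
#' a batch ABE fermentation, chosen so the network expresses the documented
#' two-phase behaviour (acids rise then fall, solvents accumulate late, an
#' early butyryl-phosphate peak at the onset of solventogenesis). They are a
#' reconstruction, not a transcription of any fitted set.
#'
#' @return Tibble with columns `reaction_index`, `parameter`, `value`.
#' @export
default_parameters <- function() {
  vals <- c(
    Vmax1 = 14, Km1 = 2, Ki1 = 600,
    k2 = 12, k3 = 25,
    Vmax4 = 4, Km4 = 2,
    Vmax5 = 45, Km5 = 1,
    Vmax6 = 3, Km6 = 2,
    Vmax7 = 8, Km7 = 30,
    Vmax8 = 8, Km8a = 30, Km8b = 0.5, Ki8 = 4,
    Vmax9 = 12, Km9 = 1,
    Vmax10 = 60, Km10 = 5, Ki10 = 80,
    Vmax11 = 2.5, Km11 = 1, Ka11 = 5,
    Vmax12 = 2, Km12 = 1,
    Vmax13 = 1.2, Km13 = 8,
    Vmax14 = 28, Km14 = 0.5, Ki14 = 90,
    Vmax15 = 6, Km15a = 15, Km15b = 0.5, Ki15 = 4,
    Vmax16 = 20, Km16 = 1,
    Vmax17 = 8, Km17 = 20, Ki17 = 250,
    Vmax18 = 22, Km18 = 1,
    Vmax19 = 26, Km19 = 1, Ka19 = 10,
    Vmax20 = 16, Km20 = 2.5,
    Vmax21 = 6.5, Km21 = 2
  )
  model <- abe_model()
  purrr::map_dfr(seq_along(model$reactions), function(j) {
    r <- model$reactions[[j]]
    pn <- reaction_parameters(r)
    tibble::tibble(reaction_index = j, parameter = pn, value = unname(vals[pn]))
  })
}

#' Bundled initial concentrations for the default batch scenario
#'
#' Glucose-rich, product-free batch start. The values are a documented
#' fixture choice (the initial conditions of the original wet-lab batch are
#' not part of the bundled data), at the concentration scale typical of a
#' laboratory ABE batch culture.
#'
#' @return Named numeric vector of initial concentrations (mM).
#' @export
default_initial_state <- function() {
  c(Glc = 300)
}

# fixed two/three-plateau activity level tables used by the synthetic
# profiles; levels differ a little per enzyme so EAC tracks are distinct
.acidogenic_levels <- list(
  PTA = c(1.00, 0.40, 0.28),
  AK  = c(1.00, 0.45, 0.30),
  PTB = c(1.00, 0.35, 0.25),
  BK  = c(1.00, 0.42, 0.32)
)
.solventogenic_levels <- list(
  CoAT = c(0.18, 1.00, 0.85),
  AAD  = c(0.12, 1.00, 0.80),
  AADC = c(0.15, 1.00, 0.90),
  BDH  = c(0.04, 1.00, 0.85)
)
.bcb_levels <- list(`B-C-B` = c(1.00, 0.75, 0.60))

#' Synthetic enzyme-activity profiles
#'
#' Emulates literature activity-assay time courses for the regulated enzyme
#' subset with a two-phase pattern: acidogenic enzymes (PTA, AK, PTB, BK) are
#' at maximal activity before the switch time and reduced after it;
#' solventogenic enzymes (CoAT, AAD, AADC, BDH) are low before the switch and
#' maximal after it; the lumped B-C-B step declines mildly. A second, smaller
#' level change at twice the switch time gives each profile three plateaus.
#' All activities are strictly positive and the profiles are deterministic
#' given the configuration.
#'
#' @param config A [fixture_config()].
#' @param horizon Last sample time in hr (default 24).
#' @param by Sampling interval in hr (default 1).
#' @return Tidy tibble with columns `enzyme`, `time_hr`, `activity`.
#' @export
make_activity_profiles <- function(config = fixture_config(), horizon = 24,
                                   by = 1) {
  stopifnot(inherits(config, "fixture_config"))
  levels <- c(.acidogenic_levels, .solventogenic_levels, .bcb_levels)
  tt <- seq(0, horizon, by = by)
  s1 <- config$switch_time
  s2 <- 2 * config$switch_time
  purrr::map_dfr(names(levels), function(enz) {
    lv <- levels[[enz]]
    phase <- ifelse(tt < s1, 1L, ifelse(tt < s2, 2L, 3L))
    tibble::tibble(enzyme = enz, time_hr = tt, activity = lv[phase])
  })
}

#' Synthetic reference observations for parameter fitting
#'
#' Integrates the model at the `truth` parameter set, samples the non-BuP
#' metabolites on the observation grid, and applies multiplicative lognormal
#' noise (`y * exp(rnorm(0, noise_sd))`). Butyryl-phosphate is omitted by
#' construction: the fitting pipeline never sees BuP information. With
#' `noise_sd = 0` the reference equals the trajectory exactly on the grid.
#'
#' @param truth Parameter table or named vector used as ground truth.
#' @param config A [fixture_config()]; supplies seed, noise level and grid.
#' @param setup An [abe_setup()] (its own parameter values are ignored in
#'   favour of `truth`).
#' @return Tibble with `time_hr` and one column per observed species (16 for
#'   the default model); the `source` attribute is `"synthetic"`.
#' @export
make_reference <- function(truth, config, setup) {
  stopifnot(inherits(config, "fixture_config"), inherits(setup, "abe_setup"))
  traj <- simulate_abe(setup, params = truth, times = config$obs_times)
  obs_sp <- setdiff(species_order(setup$model), "BuP")
  ref <- traj[, c("time_hr", obs_sp)]
  if (config$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(config$seed)
    for (sp in obs_sp)
      ref[[sp]] <- ref[[sp]] * exp(rnorm(nrow(ref), 0, config$noise_sd))
  }
  ref <- tibble::as_tibble(ref)
  class(ref) <- setdiff(class(ref), "abe_trajectory")
  attr(ref, "source") <- "synthetic"
  ref
}

#' The fully assembled default scenario
#'
#' Convenience constructor bundling the default model, the bundled parameter
#' values, the synthetic activity profiles (turned into an EAC schedule on
#' their time division) and the default initial state into one
#' [abe_setup()].
#'
#' @param horizon Simulation horizon in hr (default 24).
#' @param dt Output grid step in hr (default 0.1).
#' @param config A [fixture_config()] shaping the activity profiles.
#' @param ... Passed on to [abe_setup()] (e.g. `rtol`, `atol`).
#' @return An `abe_setup` for the bundled batch scenario.
#' @examples
#' setup <- abe_default_setup()
#' traj <- simulate_abe(setup)
#' @export
abe_default_setup <- function(horizon = 24, dt = 0.1,
                              config = fixture_config(), ...) {
  model <- abe_model()
  profiles <- make_activity_profiles(config, horizon = horizon)
  schedule <- eac_schedule(model, profiles, horizon = horizon)
  abe_setup(model, default_parameters(), default_initial_state(),
            schedule = schedule, horizon = horizon, dt = dt, ...)
}
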