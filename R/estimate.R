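#' Specify a genetic-algorithm fit
#'
#' Declares which parameters are free, their positive search bounds, and the
#' GA hyperparameters. By default the five unknowns introduced by the
#' butyryl-phosphate branch split (`Ki17`, `Vmax20`, `Km20`, `Vmax21`,
#' `Km21`) are estimated. The search operates on `log10(parameter)` so
#' positivity is structural; mutation is per-gene Gaussian on that log scale.
#'
#' @param parameters Character vector of free parameter names.
#' @param lower,upper Positive numeric bounds, recycled against `parameters`.
#'   When `NULL` (the default), plausible kinetic ranges are chosen from the
#'   parameter-name prefix: Vmax in `[0.5, 200]` mM/hr, Km in `[0.02, 20]`
#'   mM, Ki in `[5, 2000]` mM, Ka in `[0.2, 200]` mM, first-order rate
#'   constants in `[0.1, 500]` /hr.
#' @param population Population size (default 100).
#' @param generations Number of generations (default 250).
#' @param crossover Per-pair uniform-crossover probability (default 0.8).
#' @param mutation_rate Per-gene mutation probability (default 0.3).
#' @param mutation_sd Initial Gaussian mutation standard deviation on the
#'   log10 scale (default 0.1).
#' @param mutation_decay Per-generation geometric decay of the mutation SD
#'   (default so the SD ends 100-fold smaller, giving a coarse exploration
#'   phase followed by fine convergence; the SD never drops below 0.003).
#' @param immigrants Number of freshly drawn individuals injected per
#'   generation (default 5% of the population), guarding against premature
#'   convergence; elitism is unaffected.
#' @param elitism Number of best individuals copied unchanged (default 2).
#' @param seed Integer random seed; identical seed and inputs give
#'   bitwise-identical results.
#' @return An object of class `abe_fit_spec`.
#' @export
fit_spec <- function(parameters = c("Ki17", "Vmax20", "Km20", "Vmax21", "Km21"),
                     lower = NULL, upper = NULL,
                     population = 100, generations = 250, crossover = 0.8,
                     mutation_rate = 0.3, mutation_sd = 0.1,
                     mutation_decay = 0.01^(1 / generations),
                     immigrants = ceiling(0.05 * population), elitism = 2,
                     seed = 1L) {
  n <- length(parameters)
  if (!n) abort("at least one free parameter is required")
  if (is.null(lower) || is.null(upper)) {
    type <- sub("[0-9].*$", "", parameters)
    ranges <- list(Vmax = c(0.5, 200), Km = c(0.02, 20), Ki = c(5, 2000),
                   Ka = c(0.2, 200), k = c(0.1, 500))
    if (!all(type %in% names(ranges)))
      abort("cannot infer default bounds; supply `lower` and `upper`")
    if (is.null(lower)) lower <- vapply(type, function(tp) ranges[[tp]][1], 1)
    if (is.null(upper)) upper <- vapply(type, function(tp) ranges[[tp]][2], 1)
  }
  lower <- rep_len(as.numeric(lower), n)
  upper <- rep_len(as.numeric(upper), n)
  if (any(lower <= 0) || any(upper < lower))
    abort("bounds must be strictly positive with upper >= lower")
  if (population < 1 || generations < 1)
    abort("population and generations must both be at least 1")
  if (elitism >= population) abort("elitism must be smaller than the population")
  structure(list(parameters = parameters, lower = lower, upper = upper,
                 population = as.integer(population),
                 generations = as.integer(generations),
                 crossover = crossover, mutation_rate = mutation_rate,
                 mutation_sd = mutation_sd, mutation_decay = mutation_decay,
                 immigrants = as.integer(immigrants),
                 elitism = as.integer(elitism),
                 seed = as.integer(seed)),
            class = "abe_fit_spec")
}

#' @export
print.abe_fit_spec <- function(x, ...) {
  cat(sprintf("<abe_fit_spec> %d free parameter(s): %s\n",
              length(x$parameters), paste(x$parameters, collapse = ", ")))
  cat(sprintf("  GA: population %d, generations %d, crossover %.2f, mutation %.2f (sd %.2f, log10), elitism %d, seed %d\n",
              x$population, x$generations, x$crossover, x$mutation_rate,
              x$mutation_sd, x$elitism, x$seed))
  invisible(x)
}

# validate the reference layout: observation times plus the 16 non-BuP
# metabolite columns; BuP observations are excluded by construction
.check_reference <- function(reference, model) {
  reference <- tibble::as_tibble(reference)
  if (!"time_hr" %in% names(reference))
    abort("reference data need a `time_hr` column")
  if ("BuP" %in% names(reference))
    abort("reference data must not contain BuP observations")
  obs_sp <- setdiff(names(reference), "time_hr")
  unknown <- setdiff(obs_sp, model$species$id)
  if (length(unknown))
    abort(sprintf("reference columns are not model species: %s",
                  paste(unknown, collapse = ", ")))
  if (!length(obs_sp)) abort("reference data contain no metabolite columns")
  reference
}

#' Sum-of-squared-relative-residuals fitness of a candidate parameter set
#'
#' Integrates the model under the candidate parameters and scores the match
#' of the observed metabolites (the 16 non-BuP species for the default
#' reference) at the observation times:
#' `sum(((y - y0) / (y0 + delta))^2)`, where the small guard `delta` keeps
#' residuals finite when an observation is 0 and puts metabolites spanning
#' orders of magnitude in mM on a comparable scale. Zero iff the simulated
#' concentrations match the reference exactly.
#'
#' @param params Candidate parameter table or named vector (complete set).
#' @param reference Tibble with `time_hr` and one column per observed species;
#'   must not contain BuP.
#' @param setup An [abe_setup()].
#' @param delta Relative-residual guard in mM (default 1e-3).
#' @param penalty Large finite value returned if the integration fails.
#' @return Non-negative scalar fitness (smaller is better).
#' @export
fitness <- function(params, reference, setup, delta = 1e-3, penalty = 1e12) {
  stopifnot(inherits(setup, "abe_setup"))
  reference <- .check_reference(reference, setup$model)
  obs_sp <- setdiff(names(reference), "time_hr")
  .fitness_fast(as_param_vector(params), reference$time_hr,
                as.matrix(reference[, obs_sp]), obs_sp, setup, delta, penalty)
}

# hot-path fitness shared with run_ga: inputs already validated/extracted
.fitness_fast <- function(pvec, times, obs, obs_sp, setup, delta, penalty) {
  core <- tryCatch(.integrate_core(setup, pvec, times),
                   error = function(e) NULL)
  if (is.null(core) || nrow(core$mat) != nrow(obs)) return(penalty)
  sim <- core$mat[, obs_sp, drop = FALSE]
  val <- sum(((sim - obs) / (obs + delta))^2)
  if (!is.finite(val)) penalty else val
}

#' Estimate free parameters with a genetic algorithm
#'
#' Minimizes [fitness()] over the free parameters of `spec` with a real-coded
#' genetic algorithm on the log10 scale: tournament selection (size 3),
#' per-gene blend (BLX-0.5) crossover, per-gene Gaussian mutation
#' with a geometrically annealed step size, and elitism, which makes the
#' best-so-far fitness non-increasing across generations. All randomness is
#' driven by `spec$seed`.
#'
#' @param spec An [fit_spec()].
#' @param reference Reference observations (see [fitness()]); typically from
#'   [make_reference()].
#' @param setup An [abe_setup()]; its parameter set supplies the fixed values
#'   of all non-free parameters (free slots are overwritten by candidates).
#' @return An `abe_fit`: fitted parameters, best fitness, and a per-generation
#'   convergence log. Use [tidy()] and [glance()] to extract results.
#' @examples
#' \donttest{
#' setup <- abe_default_setup()
#' ref <- make_reference(default_parameters(), fixture_config(noise_sd = 0), setup)
#' fit <- run_ga(fit_spec(population = 20, generations = 10, seed = 1), ref, setup)
#' tidy(fit)
#' }
#' @export
run_ga <- function(spec, reference, setup) {
  stopifnot(inherits(spec, "abe_fit_spec"), inherits(setup, "abe_setup"))
  reference <- .check_reference(reference, setup$model)
  missing <- setdiff(spec$parameters, names(setup$params))
  if (length(missing))
    abort(sprintf("free parameter(s) not in the model: %s",
                  paste(missing, collapse = ", ")))

  lo <- log10(spec$lower); hi <- log10(spec$upper)
  ng <- length(spec$parameters)
  np <- spec$population

  obs_sp <- setdiff(names(reference), "time_hr")
  obs <- as.matrix(reference[, obs_sp])
  obs_times <- reference$time_hr
  eval_genes <- function(genes) {
    p <- setup$params
    p[spec$parameters] <- 10^genes
    .fitness_fast(p, obs_times, obs, obs_sp, setup, 1e-3, 1e12)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  pop <- matrix(runif(np * ng, rep(lo, each = np), rep(hi, each = np)),
                nrow = np, ncol = ng)
  fit <- apply(pop, 1, eval_genes)
  log <- tibble::tibble(generation = 0L, best_fitness = min(fit),
                        mean_fitness = mean(fit))

  draw_uniform <- function(n)
    matrix(runif(n * ng, rep(lo, each = n), rep(hi, each = n)),
           nrow = n, ncol = ng)

  last_best <- min(fit)
  stagnant <- 0L
  anneal_from <- 1L

  for (gen in seq_len(spec$generations)) {
    ord <- order(fit)
    new_pop <- pop[ord[seq_len(spec$elitism)], , drop = FALSE]

    tournament <- function() {
      cand <- sample.int(np, min(3L, np))
      cand[which.min(fit[cand])]
    }
    sd_gen <- max(spec$mutation_sd * spec$mutation_decay^(gen - anneal_from),
                  0.003)
    mutate_genes <- function(g) {
      hit <- runif(ng) < spec$mutation_rate
      g[hit] <- g[hit] + rnorm(sum(hit), 0, sd_gen)
      pmin(pmax(g, lo), hi)
    }
    while (nrow(new_pop) < np) {
      ia <- tournament(); ib <- tournament()
      a <- pop[ia, ]; b <- pop[ib, ]
      if (runif(1) < spec$crossover) {
        if (runif(1) < 0.5) {
          # per-gene blend (BLX-0.5): children drawn around and between the
          # parents, so the search can follow correlated valleys
          d <- abs(a - b)
          lo_c <- pmin(a, b) - 0.5 * d
          hi_c <- pmax(a, b) + 0.5 * d
          a <- runif(ng, lo_c, hi_c)
          b <- runif(ng, lo_c, hi_c)
        } else {
          # heuristic (directional) crossover: extrapolate from the fitter
          # parent along the parent difference, accelerating descent along
          # narrow curved valleys
          if (fit[ib] < fit[ia]) { tmp <- a; a <- b; b <- tmp }
          d <- a - b
          a <- a + runif(1) * d
          b <- a + runif(1) * d
        }
      }
      new_pop <- rbind(new_pop, mutate_genes(a))
      if (nrow(new_pop) < np) new_pop <- rbind(new_pop, mutate_genes(b))
    }

    n_imm <- min(spec$immigrants, np - spec$elitism)
    if (n_imm > 0)
      new_pop[np - seq_len(n_imm) + 1L, ] <- draw_uniform(n_imm)

    pop <- new_pop
    fit <- c(fit[ord[seq_len(spec$elitism)]],
             apply(pop[-seq_len(spec$elitism), , drop = FALSE], 1, eval_genes))

    # diversity restart: when the best fitness has stalled for 30
    # generations, re-draw the worst half of the population and restart the
    # mutation annealing, giving the run repeated global probes while
    # elitism preserves the incumbent
    best_now <- min(fit)
    if (best_now < last_best * 0.999) {
      last_best <- best_now
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
    }
    if (stagnant >= 30L && gen <= spec$generations - 20L && np >= 10L) {
      worst <- order(fit, decreasing = TRUE)[seq_len(np %/% 2L)]
      pop[worst, ] <- draw_uniform(length(worst))
      fit[worst] <- apply(pop[worst, , drop = FALSE], 1, eval_genes)
      anneal_from <- gen
      stagnant <- 0L
    }

    log <- dplyr::bind_rows(log, tibble::tibble(
      generation = gen, best_fitness = min(fit), mean_fitness = mean(fit)))
  }

  best <- pop[which.min(fit), ]
  fitted <- setup$params
  fitted[spec$parameters] <- 10^best
  structure(list(
    estimate = tibble::tibble(parameter = spec$parameters,
                              estimate = unname(10^best),
                              lower = spec$lower, upper = spec$upper),
    params = fitted,
    best_fitness = min(fit),
    log = log,
    spec = spec
  ), class = "abe_fit")
}

#' @export
print.abe_fit <- function(x, ...) {
  cat(sprintf("<abe_fit> %d parameter(s), best fitness %.6g after %d generations\n",
              nrow(x$estimate), x$best_fitness, x$spec$generations))
  print(x$estimate)
  invisible(x)
}

#' Tidiers for GA fits
#'
#' @param x An `abe_fit` from [run_ga()].
#' @param ... Unused.
#' @name abe_fit_tidiers
NULL

#' @describeIn abe_fit_tidiers One row per free parameter with its estimate
#'   and search bounds.
#' @export
tidy.abe_fit <- function(x, ...) x$estimate

#' @describeIn abe_fit_tidiers One-row fit summary (best fitness, GA settings).
#' @export
glance.abe_fit <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_fitness,
    n_parameters = nrow(x$estimate),
    population = x$spec$population,
    generations = x$spec$generations,
    seed = x$spec$seed
  )
}
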