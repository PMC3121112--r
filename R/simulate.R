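# length of the fixed-size parameter block shared with the compiled
# derivative (see src/abekin_rhs.c)
.ABEKIN_PARMS_LEN <- 16384L

# compile the fixed structure of a model into the flat double vector consumed
# by the compiled right-hand side, plus index maps so parameter values and
# per-interval EACs can be written in place without repacking
compile_model_template <- function(model) {
  sp <- species_order(model)
  idx <- stats::setNames(seq_along(sp), sp)
  nr <- length(model$reactions)
  ns <- length(sp)

  template <- numeric(2 + 9 * nr + ns * nr)
  template[1] <- ns
  template[2] <- nr
  par_pos <- integer(0)
  par_names <- character(0)
  for (j in seq_len(nr)) {
    r <- model$reactions[[j]]
    off <- 2 + 9 * (j - 1)
    template[off + 1] <- .kind_code[[r$kind]]
    template[off + 2] <- idx[[r$substrates[1]]]
    if (length(r$substrates) > 1L) template[off + 3] <- idx[[r$substrates[2]]]
    if (!is.null(r$effector)) template[off + 4] <- idx[[r$effector]]
    # parameter names in packing order; product inhibition keeps Ki in p4
    nm <- switch(r$kind,
      mass_action = r$params$k,
      michaelis_menten = c(r$params$Vmax, r$params$Km),
      substrate_inhibition = c(r$params$Vmax, r$params$Km, r$params$Ki),
      activation = c(r$params$Vmax, r$params$Km, r$params$Ka),
      product_inhibition = c(r$params$Vmax, r$params$Km,
                             if (length(r$params$Km) < 2L) NA_character_,
                             r$params$Ki)
    )
    pos <- off + 4 + seq_along(nm)
    keep <- !is.na(nm)
    par_pos <- c(par_pos, pos[keep])
    par_names <- c(par_names, nm[keep])
  }
  A <- stoich_matrix(model)
  template[(2 + 9 * nr + 1):length(template)] <- as.numeric(A)

  if (length(template) > .ABEKIN_PARMS_LEN)
    abort(sprintf("model too large for the compiled engine (%d > %d packed values)",
                  length(template), .ABEKIN_PARMS_LEN))
  # pad once here so packing is pure in-place assignment
  template <- c(template, numeric(.ABEKIN_PARMS_LEN - length(template)))
  list(template = template, par_pos = par_pos, par_names = par_names,
       eac_pos = 2 + 9 * (seq_len(nr) - 1) + 9)
}

# pack model structure + parameter values + per-reaction EACs into the flat
# double vector consumed by the compiled right-hand side
pack_model_parms <- function(model, pvec, eac, compiled = NULL) {
  if (is.null(compiled)) compiled <- compile_model_template(model)
  missing <- setdiff(compiled$par_names, names(pvec))
  if (length(missing))
    abort(sprintf("parameter '%s' not found in the parameter set", missing[1]))
  out <- compiled$template
  out[compiled$par_pos] <- pvec[compiled$par_names]
  out[compiled$eac_pos] <- eac
  out
}

#' Bundle everything needed to integrate the model
#'
#' A simulation setup couples a model to a parameter set, an EAC schedule,
#' initial concentrations and solver settings; it is the single object passed
#' to [simulate_abe()], the perturbation sweeps and the fitting routines.
#'
#' @param model An `abe_model`.
#' @param params Parameter table or named vector (see [as_param_vector()]).
#' @param y0 Named numeric vector of initial concentrations (mM); species not
#'   named start at 0. All values must be non-negative.
#' @param schedule An `abe_eac_schedule`, or `NULL` for unregulated dynamics
#'   (every coefficient 1).
#' @param horizon Simulation horizon `T` in hr (> 0). Default 24 hr, a typical
#'   batch culture.
#' @param dt Output grid step in hr (default 0.1).
#' @param rtol,atol Solver tolerances (relative; absolute in mM). The tight
#'   defaults resolve Rd differences of order 1e-4 well above numerical noise.
#'
#' @return An object of class `abe_setup`.
#' @export
abe_setup <- function(model, params, y0, schedule = NULL, horizon = 24,
                      dt = 0.1, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "abe_model"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    abort("`horizon` must be a single positive time in hr")
  pvec <- as_param_vector(params)
  missing <- setdiff(parameter_names(model), names(pvec))
  if (length(missing))
    abort(sprintf("parameter set is missing model parameter(s): %s",
                  paste(missing, collapse = ", ")))

  sp <- species_order(model)
  if (is.null(names(y0)) || !all(names(y0) %in% sp))
    abort("`y0` must be a named vector over model species")
  if (any(y0 < 0)) abort("initial concentrations must be non-negative")
  full_y0 <- stats::setNames(numeric(length(sp)), sp)
  full_y0[names(y0)] <- as.numeric(y0)

  if (is.null(schedule)) schedule <- constant_schedule(model, horizon)
  stopifnot(inherits(schedule, "abe_eac_schedule"))
  if (!identical(rownames(schedule$values), names(model$reactions)))
    abort("schedule and model reaction lists do not agree")
  if (max(schedule$breakpoints) < horizon - 1e-12)
    abort("the EAC schedule does not span the simulation horizon")

  structure(list(model = model, params = pvec, y0 = full_y0,
                 schedule = schedule, horizon = horizon, dt = dt,
                 rtol = rtol, atol = atol,
                 compiled = compile_model_template(model),
                 par_names = parameter_names(model)),
            class = "abe_setup")
}

#' @export
print.abe_setup <- function(x, ...) {
  cat(sprintf("<abe_setup> horizon %g hr, dt %g hr, rtol %g, atol %g\n",
              x$horizon, x$dt, x$rtol, x$atol))
  print(x$model)
  invisible(x)
}

#' Assemble the regulated derivative function
#'
#' Returns the right-hand side `dY/dt(t, Y) = A diag(EAC(t)) v(Y; P)` as a
#' plain R closure over the species order of the model. This is the reference
#' (uncompiled) evaluation path; [simulate_abe()] uses an equivalent compiled
#' implementation.
#'
#' @param model An `abe_model`.
#' @param params Parameter table or named vector.
#' @param schedule An `abe_eac_schedule`, or `NULL` for all-ones regulation.
#' @return Function `(t, y) -> named dY/dt` with `y` named over
#'   [species_order()].
#' @export
assemble_ode <- function(model, params, schedule = NULL) {
  pvec <- as_param_vector(params)
  A <- stoich_matrix(model)
  rids <- colnames(A)
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "abe_eac_schedule"))
    if (!identical(rownames(schedule$values), rids))
      abort("dimension mismatch: schedule reactions do not match the model")
  }
  force(pvec)
  function(t, y) {
    v <- rate_vector(model, y, pvec)
    e <- if (is.null(schedule)) rep(1, length(v))
         else schedule$values[, .interval_index(schedule$breakpoints, t)]
    stats::setNames(as.numeric(A %*% (e * v)), rownames(A))
  }
}

#' Integrate the model over a batch time course
#'
#' Integrates `dY/dt = A E(t) v(Y; P)` with a stiff-capable solver
#' ([deSolve::lsoda]), restarting at every EAC breakpoint because the
#' right-hand side is discontinuous in `t` there. Small negative solver
#' undershoots are clipped to 0 between segments and counted.
#'
#' @param setup An [abe_setup()].
#' @param params Optional parameter override (table or named vector); defaults
#'   to the setup's parameters. Used by the perturbation and fitting engines.
#' @param times Optional output grid (hr) within `[0, horizon]`; defaults to
#'   `seq(0, horizon, by = dt)`.
#' @param engine `"compiled"` (default, C right-hand side) or `"r"` (pure R
#'   rate evaluation; slower, used for cross-checking).
#'
#' @return An `abe_trajectory`: a tibble with `time_hr` and one mM column per
#'   species, plus solver metadata in attributes (`rtol`, `atol`,
#'   `n_clipped`).
#' @examples
#' setup <- abe_default_setup()
#' traj <- simulate_abe(setup)
#' dplyr::select(tail(traj, 3), time_hr, But, BuOH, Actn)
#' @export
simulate_abe <- function(setup, params = NULL, times = NULL,
                         engine = c("compiled", "r")) {
  stopifnot(inherits(setup, "abe_setup"))
  engine <- match.arg(engine)
  pvec <- if (is.null(params)) setup$params else {
    pv <- as_param_vector(params)
    missing <- setdiff(setup$par_names %||% parameter_names(setup$model),
                       names(pv))
    if (length(missing))
      abort(sprintf("parameter set is missing model parameter(s): %s",
                    paste(missing, collapse = ", ")))
    pv
  }
  core <- .integrate_core(setup, pvec, times, engine)
  traj <- tibble::as_tibble(as.data.frame(core$mat))
  class(traj) <- c("abe_trajectory", class(traj))
  attr(traj, "rtol") <- setup$rtol
  attr(traj, "atol") <- setup$atol
  attr(traj, "n_clipped") <- core$n_clipped
  traj
}

# integration core shared by simulate_abe and the fitting hot path: returns
# a plain numeric matrix (time_hr + species columns) plus the clip count
.integrate_core <- function(setup, pvec, times = NULL, engine = "compiled") {
  model <- setup$model
  if (is.null(times)) times <- seq(0, setup$horizon, by = setup$dt)
  times <- sort(unique(as.numeric(times)))
  if (min(times) < 0 || max(times) > setup$horizon + 1e-12)
    abort("output grid must lie within [0, horizon]")

  bp <- setup$schedule$breakpoints
  cuts <- sort(unique(c(0, bp[bp > 0 & bp < setup$horizon], setup$horizon)))
  # snap output times that are numerically at a breakpoint onto it, so the
  # per-segment bookkeeping can use exact comparisons
  for (cc in cuts) times[abs(times - cc) < 1e-9] <- cc
  times <- sort(unique(times))
  sp <- species_order(model)
  y <- unname(setup$y0[sp])

  ode_r <- if (engine == "r") assemble_ode(model, pvec, setup$schedule)

  out_rows <- list()
  n_clipped <- 0L
  for (k in seq_len(length(cuts) - 1L)) {
    a <- cuts[k]; b <- cuts[k + 1L]
    seg_times <- sort(unique(c(a, times[times >= a - 1e-12 & times <= b + 1e-12], b)))
    eac <- setup$schedule$values[, .interval_index(bp, (a + b) / 2)]
    sol <- if (engine == "compiled") {
      deSolve::lsoda(y = y, times = seg_times, func = "abekin_deriv",
                     parms = pack_model_parms(model, pvec, eac,
                                              compiled = setup$compiled),
                     dllname = "abekin", initfunc = "abekin_initmod",
                     rtol = setup$rtol, atol = setup$atol)
    } else {
      deSolve::lsoda(y = stats::setNames(y, sp), times = seg_times,
                     func = function(t, y, parms) list(unname(ode_r(t, y))),
                     parms = NULL, rtol = setup$rtol, atol = setup$atol)
    }
    if (attr(sol, "istate")[1] < 0)
      abort(sprintf("solver failed to converge; last good time %.4f hr",
                    max(sol[, 1])))
    mat <- unname(sol[, -1, drop = FALSE])
    n_clipped <- n_clipped + sum(mat < -setup$atol)
    mat[mat < 0] <- 0
    keep <- seg_times %in% times & (seg_times < b | k == length(cuts) - 1L)
    if (any(keep))
      out_rows[[k]] <- cbind(seg_times[keep], mat[keep, , drop = FALSE])
    y <- mat[nrow(mat), ]
  }

  res <- do.call(rbind, out_rows)
  colnames(res) <- c("time_hr", sp)
  list(mat = res, n_clipped = n_clipped)
}

#' @export
print.abe_trajectory <- function(x, ...) {
  cat(sprintf("<abe_trajectory> %d time points over [%g, %g] hr, %d species\n",
              nrow(x), min(x$time_hr), max(x$time_hr), ncol(x) - 1L))
  NextMethod()
}
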