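# trapezoid integral over an arbitrary grid
.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Describe a multiplicative parameter perturbation
#'
#' @param parameter Character vector of distinct parameter names.
#' @param shift Signed fractional magnitudes (e.g. `0.05` for +5%,
#'   `-0.05` for -5%); recycled against `parameter`.
#' @return A perturbation spec: tibble with columns `parameter`, `shift`.
#' @examples
#' perturbation_spec(c("Vmax14", "Vmax19", "Vmax17"), 0.05)
#' @export
perturbation_spec <- function(parameter = character(), shift = numeric()) {
  spec <- tibble::tibble(parameter = as.character(parameter),
                         shift = as.numeric(shift))
  if (anyDuplicated(spec$parameter))
    abort("parameter names must be distinct within a perturbation spec")
  if (any(spec$shift == 0))
    abort("perturbation magnitudes must be nonzero")
  if (any(spec$shift <= -1))
    abort("perturbed parameter values must remain positive (shift > -1)")
  spec
}

#' Apply a perturbation to a parameter set
#'
#' Each named parameter is multiplied by `(1 + shift)`; all others are
#' untouched. The input is not mutated.
#'
#' @param params Parameter table (tibble with `parameter`, `value`) or named
#'   numeric vector.
#' @param spec A [perturbation_spec()] (any tibble with `parameter`, `shift`).
#' @return Object of the same shape as `params` with the shifted values.
#' @examples
#' p <- default_parameters()
#' p2 <- apply_perturbation(p, perturbation_spec("Vmax17", 0.05))
#' @export
apply_perturbation <- function(params, spec) {
  spec <- perturbation_spec(spec$parameter, spec$shift)
  if (is.data.frame(params)) {
    unknown <- setdiff(spec$parameter, params$parameter)
    if (length(unknown))
      abort(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")))
    i <- match(params$parameter, spec$parameter)
    out <- params
    out$value <- params$value * ifelse(is.na(i), 1, 1 + spec$shift[i])
    out
  } else {
    pvec <- as_param_vector(params)
    unknown <- setdiff(spec$parameter, names(pvec))
    if (length(unknown))
      abort(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")))
    pvec[spec$parameter] <- pvec[spec$parameter] * (1 + spec$shift)
    pvec
  }
}

#' The Rd statistic: relative change in integrated butanol production
#'
#' `Rd = (int y_p dt - int y_c dt) / int y_c dt` over the shared time grid,
#' where `y_p` is the instantaneous butanol concentration in the perturbed
#' state and `y_c` in the control (normal) state. Integrals are discretized
#' with the trapezoid rule on the trajectory grid. With this ratio form,
#' `y_p = (1 + a) y_c` gives exactly `Rd = a`, and rescaling both
#' trajectories by a common factor leaves Rd unchanged.
#'
#' @param perturbed,control `abe_trajectory` objects on the same time grid.
#' @param species Column integrated (default `"BuOH"`, butanol).
#' @return One-row tibble with `species`, `rd`, `horizon`, `n_times`.
#' @examples
#' setup <- abe_default_setup()
#' ctrl <- simulate_abe(setup)
#' pert <- simulate_abe(setup,
#'   params = apply_perturbation(setup$params, perturbation_spec("Vmax19", 0.05)))
#' compute_rd(pert, ctrl)
#' @export
compute_rd <- function(perturbed, control, species = "BuOH") {
  if (!species %in% names(perturbed) || !species %in% names(control))
    abort(sprintf("species '%s' not present in both trajectories", species))
  if (nrow(perturbed) != nrow(control) ||
      max(abs(perturbed$time_hr - control$time_hr)) > 1e-9)
    abort("perturbed and control trajectories must share the same time grid")
  tt <- control$time_hr
  int_c <- .trapz(tt, control[[species]])
  if (int_c == 0)
    abort("control trajectory integrates to zero: Rd is undefined")
  int_p <- .trapz(tt, perturbed[[species]])
  tibble::tibble(species = species, rd = (int_p - int_c) / int_c,
                 horizon = max(tt) - min(tt), n_times = length(tt))
}

# run one perturbed integration and return its Rd against a precomputed
# control trajectory
.rd_one <- function(setup, spec, control, species) {
  pert <- simulate_abe(setup, params = apply_perturbation(setup$params, spec))
  compute_rd(pert, control, species)$rd
}

#' Single-parameter perturbation sweep
#'
#' Traverses the entire parameter set, shifting one parameter at a time by
#' `direction * magnitude` and recording the Rd statistic of each run against
#' the unperturbed control. Rows follow parameter-index order (the order of
#' [parameter_names()]), and each row equals a standalone
#' apply/integrate/[compute_rd()] run.
#'
#' @param setup An [abe_setup()].
#' @param magnitude Fractional shift magnitude (default 0.05, i.e. 5%).
#' @param direction `+1` (upward) or `-1` (downward).
#' @param species Species whose production is scored (default butanol).
#' @param parameters Optional subset of parameter names to traverse; defaults
#'   to all parameters of the model.
#' @return An `abe_sweep` tibble: `index`, `parameter`, `rd` (50 rows per
#'   direction for the default model).
#' @export
sweep_single <- function(setup, magnitude = 0.05, direction = 1,
                         species = "BuOH", parameters = NULL) {
  stopifnot(inherits(setup, "abe_setup"), direction %in% c(-1, 1))
  pnames <- parameters %||% parameter_names(setup$model)
  control <- simulate_abe(setup)
  rd <- vapply(pnames, function(pn)
    .rd_one(setup, perturbation_spec(pn, direction * magnitude),
            control, species), numeric(1))
  out <- tibble::tibble(index = seq_along(pnames), parameter = pnames,
                        rd = unname(rd))
  class(out) <- c("abe_sweep", class(out))
  attr(out, "order") <- 1L
  attr(out, "magnitude") <- direction * magnitude
  out
}

#' Double-parameter perturbation sweep
#'
#' Traverses all unordered parameter pairs `{i, j}`, `i < j`, for one sign
#' pattern: the first parameter of each pair is shifted by `magnitudes[1]`,
#' the second by `magnitudes[2]`. For `n` parameters this yields
#' `choose(n, 2)` rows (1225 for the default model's 50 parameters).
#'
#' @param setup An [abe_setup()].
#' @param magnitudes Length-2 signed fractional shifts, e.g. `c(0.05, -0.05)`.
#' @param species Species whose production is scored (default butanol).
#' @param parameters Optional subset of parameter names.
#' @return An `abe_sweep` tibble: `index_pair`, `parameter_1`, `parameter_2`,
#'   `rd`.
#' @export
sweep_double <- function(setup, magnitudes = c(0.05, 0.05),
                         species = "BuOH", parameters = NULL) {
  stopifnot(inherits(setup, "abe_setup"), length(magnitudes) == 2)
  pnames <- parameters %||% parameter_names(setup$model)
  if (length(pnames) < 2L) abort("need at least two parameters to sweep pairs")
  control <- simulate_abe(setup)
  pairs <- utils::combn(seq_along(pnames), 2)
  rd <- vapply(seq_len(ncol(pairs)), function(k) {
    ij <- pairs[, k]
    .rd_one(setup, perturbation_spec(pnames[ij], magnitudes), control, species)
  }, numeric(1))
  out <- tibble::tibble(
    index_pair = paste0("(", pairs[1, ], ",", pairs[2, ], ")"),
    parameter_1 = pnames[pairs[1, ]],
    parameter_2 = pnames[pairs[2, ]],
    rd = rd
  )
  class(out) <- c("abe_sweep", class(out))
  attr(out, "order") <- 2L
  attr(out, "magnitude") <- magnitudes
  out
}

#' Run a custom list of perturbation specs
#'
#' Evaluates one Rd per spec, in input order. A failing spec (e.g. an unknown
#' parameter name) is reported in its row's `error` column and the campaign
#' continues.
#'
#' @param setup An [abe_setup()].
#' @param specs List of [perturbation_spec()] tibbles.
#' @param species Species whose production is scored (default butanol).
#' @return Tibble with `spec_id`, `parameters`, `shifts`, `rd`, `error`.
#' @examples
#' setup <- abe_default_setup()
#' sweep_custom(setup, list(
#'   perturbation_spec(c("Vmax14", "Vmax19", "Vmax17"), 0.05)))
#' @export
sweep_custom <- function(setup, specs, species = "BuOH") {
  stopifnot(inherits(setup, "abe_setup"), is.list(specs))
  if (!length(specs))
    return(tibble::tibble(spec_id = integer(), parameters = character(),
                          shifts = character(), rd = numeric(),
                          error = character()))
  control <- simulate_abe(setup)
  purrr::map_dfr(seq_along(specs), function(i) {
    spec <- specs[[i]]
    res <- tryCatch(
      list(rd = .rd_one(setup, spec, control, species), error = NA_character_),
      error = function(e) list(rd = NA_real_, error = conditionMessage(e))
    )
    tibble::tibble(
      spec_id = i,
      parameters = paste(spec$parameter, collapse = ","),
      shifts = paste(sprintf("%+g", spec$shift), collapse = ","),
      rd = res$rd, error = res$error
    )
  })
}
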