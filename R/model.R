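#' Rate-law kinds understood by the model engine
#'
#' The rate-law catalogue covers the functional forms used by the ABE network:
#' first-order mass action, irreversible Michaelis-Menten with one or two
#' substrates, Michaelis-Menten with substrate inhibition, with noncompetitive
#' product inhibition, and with an essential activator.
#'
#' @return Character vector of kind identifiers.
#' @export
rate_law_kinds <- function() {
  c("mass_action", "michaelis_menten", "substrate_inhibition",
    "product_inhibition", "activation")
}

# integer codes used by the compiled derivative
.kind_code <- c(
  mass_action = 1L, michaelis_menten = 2L, substrate_inhibition = 3L,
  product_inhibition = 4L, activation = 5L
)

#' Declare a single reaction
#'
#' A reaction couples a signed stoichiometry map to a rate law. Parameter
#' slots hold the *names* of entries in a parameter table, so the same model
#' can be evaluated under any parameter assignment.
#'
#' @param id Reaction identifier, e.g. `"R14"`.
#' @param enzyme Enzyme abbreviation (e.g. `"BDH"`, `"PTB"`, `"B-C-B"`).
#' @param stoich Named numeric vector of signed integer stoichiometric
#'   coefficients (negative = consumed).
#' @param kind One of [rate_law_kinds()].
#' @param substrates Character vector of substrate species ids driving the
#'   rate law (one species, or two for a bi-substrate Michaelis-Menten form).
#' @param params Named list binding parameter slots to parameter names:
#'   `k` for mass action; `Vmax` plus `Km` (one name per substrate) for the
#'   Michaelis-Menten forms; additionally `Ki` (substrate/product inhibition)
#'   or `Ka` (activation).
#' @param effector Species id of the inhibiting product or essential
#'   activator, for the kinds that use one.
#' @param regulated Logical; whether a non-constant enzyme activity
#'   coefficient applies to this reaction.
#'
#' @return An object of class `abe_reaction`.
#' @export
abe_reaction <- function(id, enzyme, stoich, kind, substrates, params,
                         effector = NULL, regulated = FALSE) {
  kind <- match.arg(kind, rate_law_kinds())
  if (!is.numeric(stoich) || is.null(names(stoich)) || any(names(stoich) == ""))
    abort(sprintf("reaction %s: `stoich` must be a named numeric vector", id))
  if (any(stoich == 0))
    abort(sprintf("reaction %s: zero stoichiometric coefficients are not allowed", id))
  if (any(stoich != round(stoich)))
    abort(sprintf("reaction %s: stoichiometric coefficients must be integers", id))

  n_sub <- length(substrates)
  need <- switch(kind,
    mass_action = if (n_sub != 1L) "exactly one substrate",
    michaelis_menten = ,
    product_inhibition = if (n_sub < 1L || n_sub > 2L) "one or two substrates",
    substrate_inhibition = ,
    activation = if (n_sub != 1L) "exactly one substrate"
  )
  if (!is.null(need))
    abort(sprintf("reaction %s: rate law '%s' needs %s", id, kind, need))

  slots <- switch(kind,
    mass_action = "k",
    michaelis_menten = c("Vmax", "Km"),
    substrate_inhibition = c("Vmax", "Km", "Ki"),
    product_inhibition = c("Vmax", "Km", "Ki"),
    activation = c("Vmax", "Km", "Ka")
  )
  missing <- setdiff(slots, names(params))
  if (length(missing))
    abort(sprintf("reaction %s: missing parameter slot(s): %s",
                  id, paste(missing, collapse = ", ")))
  if (kind %in% c("michaelis_menten", "product_inhibition") &&
      length(params$Km) != n_sub)
    abort(sprintf("reaction %s: need one Km name per substrate", id))
  if (kind %in% c("product_inhibition", "activation") && is.null(effector))
    abort(sprintf("reaction %s: rate law '%s' needs an `effector` species",
                  id, kind))

  structure(
    list(id = id, enzyme = enzyme, stoich = stoich, kind = kind,
         substrates = substrates, effector = effector,
         params = params[slots], regulated = isTRUE(regulated)),
    class = "abe_reaction"
  )
}

#' @export
print.abe_reaction <- function(x, ...) {
  lhs <- x$stoich[x$stoich < 0]
  rhs <- x$stoich[x$stoich > 0]
  side <- function(s, sign) paste(
    ifelse(abs(s) == 1, names(s), paste0(abs(s), " ", names(s))),
    collapse = " + ")
  cat(sprintf("<%s> [%s, %s]  %s -> %s\n", x$id, x$enzyme, x$kind,
              side(lhs), side(rhs)))
  invisible(x)
}

#' Parameter slot names of a reaction, in canonical order
#' @param reaction An [abe_reaction()].
#' @return Character vector of parameter names.
#' @export
reaction_parameters <- function(reaction) {
  unname(unlist(reaction$params))
}

#' Construct a model from species and reactions
#'
#' Low-level constructor; most users will call [abe_model()] for the bundled
#' ABE network. Validates that species ids are unique, that every species
#' referenced by a reaction exists, and that every parameter slot name is
#' bound by exactly one reaction.
#'
#' @param species Tibble with columns `id`, `name`, `role` (one of
#'   `"external-substrate"`, `"intermediate"`, `"end-product"`).
#' @param reactions List of [abe_reaction()] objects.
#' @param note Free-text provenance note stored with the model.
#'
#' @return An object of class `abe_model`.
#' @export
new_abe_model <- function(species, reactions, note = NULL) {
  species <- tibble::as_tibble(species)
  stopifnot(all(c("id", "name", "role") %in% names(species)))
  if (anyDuplicated(species$id))
    abort("species ids must be unique within a model")
  bad_role <- setdiff(unique(species$role),
                      c("external-substrate", "intermediate", "end-product"))
  if (length(bad_role))
    abort(sprintf("unknown species role(s): %s", paste(bad_role, collapse = ", ")))

  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids)) abort("reaction ids must be unique within a model")

  for (r in reactions) {
    refs <- unique(c(names(r$stoich), r$substrates, r$effector))
    unknown <- setdiff(refs, species$id)
    if (length(unknown))
      abort(sprintf("reaction %s references unknown species: %s",
                    r$id, paste(unknown, collapse = ", ")))
  }

  pnames <- unlist(lapply(reactions, reaction_parameters))
  if (anyDuplicated(pnames))
    abort(sprintf("parameter name(s) bound by more than one slot: %s",
                  paste(unique(pnames[duplicated(pnames)]), collapse = ", ")))

  structure(list(species = species, reactions = stats::setNames(reactions, ids),
                 note = note),
            class = "abe_model")
}

#' The bundled ABE pathway model of *C. acetobutylicum*
#'
#' Builds the acetone-butanol-ethanol reaction network: glucose uptake by the
#' phosphotransferase system (R1), lumped glycolysis (R2-R3), the lactate
#' shunt (R4, R13), pyruvate cleavage to acetyl-CoA (R5), a biomass drain
#' (R6), the acetate branch (R9 production by PTA-AK, R7 reassimilation, R8
#' CoA-transferase), ethanol formation (R11, AAD), the thiolase couple
#' (R10/R12), the lumped BHBD-CRO-BCD step to butyryl-CoA (R14), the
#' CoA-transferase butyrate side (R15), acetone formation (R16, AADC), the
#' butyrate branch routed through butyryl-phosphate (R17/R20 catalysed by BK,
#' R18/R21 by PTB), and butanol formation (R19, BDH).
#'
#' With `bup = TRUE` (the default) the model has 17 species, 21 reactions and
#' 50 kinetic parameters. With `bup = FALSE` the predecessor layout is
#' returned, in which the butyrate branch is lumped into a direct But <-> BCoA
#' conversion pair (16 species, 19 reactions, 45 parameters); passing it to
#' [split_lumped_butyrate_branch()] reproduces the default model.
#'
#' The species list, stoichiometries and algebraic rate-law forms are a
#' documented reconstruction: the figure-level wiring (which enzyme catalyses
#' which arrow, which reactions are acidogenic/solventogenic) is authoritative,
#' while the exact inhibition/activation assignments follow the conventions of
#' batch ABE kinetic models (butanol product toxicity on biosynthetic steps,
#' acid-induced activation of the solventogenic alcohol dehydrogenases). Note
#' that the AADC step (R16) is taken to produce acetone (not acetate).
#'
#' @param bup Include butyryl-phosphate and the split butyrate branch?
#'
#' @return An `abe_model`.
#' @examples
#' m <- abe_model()
#' glance(m)
#' @export
abe_model <- function(bup = TRUE) {
  sp <- tibble::tibble(
    id = c("Glc", "F6P", "G3P", "Pyr", "Lac", "ACoA", "AACoA", "AcAc", "Ace",
           "EtOH", "Actn", "BCoA", "But", "BuOH", "CO2", "X"),
    name = c("glucose", "fructose-6-phosphate", "glyceraldehyde-3-phosphate",
             "pyruvate", "lactate", "acetyl-CoA", "acetoacetyl-CoA",
             "acetoacetate", "acetate", "ethanol", "acetone", "butyryl-CoA",
             "butyrate", "butanol", "carbon dioxide", "biomass"),
    role = c("external-substrate", rep("intermediate", 8),
             "end-product", "end-product", "intermediate", "intermediate",
             "end-product", "end-product", "end-product")
  )
  if (bup) {
    sp <- dplyr::bind_rows(
      sp, tibble::tibble(id = "BuP", name = "butyryl-phosphate",
                         role = "intermediate"))
  }

  mm <- function(id, enzyme, stoich, sub, vmax, km, regulated = FALSE)
    abe_reaction(id, enzyme, stoich, "michaelis_menten", sub,
                 params = list(Vmax = vmax, Km = km), regulated = regulated)

  rx <- list(
    abe_reaction("R1", "PTS", c(Glc = -1, F6P = 1), "substrate_inhibition",
                 "Glc", list(Vmax = "Vmax1", Km = "Km1", Ki = "Ki1")),
    abe_reaction("R2", "GLY1", c(F6P = -1, G3P = 2), "mass_action", "F6P",
                 list(k = "k2")),
    abe_reaction("R3", "GLY2", c(G3P = -1, Pyr = 1), "mass_action", "G3P",
                 list(k = "k3")),
    mm("R4", "LDH", c(Pyr = -1, Lac = 1), "Pyr", "Vmax4", "Km4"),
    mm("R5", "PFOR", c(Pyr = -1, ACoA = 1, CO2 = 1), "Pyr", "Vmax5", "Km5"),
    mm("R6", "BIO", c(ACoA = -1, X = 1), "ACoA", "Vmax6", "Km6"),
    mm("R7", "AK", c(Ace = -1, ACoA = 1), "Ace", "Vmax7", "Km7",
       regulated = TRUE),
    abe_reaction("R8", "CoAT", c(Ace = -1, AACoA = -1, AcAc = 1, ACoA = 1),
                 "product_inhibition", c("Ace", "AACoA"),
                 list(Vmax = "Vmax8", Km = c("Km8a", "Km8b"), Ki = "Ki8"),
                 effector = "AcAc", regulated = TRUE),
    mm("R9", "PTA", c(ACoA = -1, Ace = 1), "ACoA", "Vmax9", "Km9",
       regulated = TRUE),
    abe_reaction("R10", "THL", c(ACoA = -2, AACoA = 1), "product_inhibition",
                 "ACoA", list(Vmax = "Vmax10", Km = "Km10", Ki = "Ki10"),
                 effector = "BuOH"),
    abe_reaction("R11", "AAD", c(ACoA = -1, EtOH = 1), "activation",
                 "ACoA", list(Vmax = "Vmax11", Km = "Km11", Ka = "Ka11"),
                 effector = "But", regulated = TRUE),
    mm("R12", "THL", c(AACoA = -1, ACoA = 2), "AACoA", "Vmax12", "Km12"),
    mm("R13", "LDH", c(Lac = -1, Pyr = 1), "Lac", "Vmax13", "Km13"),
    abe_reaction("R14", "B-C-B", c(AACoA = -1, BCoA = 1), "product_inhibition",
                 "AACoA", list(Vmax = "Vmax14", Km = "Km14", Ki = "Ki14"),
                 effector = "BuOH", regulated = TRUE),
    abe_reaction("R15", "CoAT", c(But = -1, AACoA = -1, AcAc = 1, BCoA = 1),
                 "product_inhibition", c("But", "AACoA"),
                 list(Vmax = "Vmax15", Km = c("Km15a", "Km15b"), Ki = "Ki15"),
                 effector = "AcAc", regulated = TRUE),
    mm("R16", "AADC", c(AcAc = -1, Actn = 1, CO2 = 1), "AcAc",
       "Vmax16", "Km16", regulated = TRUE)
  )

  if (bup) {
    rx <- c(rx, list(
      abe_reaction("R17", "BK", c(But = -1, BuP = 1), "substrate_inhibition",
                   "But", list(Vmax = "Vmax17", Km = "Km17", Ki = "Ki17"),
                   regulated = TRUE),
      mm("R18", "PTB", c(BCoA = -1, BuP = 1), "BCoA", "Vmax18", "Km18",
         regulated = TRUE),
      abe_reaction("R19", "BDH", c(BCoA = -1, BuOH = 1), "activation",
                   "BCoA", list(Vmax = "Vmax19", Km = "Km19", Ka = "Ka19"),
                   effector = "But", regulated = TRUE),
      mm("R20", "BK", c(BuP = -1, But = 1), "BuP", "Vmax20", "Km20",
         regulated = TRUE),
      mm("R21", "PTB", c(BuP = -1, BCoA = 1), "BuP", "Vmax21", "Km21",
         regulated = TRUE)
    ))
    note <- paste(
      "Default ABE network with butyryl-phosphate: 17 species, 21 reactions,",
      "50 kinetic parameters. Reconstructed topology; R16 (AADC) produces",
      "acetone. Butyrate branch: BCoA -R18(PTB)-> BuP -R20(BK)-> But and",
      "But -R17(BK)-> BuP -R21(PTB)-> BCoA.")
  } else {
    rx <- c(rx, list(
      mm("R17", "PTB-BK", c(But = -1, BCoA = 1), "But", "Vmax17", "Km17",
         regulated = TRUE),
      mm("R18", "PTB-BK", c(BCoA = -1, But = 1), "BCoA", "Vmax18", "Km18",
         regulated = TRUE),
      abe_reaction("R19", "BDH", c(BCoA = -1, BuOH = 1), "activation",
                   "BCoA", list(Vmax = "Vmax19", Km = "Km19", Ka = "Ka19"),
                   effector = "But", regulated = TRUE)
    ))
    note <- paste(
      "Predecessor ABE network without butyryl-phosphate: 16 species,",
      "19 reactions, 45 kinetic parameters; the butyrate branch is the",
      "lumped conversion pair R17 (But -> BCoA) / R18 (BCoA -> But).")
  }

  new_abe_model(sp, rx, note = note)
}

#' Split the lumped butyrate branch through butyryl-phosphate
#'
#' Replaces the lumped conversion pair between butyrate (But) and butyryl-CoA
#' (BCoA) by the explicit chain `BCoA <-> BuP <-> But`: R18 (PTB,
#' `BCoA -> BuP`), R20 (BK, `BuP -> But`), R17 (BK, `But -> BuP`, with
#' substrate inhibition) and R21 (PTB, `BuP -> BCoA`). The species count grows
#' by one (BuP) and five new parameter slots appear — `Ki17`, `Vmax20`,
#' `Km20`, `Vmax21`, `Km21` — the unknowns later estimated by [run_ga()]. The
#' lumped Vmax/Km constants are re-bound to the BK/PTB half-reactions they
#' were measured on; all other reactions are untouched.
#'
#' @param model An `abe_model` containing a lumped But <-> BCoA pair.
#'
#' @return An `abe_model` with the split branch. The names of the newly
#'   introduced parameters are in `attr(, "new_parameters")`.
#' @examples
#' pre <- abe_model(bup = FALSE)
#' post <- split_lumped_butyrate_branch(pre)
#' setdiff(parameter_names(post), parameter_names(pre))
#' @export
split_lumped_butyrate_branch <- function(model) {
  stopifnot(inherits(model, "abe_model"))
  is_lumped <- function(r, from, to) {
    s <- r$stoich
    length(s) == 2L && identical(sort(names(s)), sort(c(from, to))) &&
      s[[from]] == -1 && s[[to]] == 1
  }
  fwd <- Filter(function(r) is_lumped(r, "BCoA", "But"), model$reactions)
  rev <- Filter(function(r) is_lumped(r, "But", "BCoA"), model$reactions)
  if (length(fwd) != 1L || length(rev) != 1L)
    abort(paste("no lumped butyrate conversion pair (But <-> BCoA) present;",
                "the branch may already be split through BuP"))
  fwd <- fwd[[1]]; rev <- rev[[1]]

  if ("BuP" %in% model$species$id)
    abort("model already contains BuP")

  species <- dplyr::bind_rows(
    model$species,
    tibble::tibble(id = "BuP", name = "butyryl-phosphate",
                   role = "intermediate"))

  keep <- Filter(function(r) !r$id %in% c(fwd$id, rev$id), model$reactions)
  new_rx <- list(
    abe_reaction(rev$id, "BK", c(But = -1, BuP = 1), "substrate_inhibition",
                 "But", list(Vmax = rev$params$Vmax, Km = rev$params$Km,
                             Ki = "Ki17"),
                 regulated = rev$regulated),
    abe_reaction(fwd$id, "PTB", c(BCoA = -1, BuP = 1), "michaelis_menten",
                 "BCoA", list(Vmax = fwd$params$Vmax, Km = fwd$params$Km),
                 regulated = fwd$regulated),
    abe_reaction("R20", "BK", c(BuP = -1, But = 1), "michaelis_menten",
                 "BuP", list(Vmax = "Vmax20", Km = "Km20"),
                 regulated = TRUE),
    abe_reaction("R21", "PTB", c(BuP = -1, BCoA = 1), "michaelis_menten",
                 "BuP", list(Vmax = "Vmax21", Km = "Km21"),
                 regulated = TRUE)
  )

  # keep R1..R19 ordering, then append the two new reactions
  rx <- c(keep, new_rx)
  ord <- order(as.integer(sub("^R", "", vapply(rx, `[[`, "", "id"))))
  out <- new_abe_model(species, rx[ord],
                       note = paste(model$note, "| butyrate branch split",
                                    "through BuP (R17/R20 BK, R18/R21 PTB)"))
  attr(out, "new_parameters") <- c("Ki17", "Vmax20", "Km20", "Vmax21", "Km21")
  out
}

#' All parameter names bound by a model
#'
#' @param model An `abe_model`.
#' @return Character vector of parameter names, in reaction order and, within
#'   a reaction, canonical slot order (Vmax, Km..., Ki/Ka).
#' @export
parameter_names <- function(model) {
  unname(unlist(lapply(model$reactions, reaction_parameters)))
}

#' Fixed species (row) order of the stoichiometric matrix
#' @param model An `abe_model`.
#' @return Species ids sorted in locale-independent (C radix) order.
#' @export
species_order <- function(model) {
  sort(model$species$id, method = "radix")
}

#' Build the stoichiometric matrix A
#'
#' Assembles the species-by-reactions matrix of signed stoichiometric
#' coefficients, so that the mass balances read `dY/dt = A (E v)`. Rows follow
#' [species_order()] (recorded in the model file), columns follow reaction
#' order.
#'
#' @param model An `abe_model`.
#' @return Integer matrix with species ids as row names and reaction ids as
#'   column names (17 x 21 for the default model).
#' @examples
#' dim(stoich_matrix(abe_model()))
#' @export
stoich_matrix <- function(model) {
  stopifnot(inherits(model, "abe_model"))
  rows <- species_order(model)
  cols <- names(model$reactions)
  A <- matrix(0L, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoich), rows)
    if (length(unknown))
      abort(sprintf("reaction %s references species absent from the species list: %s",
                    r$id, paste(unknown, collapse = ", ")))
    A[names(r$stoich), r$id] <- as.integer(r$stoich)
  }
  A
}

#' Resolve a parameter table or named vector to a named numeric vector
#'
#' @param params Either a named numeric vector or a parameter table with
#'   columns `parameter` and `value` (the three-column on-disk layout of
#'   [read_parameter_table()] is accepted).
#' @return Named numeric vector of strictly positive parameter values.
#' @export
as_param_vector <- function(params) {
  if (is.data.frame(params)) {
    stopifnot(all(c("parameter", "value") %in% names(params)))
    p <- stats::setNames(as.numeric(params$value), params$parameter)
  } else if (is.numeric(params) && !is.null(names(params))) {
    p <- params
  } else {
    abort("`params` must be a named numeric vector or a parameter table")
  }
  if (anyDuplicated(names(p)))
    abort(sprintf("duplicate parameter name(s): %s",
                  paste(unique(names(p)[duplicated(names(p))]), collapse = ", ")))
  if (any(!is.finite(p)) || any(p <= 0))
    abort("all kinetic parameters must be finite and strictly positive")
  p
}

# resolve one slot, with a helpful error naming the slot
.resolve <- function(pvec, name, reaction_id, slot) {
  if (!name %in% names(pvec))
    abort(sprintf("parameter '%s' (slot %s of reaction %s) not found in the parameter set",
                  name, slot, reaction_id))
  pvec[[name]]
}

#' Evaluate the unregulated rate law of one reaction
#'
#' Computes `v(Y; P)` for a single reaction; the enzyme activity coefficient
#' is *not* applied here (it multiplies the rate inside the ODE assembly).
#'
#' @param reaction An [abe_reaction()].
#' @param y Named numeric vector of species concentrations (mM), non-negative.
#' @param params Parameter table or named vector (see [as_param_vector()]).
#'
#' @return A single non-negative rate in mM/hr.
#' @examples
#' r <- abe_model()$reactions$R19
#' evaluate_rate(r, c(BCoA = 1, But = 4), default_parameters())
#' @export
evaluate_rate <- function(reaction, y, params) {
  stopifnot(inherits(reaction, "abe_reaction"))
  pvec <- as_param_vector(params)
  conc <- function(id) {
    v <- if (id %in% names(y)) as.numeric(y[[id]]) else 0
    max(v, 0)
  }
  S <- vapply(reaction$substrates, conc, numeric(1))
  get <- function(nm, slot) .resolve(pvec, nm, reaction$id, slot)

  switch(reaction$kind,
    mass_action = get(reaction$params$k, "k") * S[[1]],
    michaelis_menten = {
      v <- get(reaction$params$Vmax, "Vmax")
      for (i in seq_along(S))
        v <- v * S[[i]] / (get(reaction$params$Km[[i]], "Km") + S[[i]])
      v
    },
    substrate_inhibition = {
      Vmax <- get(reaction$params$Vmax, "Vmax")
      Km <- get(reaction$params$Km, "Km")
      Ki <- get(reaction$params$Ki, "Ki")
      Vmax * S[[1]] / (Km + S[[1]] + S[[1]]^2 / Ki)
    },
    product_inhibition = {
      v <- get(reaction$params$Vmax, "Vmax")
      for (i in seq_along(S))
        v <- v * S[[i]] / (get(reaction$params$Km[[i]], "Km") + S[[i]])
      v / (1 + conc(reaction$effector) / get(reaction$params$Ki, "Ki"))
    },
    activation = {
      Vmax <- get(reaction$params$Vmax, "Vmax")
      Km <- get(reaction$params$Km, "Km")
      Ka <- get(reaction$params$Ka, "Ka")
      A <- conc(reaction$effector)
      Vmax * S[[1]] / (Km + S[[1]]) * A / (Ka + A)
    }
  )
}

#' Evaluate the full unregulated rate vector v(Y; P)
#'
#' @param model An `abe_model`.
#' @inheritParams evaluate_rate
#' @return Named numeric vector, one rate (mM/hr) per reaction.
#' @export
rate_vector <- function(model, y, params) {
  vapply(model$reactions, evaluate_rate, numeric(1), y = y, params = params)
}

#' @export
print.abe_model <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<abe_model> %d species, %d reactions, %d parameters (%d regulated reactions)\n",
              g$n_species, g$n_reactions, g$n_parameters,
              sum(vapply(x$reactions, `[[`, logical(1), "regulated"))))
  if (!is.null(x$note)) cat(strwrap(x$note, indent = 2, exdent = 2), sep = "\n")
  invisible(x)
}

#' @describeIn abe_model_tidiers One row per reaction with enzyme, rate-law
#'   kind, substrates, products and bound parameter names.
#' @export
tidy.abe_model <- function(x, ...) {
  purrr::map_dfr(x$reactions, function(r) {
    tibble::tibble(
      reaction = r$id,
      enzyme = r$enzyme,
      kind = r$kind,
      substrates = paste(names(r$stoich)[r$stoich < 0], collapse = "+"),
      products = paste(names(r$stoich)[r$stoich > 0], collapse = "+"),
      regulated = r$regulated,
      parameters = paste(reaction_parameters(r), collapse = ",")
    )
  })
}

#' Tidiers for ABE models
#'
#' @param x An `abe_model`.
#' @param ... Unused.
#' @name abe_model_tidiers
NULL

#' @describeIn abe_model_tidiers One-row summary with species, reaction and
#'   parameter counts.
#' @export
glance.abe_model <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$species),
    n_reactions = length(x$reactions),
    n_parameters = length(parameter_names(x))
  )
}
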