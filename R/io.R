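#' Read a kinetic parameter table
#'
#' Parses the canonical three-column CSV layout: reaction index, parameter
#' name, value (Vmax in mM/hr; Km/Ki/Ka in mM).
#'
#' @param path Path to a CSV file with columns `reaction_index`, `parameter`,
#'   `value`.
#' @return Tibble with the three columns, validated: no duplicate parameter
#'   names, all values strictly positive.
#' @export
read_parameter_table <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    reaction_index = readr::col_integer(),
    parameter = readr::col_character(),
    value = readr::col_double()
  ))
  if (!nrow(tbl)) abort(sprintf("parameter table '%s' is empty", path))
  bad <- which(!is.finite(tbl$value) | tbl$value <= 0)
  if (length(bad))
    abort(sprintf("non-positive or missing parameter value at row %d ('%s')",
                  bad[1], tbl$parameter[bad[1]]))
  dup <- tbl$parameter[duplicated(tbl$parameter)]
  if (length(dup))
    abort(sprintf("duplicate parameter name(s): %s",
                  paste(unique(dup), collapse = ", ")))
  tbl
}

#' Write a kinetic parameter table
#' @param params Tibble with `reaction_index`, `parameter`, `value`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(params, path) {
  stopifnot(all(c("reaction_index", "parameter", "value") %in% names(params)))
  readr::write_csv(params, path)
  invisible(path)
}

#' Read tidy enzyme-activity profiles
#' @param path CSV with columns `enzyme`, `time_hr`, `activity`.
#' @return Validated tibble of activity samples.
#' @export
read_activity_profiles <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    enzyme = readr::col_character(),
    time_hr = readr::col_double(),
    activity = readr::col_double()
  ))
  .check_profiles(tbl)
}

#' Write tidy enzyme-activity profiles
#' @param profiles Tibble with `enzyme`, `time_hr`, `activity`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_profiles <- function(profiles, path) {
  readr::write_csv(.check_profiles(profiles), path)
  invisible(path)
}

#' Write an EAC schedule in the audit layout
#' @param schedule An `abe_eac_schedule`.
#' @param path Output CSV path (columns reaction, interval_start,
#'   interval_end, eac).
#' @return `path`, invisibly.
#' @export
write_eac_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "abe_eac_schedule"))
  readr::write_csv(tidy(schedule), path)
  invisible(path)
}

#' Write / read a simulated trajectory
#'
#' CSV layout: `time_hr` plus one concentration column (mM) per species.
#'
#' @param trajectory An `abe_trajectory` (or compatible tibble).
#' @param path CSV path.
#' @return `path` (write) or a tibble (read), invisibly for write.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot("time_hr" %in% names(trajectory))
  readr::write_csv(trajectory, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  if (!"time_hr" %in% names(tbl)) abort("trajectory file needs a time_hr column")
  class(tbl) <- c("abe_trajectory", class(tbl))
  tbl
}

#' Write a perturbation-sweep result table
#'
#' Single-parameter sweeps are written with three columns (index, parameter,
#' Rd), double-parameter sweeps with four (index_pair, parameter_1,
#' parameter_2, Rd); Rd is printed with six decimal places.
#'
#' @param results An `abe_sweep` from [sweep_single()] or [sweep_double()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(results, path) {
  ord <- attr(results, "order")
  single_cols <- c("index", "parameter", "rd")
  double_cols <- c("index_pair", "parameter_1", "parameter_2", "rd")
  if (is.null(ord))
    ord <- if (all(single_cols %in% names(results))) 1L
           else if (all(double_cols %in% names(results))) 2L
           else abort("`results` is not a recognisable sweep table")
  cols <- if (ord == 1L) single_cols else double_cols
  if (!all(cols %in% names(results)))
    abort("mixed or incomplete sweep results: column layout does not match the sweep order")
  out <- results[, cols]
  names(out)[names(out) == "rd"] <- "Rd"
  out$Rd <- sprintf("%.6f", out$Rd)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read back a sweep table written by [write_sweep_table()]
#' @param path CSV path.
#' @return Tibble with an `rd` column (numeric).
#' @export
read_sweep_table <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols())
  if (!"Rd" %in% names(tbl)) abort("sweep table needs an Rd column")
  names(tbl)[names(tbl) == "Rd"] <- "rd"
  tbl$rd <- as.numeric(tbl$rd)
  tbl
}

#' Write / read reference observations
#'
#' CSV layout: `time_hr` plus one mM column per observed metabolite (no BuP).
#'
#' @param reference Reference tibble (see [make_reference()]).
#' @param path CSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_reference <- function(reference, path) {
  stopifnot("time_hr" %in% names(reference))
  if ("BuP" %in% names(reference)) abort("reference data must not contain BuP")
  readr::write_csv(reference, path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  if (!"time_hr" %in% names(tbl)) abort("reference file needs a time_hr column")
  if ("BuP" %in% names(tbl)) abort("reference data must not contain BuP")
  tbl
}

# ---- declarative model file (YAML) ------------------------------------------

# model -> plain nested list, stable field order
.model_to_list <- function(model) {
  list(
    note = model$note %||% "",
    species = purrr::pmap(model$species, function(id, name, role)
      list(id = id, name = name, role = role)),
    reactions = purrr::map(unname(model$reactions), function(r) {
      out <- list(
        id = r$id, enzyme = r$enzyme,
        stoich = as.list(r$stoich),
        kind = r$kind,
        substrates = as.list(r$substrates),
        params = purrr::map(r$params, function(p) as.list(p)),
        regulated = r$regulated
      )
      if (!is.null(r$effector)) out$effector <- r$effector
      out
    })
  )
}

#' Write a model to a declarative YAML file
#'
#' The file records the species list (in model order), every reaction's
#' stoichiometry, rate-law kind, substrate/effector references and parameter
#' slot bindings, and the provenance note. Reading the file back with
#' [read_model_yaml()] reproduces the model exactly, so read -> write -> read
#' round-trips bit-exactly.
#'
#' @param model An `abe_model`.
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_model_yaml <- function(model, path) {
  stopifnot(inherits(model, "abe_model"))
  yaml::write_yaml(.model_to_list(model), path)
  invisible(path)
}

#' Read a model from a declarative YAML file
#' @param path Path to a file written by [write_model_yaml()].
#' @return An `abe_model`.
#' @export
read_model_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  species <- purrr::map_dfr(x$species, tibble::as_tibble)
  reactions <- purrr::map(x$reactions, function(r) {
    abe_reaction(
      id = r$id, enzyme = r$enzyme,
      stoich = unlist(r$stoich),
      kind = r$kind,
      substrates = unlist(r$substrates),
      params = purrr::map(r$params, function(p) unlist(p)),
      effector = r$effector,
      regulated = isTRUE(r$regulated)
    )
  })
  new_abe_model(species, reactions,
                note = if (nzchar(x$note %||% "")) x$note)
}

# ---- SBML Level 3 export (export-only) --------------------------------------

# MathML expression for one rate law (kinetic law body, EAC not included)
.mathml_rate <- function(r) {
  ci <- function(x) sprintf("<ci> %s </ci>", x)
  times <- function(...) paste0("<apply><times/>", paste0(...), "</apply>")
  divide <- function(a, b) paste0("<apply><divide/>", a, b, "</apply>")
  plus <- function(...) paste0("<apply><plus/>", paste0(...), "</apply>")
  S <- ci(r$substrates[1])
  switch(r$kind,
    mass_action = times(ci(r$params$k), S),
    michaelis_menten = {
      out <- divide(times(ci(r$params$Vmax), S), plus(ci(r$params$Km[1]), S))
      if (length(r$substrates) > 1L) {
        S2 <- ci(r$substrates[2])
        out <- times(out, divide(S2, plus(ci(r$params$Km[2]), S2)))
      }
      out
    },
    substrate_inhibition = divide(
      times(ci(r$params$Vmax), S),
      plus(ci(r$params$Km), S, divide(times(S, S), ci(r$params$Ki)))),
    product_inhibition = {
      out <- divide(times(ci(r$params$Vmax), S), plus(ci(r$params$Km[1]), S))
      if (length(r$substrates) > 1L) {
        S2 <- ci(r$substrates[2])
        out <- times(out, divide(S2, plus(ci(r$params$Km[2]), S2)))
      }
      divide(out, plus("<cn> 1 </cn>",
                       divide(ci(r$effector), ci(r$params$Ki))))
    },
    activation = times(
      divide(times(ci(r$params$Vmax), S), plus(ci(r$params$Km), S)),
      divide(ci(r$effector), plus(ci(r$params$Ka), ci(r$effector))))
  )
}

#' Export the assembled model as SBML Level 3 (export-only)
#'
#' Writes species, parameters and reactions with their kinetic laws (MathML)
#' to an SBML Level 3 Version 2 document. This is a one-way exchange format
#' for downstream SBML tooling; the package never reads SBML back.
#'
#' @param model An `abe_model`.
#' @param params Parameter table or named vector supplying values.
#' @param path Output `.xml` path.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(model, params, path) {
  stopifnot(inherits(model, "abe_model"))
  pvec <- as_param_vector(params)
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)

  species_xml <- paste0(sprintf(
    '    <species id="%s" name="%s" compartment="cell" initialConcentration="0" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    model$species$id, esc(model$species$name)), collapse = "\n")

  pn <- parameter_names(model)
  params_xml <- paste0(sprintf(
    '    <parameter id="%s" value="%.12g" constant="true"/>',
    pn, unname(pvec[pn])), collapse = "\n")

  rx_xml <- paste0(vapply(model$reactions, function(r) {
    refs <- function(side, tag) {
      s <- r$stoich[sign(r$stoich) == side]
      if (!length(s)) return("")
      paste0(sprintf('        <%s species="%s" stoichiometry="%d" constant="true"/>',
                     tag, names(s), abs(as.integer(s))), collapse = "\n")
    }
    mods <- setdiff(unique(c(r$substrates, r$effector)),
                    names(r$stoich)[r$stoich < 0])
    mods_xml <- if (length(mods))
      paste0(sprintf('        <modifierSpeciesReference species="%s"/>', mods),
             collapse = "\n") else ""
    paste0(
      sprintf('    <reaction id="%s" name="%s" reversible="false">\n', r$id, esc(r$enzyme)),
      "      <listOfReactants>\n", refs(-1, "speciesReference"),
      "\n      </listOfReactants>\n",
      "      <listOfProducts>\n", refs(1, "speciesReference"),
      "\n      </listOfProducts>\n",
      if (nzchar(mods_xml))
        paste0("      <listOfModifiers>\n", mods_xml, "\n      </listOfModifiers>\n")
      else "",
      "      <kineticLaw>\n",
      '        <math xmlns="http://www.w3.org/1998/Math/MathML">\n',
      "          ", .mathml_rate(r), "\n",
      "        </math>\n",
      "      </kineticLaw>\n",
      "    </reaction>")
  }, character(1)), collapse = "\n")

  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">\n',
    '  <model id="abe_pathway" name="ABE pathway kinetic model">\n',
    "  <listOfCompartments>\n",
    '    <compartment id="cell" spatialDimensions="3" size="1" constant="true"/>\n',
    "  </listOfCompartments>\n",
    "  <listOfSpecies>\n", species_xml, "\n  </listOfSpecies>\n",
    "  <listOfParameters>\n", params_xml, "\n  </listOfParameters>\n",
    "  <listOfReactions>\n", rx_xml, "\n  </listOfReactions>\n",
    "  </model>\n</sbml>\n")

  # validate well-formedness before writing
  xml2::read_xml(doc)
  writeLines(doc, path)
  invisible(path)
}
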