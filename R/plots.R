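#' Plot a simulated trajectory
#'
#' @param object An `abe_trajectory`.
#' @param species Character vector of species to draw; defaults to the main
#'   acids and solvents plus butyryl-phosphate where present.
#' @param ... Unused.
#' @return A ggplot object (time vs concentration, coloured by species).
#' @export
autoplot.abe_trajectory <- function(object, species = NULL, ...) {
  default <- intersect(c("Ace", "But", "BuP", "BuOH", "Actn", "EtOH", "Glc"),
                       names(object))
  species <- species %||% default
  long <- tidyr::pivot_longer(object[, c("time_hr", species)],
                              -"time_hr", names_to = "species",
                              values_to = "mM")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_hr, .data$mM,
                                     colour = .data$species)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (hr)", y = "concentration (mM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a perturbation sweep
#'
#' Single-parameter sweeps are drawn as a signed bar chart of Rd by parameter;
#' double-parameter sweeps show the `top` largest-|Rd| pairs.
#'
#' @param object An `abe_sweep`.
#' @param top For double sweeps, how many pairs to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abe_sweep <- function(object, top = 20, ...) {
  if (identical(attr(object, "order"), 2L)) {
    dat <- dplyr::slice_max(object, abs(.data$rd), n = top)
    dat$label <- paste(dat$parameter_1, dat$parameter_2, sep = " + ")
  } else {
    dat <- object
    dat$label <- dat$parameter
  }
  dat$label <- stats::reorder(dat$label, dat$rd)
  ggplot2::ggplot(dat, ggplot2::aes(.data$rd, .data$label,
                                    fill = .data$rd > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "Rd (relative change in butanol production)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a GA convergence log
#'
#' @param object An `abe_fit`.
#' @param ... Unused.
#' @return A ggplot object of best fitness per generation (log scale).
#' @export
autoplot.abe_fit <- function(object, ...) {
  ggplot2::ggplot(object$log,
                  ggplot2::aes(.data$generation, .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "best fitness (SSR)") +
    ggplot2::theme_minimal()
}

#' Plot an EAC schedule
#'
#' Draws the piecewise-constant enzyme activity coefficient of each regulated
#' reaction over the time division.
#'
#' @param object An `abe_eac_schedule`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abe_eac_schedule <- function(object, ...) {
  dat <- tidy(object)
  regulated <- dat |>
    dplyr::group_by(.data$reaction) |>
    dplyr::filter(any(.data$eac < 1)) |>
    dplyr::ungroup()
  if (!nrow(regulated)) regulated <- dat
  ggplot2::ggplot(regulated) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$interval_start,
                                       xend = .data$interval_end,
                                       y = .data$eac, yend = .data$eac)) +
    ggplot2::facet_wrap(~reaction) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (hr)", y = "enzyme activity coefficient") +
    ggplot2::theme_minimal()
}
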