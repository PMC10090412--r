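#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an equilibrium result
#'
#' One row per root found, with frequency, payoff, stability flag, solver
#' method and residual.
#'
#' @param x An `ess_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ess_result
#' @export
tidy.ess_result <- function(x, ...) {
  x$roots
}

#' One-row summary of an equilibrium result
#'
#' @param x An `ess_result`.
#' @param ... Unused.
#' @return A one-row tibble with `p_star`, `payoff_at_eq`, `stable`,
#'   `status`, `n_roots`, `residual`.
#' @method glance ess_result
#' @export
glance.ess_result <- function(x, ...) {
  tibble::tibble(
    p_star = x$p_star, payoff_at_eq = x$payoff_at_eq, stable = x$stable,
    status = x$status, n_roots = nrow(x$roots), residual = x$residual)
}

#' Tidy an encounter simulation
#'
#' @param x An `encounter_sim`.
#' @param ... Unused.
#' @return The interaction ledger tibble.
#' @method tidy encounter_sim
#' @export
tidy.encounter_sim <- function(x, ...) {
  x$ledger
}

#' One-row-per-phenotype summary of an encounter simulation
#'
#' @param x An `encounter_sim`.
#' @param ... Unused.
#' @return The per-phenotype summary tibble.
#' @method glance encounter_sim
#' @export
glance.encounter_sim <- function(x, ...) {
  x$summary
}

#' Plot a frequency trajectory
#'
#' Focal-strategy frequency against time, with the stable interior
#' equilibrium (when supplied) as a dashed reference line.
#'
#' @param object A `sens_trajectory`.
#' @param p_star Optional equilibrium frequency to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sens_trajectory
#' @export
autoplot.sens_trajectory <- function(object, p_star = NULL, ...) {
  gg <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$p)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = if (identical(attr(object, "source"), "moran")) {
      "generation"
    } else "time",
    y = "focal-strategy frequency p",
    title = sprintf("%s trajectory", attr(object, "source"))) +
    ggplot2::theme_minimal()
  if (!is.null(p_star)) {
    gg <- gg + ggplot2::geom_hline(yintercept = p_star, linetype = "dashed")
  }
  gg
}

#' Plot an equilibrium sweep
#'
#' Equilibrium focal frequency against the swept parameter; skipped grid
#' points are omitted.
#'
#' @param object A `sens_sweep` from [sweep_equilibrium()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sens_sweep
#' @export
autoplot.sens_sweep <- function(object, ...) {
  valid <- object[!is.na(object$p_star), ]
  ggplot2::ggplot(valid,
                  ggplot2::aes(x = .data$param_value, y = .data$p_star)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$stable)) +
    ggplot2::labs(x = attr(object, "parameter"),
                  y = "equilibrium focal frequency p*",
                  title = "comparative statics of the mixed equilibrium") +
    ggplot2::theme_minimal()
}

#' Plot the expected-payoff lines of a game
#'
#' Draws `EV_focal(p)` and `EV_other(p)` over the full frequency range —
#' the crossing-lines picture whose intersection is the mixed equilibrium.
#'
#' @param game A [static_game()].
#' @param n Number of grid points, default 201.
#' @return A ggplot object.
#' @export
plot_payoff_lines <- function(game, n = 201) {
  p <- seq(0, 1, length.out = n)
  ev <- expected_payoffs(game, p)
  long <- tidyr::pivot_longer(ev, c("ev_focal", "ev_other"),
                              names_to = "strategy", values_to = "ev")
  long$strategy <- ifelse(long$strategy == "ev_focal",
                          game$focal_label, game$other_label)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$p, y = .data$ev,
                                     colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("%s frequency p", game$focal_label),
                  y = "expected payoff",
                  title = "expected payoffs by frequency") +
    ggplot2::theme_minimal()
}
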