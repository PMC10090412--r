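#' Sweep the mixed equilibrium over one parameter
#'
#' Comparative statics of the equilibrium migraineur fraction: one parameter
#' of the game is varied over a grid while the others are held fixed, and
#' [mixed_equilibrium()] is solved at each grid point. Grid points that
#' violate the fitness ordering (for the generalized form) or the parameter
#' invariants (for the printed form) are flagged `"skipped"` with the
#' violated invariant as the reason rather than dropped silently.
#'
#' For the generalized game the closed form
#' `p* = (d_m - d_n) / ((d_m - d_n) + (f_n - f_m))` makes the predicted
#' directions transparent: lowering `d_n` (non-migraineurs fare worse alone)
#' raises the equilibrium migraineur fraction, and widening `f_n - f_m`
#' lowers it.
#'
#' @param parameter Name of the parameter to vary: one of `"f_n"`, `"f_m"`,
#'   `"d_m"`, `"d_n"` (generalized form) or `"c_m"`, `"c_n"`, `"d_m_prime"`
#'   (printed form).
#' @param values Numeric grid of parameter values (non-empty).
#' @param fixed A [generalized_game()] or [migraine_params()] object holding
#'   the remaining parameters; its class selects the game form.
#' @return A tibble of class `sens_sweep` with columns `parameter`,
#'   `param_value`, `p_star`, `payoff`, `stable`, `status`.
#' @export
#' @examples
#' sweep_equilibrium("d_n", c(0.9, 0.8),
#'                   fixed = generalized_game(1.2, 1.1, 1.0, 0.9))
sweep_equilibrium <- function(parameter, values, fixed) {
  if (length(values) == 0 || !is.numeric(values)) {
    abort_config("`values` must be a non-empty numeric grid")
  }
  form <- if (inherits(fixed, "generalized_game")) {
    "generalized"
  } else if (inherits(fixed, "migraine_params")) {
    "printed"
  } else {
    abort_config("`fixed` must be a generalized_game or migraine_params object")
  }
  valid_pars <- if (form == "generalized") {
    c("f_n", "f_m", "d_m", "d_n", "d_m_prime")
  } else {
    c("c_m", "c_n", "d_m_prime")
  }
  if (!parameter %in% valid_pars) {
    abort_config(sprintf("`parameter` must be one of: %s",
                         paste(valid_pars, collapse = ", ")))
  }

  rows <- purrr::map_dfr(values, function(v) {
    args <- unclass(fixed)
    if (form == "generalized") {
      args <- args[c("f_n", "f_m", "d_m", "d_n", "d_m_prime")]
      args[[parameter]] <- v
      g <- tryCatch(do.call(generalized_game, args),
                    sensgame_validation_error = function(e) e)
    } else {
      args <- args[c("c_m", "c_n", "d_m_prime")]
      args[[parameter]] <- v
      g <- tryCatch(do.call(migraine_params, args),
                    sensgame_validation_error = function(e) e)
    }
    if (inherits(g, "error")) {
      return(tibble::tibble(
        parameter = parameter, param_value = v, p_star = NA_real_,
        payoff = NA_real_, stable = NA,
        status = paste0("skipped: ", g$invariant %||% conditionMessage(g))))
    }
    game <- if (form == "generalized") {
      migraine_game_generalized(g)
    } else {
      migraine_game_printed(g)
    }
    eq <- mixed_equilibrium(game)
    tibble::tibble(
      parameter = parameter, param_value = v, p_star = eq$p_star,
      payoff = eq$payoff_at_eq, stable = eq$stable, status = eq$status)
  })
  structure(rows, class = c("sens_sweep", class(rows)),
            parameter = parameter, form = form)
}

#' Check monotonicity of the equilibrium across a sweep
#'
#' Verifies that `p_star` moves strictly in the expected direction across all
#' adjacent valid (non-skipped) rows of a sweep table sorted by
#' `param_value`. An unsorted table is a precondition violation and raises an
#' error; fewer than two valid rows give status `"inconclusive"`.
#'
#' @param table A tibble from [sweep_equilibrium()] (or any table with
#'   `param_value`, `p_star` and `status` columns), sorted by `param_value`.
#' @param expected `"increasing"` or `"decreasing"` (direction of `p_star`
#'   as `param_value` increases).
#' @return A one-row tibble with columns `status` (`"pass"`, `"fail"`,
#'   `"inconclusive"`), `n_valid`, and `first_violation_at` (the
#'   `param_value` at which the first violation occurs, `NA` otherwise).
#' @export
monotonicity_test <- function(table, expected = c("increasing", "decreasing")) {
  expected <- match.arg(expected)
  stopifnot(all(c("param_value", "p_star") %in% names(table)))
  if (is.unsorted(table$param_value, strictly = FALSE)) {
    abort_config("`table` must be sorted by param_value")
  }
  valid <- !is.na(table$p_star)
  if ("status" %in% names(table)) {
    valid <- valid & !startsWith(table$status, "skipped")
  }
  tv <- table[valid, ]
  if (nrow(tv) < 2) {
    return(tibble::tibble(status = "inconclusive", n_valid = nrow(tv),
                          first_violation_at = NA_real_))
  }
  dp <- diff(tv$p_star)
  ok <- if (expected == "increasing") dp > 0 else dp < 0
  if (all(ok)) {
    tibble::tibble(status = "pass", n_valid = nrow(tv),
                   first_violation_at = NA_real_)
  } else {
    tibble::tibble(status = "fail", n_valid = nrow(tv),
                   first_violation_at = tv$param_value[which(!ok)[1] + 1L])
  }
}
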