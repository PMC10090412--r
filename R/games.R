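#' Contest scoring primitives for the Hawk-Dove game
#'
#' Bundles the four scoring primitives of the classic two-strategy contest:
#' the value of a win, the value of a loss, the (negative) value of serious
#' injury or death, and the (negative) value of time wasted in a threat
#' display. The canonical defaults are Dawkins's +50 / 0 / -100 / -10.
#'
#' @param win_value Payoff points for winning a contest.
#' @param loss_value Payoff points for losing a contest.
#' @param injury_value Payoff points for serious injury or death; must be
#'   strictly below `loss_value`.
#' @param time_cost Payoff points for time wasted in a display, stored as the
#'   signed value (e.g. `-10`).
#'
#' @return An object of class `contest_rules`.
#' @export
#' @examples
#' contest_rules()                     # Dawkins's scoring
#' contest_rules(40, 0, -60, -5)
contest_rules <- function(win_value = 50, loss_value = 0,
                          injury_value = -100, time_cost = -10) {
  vals <- c(win_value = win_value, loss_value = loss_value,
            injury_value = injury_value, time_cost = time_cost)
  if (!all(is.finite(vals))) {
    abort_validation("contest_rules: all values must be finite",
                     invariant = "all values finite")
  }
  if (!(injury_value <= loss_value)) {
    abort_validation(
      "contest_rules: injury_value must not exceed loss_value",
      invariant = "injury_value <= loss_value")
  }
  if (!(loss_value <= win_value)) {
    abort_validation(
      "contest_rules: loss_value must not exceed win_value",
      invariant = "loss_value <= win_value")
  }
  structure(as.list(vals), class = "contest_rules")
}

#' @export
print.contest_rules <- function(x, ...) {
  cat("<contest_rules>\n")
  cat(sprintf("  win %+g, loss %+g, injury %+g, time cost %+g\n",
              x$win_value, x$loss_value, x$injury_value, x$time_cost))
  invisible(x)
}

#' Construct a two-strategy game
#'
#' Low-level constructor for a symmetric 2x2 game whose payoff cells may be
#' constants or functions of the focal-strategy frequency `p`. Most users
#' should call [hawk_dove_game()], [migraine_game_printed()] or
#' [migraine_game_generalized()] instead.
#'
#' The internal cell convention is payoff(actor, partner): `ff` focal vs
#' focal, `fo` focal vs other, `of` other vs focal, `oo` other vs other.
#' `p` always denotes the frequency of the *focal* strategy.
#'
#' @param focal_label,other_label Strategy names.
#' @param cells Either a named numeric vector `c(ff=, fo=, of=, oo=)` or a
#'   function of `p` returning a list with those four components, vectorised
#'   over `p`.
#' @param frequency_dependent Logical; must be `TRUE` iff `cells` is a
#'   function.
#' @param meta Optional list of provenance (parameters used to build the
#'   game).
#'
#' @return An object of class `static_game`.
#' @export
static_game <- function(focal_label, other_label, cells,
                        frequency_dependent = FALSE, meta = list()) {
  if (frequency_dependent) {
    stopifnot(is.function(cells))
    cells_fun <- cells
  } else {
    stopifnot(is.numeric(cells), all(c("ff", "fo", "of", "oo") %in% names(cells)))
    if (!all(is.finite(cells))) {
      abort_validation("static_game: all payoff cells must be finite",
                       invariant = "payoff finite")
    }
    const <- as.list(cells[c("ff", "fo", "of", "oo")])
    cells_fun <- function(p) {
      lapply(const, function(v) rep_len(unname(v), length(p)))
    }
  }
  structure(
    list(focal_label = focal_label, other_label = other_label,
         cells_fun = cells_fun, frequency_dependent = frequency_dependent,
         meta = meta),
    class = "static_game")
}

#' @export
print.static_game <- function(x, ...) {
  cat(sprintf("<static_game> %s vs %s (%s)\n", x$focal_label, x$other_label,
              if (x$frequency_dependent) "frequency-dependent" else "constant"))
  m <- as_payoff_matrix(x, p = 0.5)
  print(round(m, 4))
  if (x$frequency_dependent) cat("  (cells shown at p = 0.5)\n")
  invisible(x)
}

#' Payoff matrix of a game at a given focal frequency
#'
#' @param game A `static_game`.
#' @param p Focal-strategy frequency at which frequency-dependent cells are
#'   evaluated (irrelevant for constant games).
#' @return A 2x2 numeric matrix, rows = actor, columns = partner, labelled
#'   with the strategy names (focal strategy first).
#' @export
as_payoff_matrix <- function(game, p = 0.5) {
  stopifnot(inherits(game, "static_game"))
  cl <- game$cells_fun(p)
  m <- matrix(c(cl$ff, cl$of, cl$fo, cl$oo), nrow = 2,
              dimnames = list(actor = c(game$focal_label, game$other_label),
                              partner = c(game$focal_label, game$other_label)))
  m
}

#' Payoff of one strategy against another
#'
#' @param game A `static_game`.
#' @param actor,partner Strategy labels.
#' @param p Focal-strategy frequency (for frequency-dependent cells);
#'   vectorised.
#' @return Numeric vector of payoff points, one per element of `p`.
#' @export
payoff_value <- function(game, actor, partner, p = 0.5) {
  stopifnot(inherits(game, "static_game"))
  check_probability(p, "p")
  key <- paste(match_strategy(game, actor), match_strategy(game, partner),
               sep = "")
  game$cells_fun(p)[[c(ff = "ff", fo = "fo", of = "of", oo = "oo")[[key]]]]
}

match_strategy <- function(game, label) {
  if (identical(label, game$focal_label)) return("f")
  if (identical(label, game$other_label)) return("o")
  abort_validation(
    sprintf("unknown strategy label '%s' (expected '%s' or '%s')",
            label, game$focal_label, game$other_label),
    invariant = "strategy label")
}

#' Build the Hawk-Dove game from contest primitives
#'
#' Each cell is the expected score over the contest outcomes: two hawks fight
#' until one is injured, so each expects `(win + injury) / 2`; a hawk beats a
#' dove outright; two doves posture until one backs down, each expecting
#' `(win + loss) / 2 + time_cost`. Winners of symmetric contests are decided
#' by a fair coin flip and the cell is the average over both outcomes.
#'
#' The focal strategy is the dove, so `p` denotes the dove frequency
#' throughout (the convention used for this game's expected-payoff lines).
#'
#' @param rules A [contest_rules()] object.
#' @return A constant `static_game` with strategies `"dove"` (focal) and
#'   `"hawk"`.
#' @export
#' @examples
#' g <- hawk_dove_game(contest_rules(50, 0, -100, -10))
#' as_payoff_matrix(g)   # hawk-hawk -25, hawk-dove +50, dove-hawk 0, dove-dove +15
hawk_dove_game <- function(rules = contest_rules()) {
  if (!inherits(rules, "contest_rules")) {
    rules <- do.call(contest_rules, as.list(rules))
  }
  a_hh <- (rules$win_value + rules$injury_value) / 2
  a_hd <- rules$win_value
  a_dh <- rules$loss_value
  a_dd <- (rules$win_value + rules$loss_value) / 2 + rules$time_cost
  static_game(
    focal_label = "dove", other_label = "hawk",
    cells = c(ff = a_dd, fo = a_dh, of = a_hd, oo = a_hh),
    frequency_dependent = FALSE,
    meta = list(rules = rules, form = "hawk_dove"))
}

#' Cost parameters of the migraineur / non-migraineur game
#'
#' The printed form of the cooperation game is parameterised by the
#' migraineur's cost `c_m` (maintaining a hypersensitive nervous system and
#' warning a partner of predators at the risk of exposure), the
#' non-migraineur's cost `c_n` (rescuing a migraineur mid-attack), and the
#' betrayal fitness `d_m'` (a migraineur abandoned mid-attack). The baseline
#' fitness of a rescued migraineur, `d_m`, is normalised to 1; rescaling is
#' multiplicative. Derived values: `f_n = 1 + c_n`, `d_n = 1 - (c_m - c_n)`,
#' `b_n = f_n - d_n`, `b_m = d_m - d_m'`, and the frequency-dependent
#' `f_m(p) = 1 + c_n - (1 - p) p (c_m - c_n)`.
#'
#' Validity requires `c_m > c_n > 0` (so the fitness ordering
#' `f_n > d_m > d_n` holds) and `1 - d_m' > c_m` (the migraineur's net
#' benefit of the exchange, `b_m - c_m`, is positive).
#'
#' @param c_m Migraineur cost, fitness units, in (0, 1).
#' @param c_n Non-migraineur cost, fitness units, in (0, c_m).
#' @param d_m_prime Betrayal fitness; default `(1 - c_m) / 2`, which sits
#'   below both `d_n` and `1 - c_m`.
#' @return An object of class `migraine_params` with the derived fitness
#'   values attached.
#' @export
#' @examples
#' migraine_params(c_m = 0.3, c_n = 0.2)
migraine_params <- function(c_m, c_n, d_m_prime = (1 - c_m) / 2) {
  if (!all(is.finite(c(c_m, c_n, d_m_prime)))) {
    abort_validation("migraine_params: all parameters must be finite",
                     invariant = "all values finite")
  }
  if (!(c_m > c_n && c_n > 0)) {
    abort_validation(
      "migraine_params: need c_m > c_n > 0 (otherwise the fitness ordering f_n > d_m > d_n collapses)",
      invariant = "c_m > c_n > 0")
  }
  if (!(d_m_prime < 1)) {
    abort_validation("migraine_params: d_m_prime must be below the baseline d_m = 1",
                     invariant = "d_m_prime < d_m_base")
  }
  if (!(1 - d_m_prime > c_m)) {
    abort_validation(
      "migraine_params: need d_m_base - d_m_prime > c_m (equivalently b_m - c_m > 0)",
      invariant = "d_m_base - d_m_prime > c_m")
  }
  structure(
    list(c_m = c_m, c_n = c_n, d_m_prime = d_m_prime, d_m_base = 1,
         f_n = 1 + c_n, d_m = 1, d_n = 1 - (c_m - c_n),
         b_n = (1 + c_n) - (1 - (c_m - c_n)),  # = c_m
         b_m = 1 - d_m_prime),
    class = "migraine_params")
}

#' @export
print.migraine_params <- function(x, ...) {
  cat("<migraine_params>\n")
  cat(sprintf("  c_m = %g, c_n = %g, d_m' = %g (d_m normalised to 1)\n",
              x$c_m, x$c_n, x$d_m_prime))
  cat(sprintf("  derived: f_n = %g, d_n = %g, b_m = %g, b_n = %g\n",
              x$f_n, x$d_n, x$b_m, x$b_n))
  invisible(x)
}

#' The printed, frequency-dependent migraineur game
#'
#' Builds the migraineur / non-migraineur game in its printed form, where the
#' migraineur-meets-migraineur cell carries the frequency-dependent gap term:
#' cells (actor, partner) are
#' `(m,m) = 1 + c_n - (1-p) p (c_m - c_n)`, `(m,n) = 1`, `(n,m) = 1 + c_n`,
#' `(n,n) = 1 - (c_m - c_n)`. The focal strategy is the migraineur, so `p`
#' is the migraineur frequency.
#'
#' Note that with `c_m > c_n` the migraineur's expected payoff strictly
#' exceeds the non-migraineur's for all `p < 1`, so this form has no interior
#' mixed equilibrium; see [verify_paper_identity()] for the diagnostic that
#' quantifies the discrepancy from the claimed common-payoff line.
#'
#' @param params A [migraine_params()] object.
#' @return A frequency-dependent `static_game` with strategies
#'   `"migraineur"` (focal) and `"non_migraineur"`.
#' @export
#' @examples
#' g <- migraine_game_printed(migraine_params(0.3, 0.2))
#' as_payoff_matrix(g, p = 0.5)
migraine_game_printed <- function(params) {
  stopifnot(inherits(params, "migraine_params"))
  c_m <- params$c_m; c_n <- params$c_n
  cells_fun <- function(p) {
    gap <- (1 - p) * p * (c_m - c_n)
    list(ff = 1 + c_n - gap,
         fo = rep_len(1, length(p)),
         of = rep_len(1 + c_n, length(p)),
         oo = rep_len(1 - (c_m - c_n), length(p)))
  }
  static_game("migraineur", "non_migraineur", cells_fun,
              frequency_dependent = TRUE,
              meta = list(params = params, form = "migraine_printed"))
}

#' Constant-fitness generalisation of the migraineur game
#'
#' Parameterises the cooperation game by four constant fitness values:
#' `f_n` (non-migraineur warned by a migraineur), `f_m` (migraineur meeting a
#' migraineur — each notices danger and escapes, but pays for the sensitive
#' nervous system, so `f_m < f_n`), `d_m` (migraineur rescued by a
#' non-migraineur under the agreement) and `d_n` (two non-migraineurs,
#' neither warned). The crossing-lines ordering `f_n > f_m > d_m > d_n`
#' makes the payoff pattern match the Hawk-Dove game and guarantees a unique
#' stable interior equilibrium.
#'
#' @param f_n,f_m,d_m,d_n Constant fitness values obeying
#'   `f_n > f_m > d_m > d_n`.
#' @param d_m_prime Betrayal fitness, below `d_m`; default halfway between
#'   `d_n - (d_m - d_n)` and `d_n`, i.e. below `d_n`.
#' @return An object of class `generalized_game`.
#' @export
#' @examples
#' generalized_game(f_n = 1.2, f_m = 1.1, d_m = 1.0, d_n = 0.9)
generalized_game <- function(f_n, f_m, d_m, d_n,
                             d_m_prime = d_n - (d_m - d_n) / 2) {
  vals <- c(f_n = f_n, f_m = f_m, d_m = d_m, d_n = d_n,
            d_m_prime = d_m_prime)
  if (!all(is.finite(vals))) {
    abort_validation("generalized_game: all fitness values must be finite",
                     invariant = "all values finite")
  }
  pairs <- list(c("f_n", "f_m"), c("f_m", "d_m"), c("d_m", "d_n"))
  for (pr in pairs) {
    if (!(vals[[pr[1]]] > vals[[pr[2]]])) {
      abort_validation(
        sprintf("generalized_game: ordering violated, need %s > %s", pr[1], pr[2]),
        invariant = sprintf("%s > %s", pr[1], pr[2]))
    }
  }
  if (!(d_m_prime < d_m)) {
    abort_validation("generalized_game: need d_m_prime < d_m",
                     invariant = "d_m_prime < d_m")
  }
  structure(as.list(vals), class = "generalized_game")
}

#' @export
print.generalized_game <- function(x, ...) {
  cat("<generalized_game>\n")
  cat(sprintf("  f_n = %g > f_m = %g > d_m = %g > d_n = %g; d_m' = %g\n",
              x$f_n, x$f_m, x$d_m, x$d_n, x$d_m_prime))
  invisible(x)
}

#' Build the constant-cell migraineur game
#'
#' Cells (actor, partner): `(m,m) = f_m`, `(m,n) = d_m`, `(n,m) = f_n`,
#' `(n,n) = d_n`. The focal strategy is the migraineur.
#'
#' @param g A [generalized_game()] object.
#' @return A constant `static_game`.
#' @export
migraine_game_generalized <- function(g) {
  stopifnot(inherits(g, "generalized_game"))
  static_game("migraineur", "non_migraineur",
              cells = c(ff = g$f_m, fo = g$d_m, of = g$f_n, oo = g$d_n),
              frequency_dependent = FALSE,
              meta = list(params = g, form = "migraine_generalized"))
}

#' Costs and benefits of the reciprocal exchange
#'
#' Reads the reciprocal-altruism cost/benefit decomposition off a
#' constant-fitness game, using the printed definitions:
#' `c_n = f_n - d_m` (cost of rescuing), `b_n = f_n - d_n` (benefit of being
#' warned), `c_m = f_n - d_n` (the printed definition of the migraineur's
#' total cost — note it coincides with `b_n` as printed; both are reported
#' verbatim), and `b_m = d_m - d_m'` (benefit of being rescued rather than
#' betrayed). The exchange is sustainable only when both net benefits are
#' positive; the flags report `b_m - c_m > 0` and `b_n - c_n > 0` rather
#' than raising.
#'
#' @param g A [generalized_game()] object.
#' @return A one-row tibble with columns `c_n`, `b_n`, `c_m`, `b_m`,
#'   `bm_net`, `bn_net`, `bm_positive`, `bn_positive`.
#' @export
#' @examples
#' derive_costs_benefits(generalized_game(1.2, 1.1, 1.0, 0.9, d_m_prime = 0.5))
derive_costs_benefits <- function(g) {
  stopifnot(inherits(g, "generalized_game"))
  c_n <- g$f_n - g$d_m
  b_n <- g$f_n - g$d_n
  c_m <- g$f_n - g$d_n
  b_m <- g$d_m - g$d_m_prime
  tibble::tibble(
    c_n = c_n, b_n = b_n, c_m = c_m, b_m = b_m,
    bm_net = b_m - c_m, bn_net = b_n - c_n,
    bm_positive = b_m - c_m > 0, bn_positive = b_n - c_n > 0)
}
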