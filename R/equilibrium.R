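#' Expected payoffs of both strategies at a focal frequency
#'
#' In an infinite well-mixed population a strategy's expected payoff is the
#' frequency-weighted average of its payoff against each partner type:
#' `EV_s(p) = p * payoff(s, focal) + (1 - p) * payoff(s, other)`, with
#' frequency-dependent cells evaluated at the same `p`. For the Hawk-Dove
#' game (focal = dove) this reproduces the textbook lines
#' `EV_hawk = -25 (1-p) + 50 p` and `EV_dove = 0 (1-p) + 15 p`.
#'
#' @param game A [static_game()].
#' @param p Focal-strategy frequency, vectorised.
#' @return A tibble with columns `p`, `ev_focal`, `ev_other`.
#' @export
#' @examples
#' expected_payoffs(hawk_dove_game(), p = 5 / 12)  # both 6.25
expected_payoffs <- function(game, p) {
  stopifnot(inherits(game, "static_game"))
  check_probability(p, "p")
  cl <- game$cells_fun(p)
  tibble::tibble(
    p = p,
    ev_focal = cl$ff * p + cl$fo * (1 - p),
    ev_other = cl$of * p + cl$oo * (1 - p))
}

#' Payoff advantage of the focal strategy
#'
#' `payoff_gap(game, p) = EV_focal(p) - EV_other(p)`; its roots are the mixed
#' equilibria and its sign drives the replicator dynamics.
#'
#' @inheritParams expected_payoffs
#' @return Numeric vector.
#' @export
payoff_gap <- function(game, p) {
  stopifnot(inherits(game, "static_game"))
  check_probability(p, "p")
  cl <- game$cells_fun(p)
  (cl$ff - cl$of) * p + (cl$fo - cl$oo) * (1 - p)
}

#' Mean payoff of the whole population
#'
#' `p * EV_focal(p) + (1 - p) * EV_other(p)`. For the Hawk-Dove game this is
#' +15 in an all-dove population, -25 in an all-hawk population, and +6.25 at
#' the mixed equilibrium — the group-versus-equilibrium contrast.
#'
#' @inheritParams expected_payoffs
#' @return Numeric vector of payoff points.
#' @export
population_mean_payoff <- function(game, p) {
  ev <- expected_payoffs(game, p)
  ev$p * ev$ev_focal + (1 - ev$p) * ev$ev_other
}

#' Expected payoff of a vanishingly rare invader
#'
#' The invader is too rare to affect the population composition, so its
#' payoff is its strategy's expected payoff evaluated exactly at the resident
#' focal frequency (no small-epsilon approximation). A lone hawk in an
#' all-dove population scores +50; a lone dove among hawks scores 0.
#'
#' @param game A [static_game()].
#' @param invader Strategy label of the invader.
#' @param resident_p Focal-strategy frequency among residents.
#' @return Payoff points (numeric).
#' @export
invasion_payoff <- function(game, invader, resident_p) {
  check_probability(resident_p, "resident_p")
  side <- match_strategy(game, invader)
  ev <- expected_payoffs(game, resident_p)
  if (side == "f") ev$ev_focal else ev$ev_other
}

#' Classify the stability of an equilibrium frequency
#'
#' An interior mixed state is evolutionarily stable when the focal strategy
#' is favoured below it and disfavoured above it: the payoff gap changes sign
#' from + to - across `p_star` (checked at `p_star +/- eps`). Boundary states
#' are classified by a one-sided invasion test: `p = 0` is stable iff the
#' focal strategy cannot invade (`gap(eps) < 0`), `p = 1` iff the other
#' strategy cannot (`gap(1 - eps) > 0`).
#'
#' @param game A [static_game()].
#' @param p_star Equilibrium frequency in \[0, 1\].
#' @param eps Probe offset, default `1e-6`.
#' @return `"stable"` or `"unstable"`.
#' @export
classify_stability <- function(game, p_star, eps = 1e-6) {
  check_probability(p_star, "p_star")
  if (p_star <= eps) {
    return(if (payoff_gap(game, eps) < 0) "stable" else "unstable")
  }
  if (p_star >= 1 - eps) {
    return(if (payoff_gap(game, 1 - eps) > 0) "stable" else "unstable")
  }
  lo <- payoff_gap(game, p_star - eps)
  hi <- payoff_gap(game, p_star + eps)
  if (lo > 0 && hi < 0) "stable" else "unstable"
}

#' Solve for the mixed evolutionarily stable state
#'
#' Finds the frequencies at which both strategies earn the same expected
#' payoff. For constant games the gap `EV_focal(p) - EV_other(p)` is linear
#' and the root has the closed form `p* = D0 / (D0 + D1)` with
#' `D0 = gap(0)` and `D1 = -gap(1)`; for frequency-dependent games the gap
#' is scanned on a grid (step `step`) and every bracketed sign change is
#' refined with Brent's method ([stats::uniroot()]) to tolerance `tol`.
#' All interior roots are reported, each with a stability classification.
#'
#' When no interior root exists the dominating boundary is reported with its
#' one-sided invasion classification; when the gap is identically zero the
#' status is `"degenerate"`.
#'
#' @param game A [static_game()].
#' @param method `"auto"` (closed form for constant games, scan otherwise),
#'   `"analytic"` or `"scan"`.
#' @param step Grid step for the scan, default `1e-3`.
#' @param tol Root refinement tolerance, default `1e-10`.
#' @param eps Stability probe offset passed to [classify_stability()].
#' @return An object of class `ess_result`: fields `p_star`, `payoff_at_eq`,
#'   `stable`, `method`, `residual` for the primary root (the first stable
#'   root, if any), `status` (`"interior"`, `"boundary"`, `"degenerate"`),
#'   and a tibble `roots` with one row per root found.
#' @export
#' @examples
#' mixed_equilibrium(hawk_dove_game())  # dove fraction 5/12, payoff 6.25
mixed_equilibrium <- function(game, method = c("auto", "analytic", "scan"),
                              step = 1e-3, tol = 1e-10, eps = 1e-6) {
  stopifnot(inherits(game, "static_game"))
  method <- match.arg(method)
  if (method == "analytic" && game$frequency_dependent) {
    abort_config("analytic method requires a constant game")
  }
  use_analytic <- (method == "analytic") ||
    (method == "auto" && !game$frequency_dependent)

  grid <- seq(0, 1, by = step)
  gap <- payoff_gap(game, grid)

  if (max(abs(gap)) < 1e-13) {
    return(new_ess_result(game, roots = empty_roots(), status = "degenerate"))
  }

  roots <- numeric(0)
  used_method <- if (use_analytic) "analytic" else "root_scan"
  if (use_analytic) {
    d0 <- payoff_gap(game, 0)
    d1 <- -payoff_gap(game, 1)
    if ((d0 + d1) != 0) {
      cand <- d0 / (d0 + d1)
      if (cand > 0 && cand < 1) roots <- cand
    }
  } else {
    sgn <- sign(gap)
    # exact zeros on the grid (interior)
    hit <- which(sgn == 0 & grid > 0 & grid < 1)
    roots <- grid[hit]
    flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (i in flip) {
      r <- stats::uniroot(function(q) payoff_gap(game, q),
                          lower = grid[i], upper = grid[i + 1], tol = tol)
      roots <- c(roots, r$root)
    }
    roots <- sort(unique(roots))
    roots <- roots[roots > 0 & roots < 1]
  }

  if (length(roots) > 0) {
    rows <- purrr::map_dfr(roots, function(p0) {
      ev <- expected_payoffs(game, p0)
      tibble::tibble(
        p_star = p0,
        payoff = ev$ev_focal,
        stable = classify_stability(game, p0, eps = eps) == "stable",
        method = used_method,
        residual = abs(payoff_gap(game, p0)))
    })
    return(new_ess_result(game, roots = rows, status = "interior"))
  }

  # no interior root: the sign of the gap picks the dominating boundary
  boundary <- if (mean(gap) > 0) 1 else 0
  ev <- expected_payoffs(game, boundary)
  rows <- tibble::tibble(
    p_star = boundary,
    payoff = if (boundary == 1) ev$ev_focal else ev$ev_other,
    stable = classify_stability(game, boundary, eps = eps) == "stable",
    method = used_method,
    residual = NA_real_)
  new_ess_result(game, roots = rows, status = "boundary")
}

empty_roots <- function() {
  tibble::tibble(p_star = numeric(), payoff = numeric(), stable = logical(),
                 method = character(), residual = numeric())
}

new_ess_result <- function(game, roots, status) {
  primary <- if (nrow(roots) == 0) {
    list(p_star = NA_real_, payoff = NA_real_, stable = NA)
  } else {
    k <- if (any(roots$stable)) which(roots$stable)[1] else 1L
    list(p_star = roots$p_star[k], payoff = roots$payoff[k],
         stable = roots$stable[k])
  }
  structure(
    list(p_star = primary$p_star, payoff_at_eq = primary$payoff,
         stable = primary$stable, status = status, roots = roots,
         focal_label = game$focal_label, other_label = game$other_label,
         residual = if (nrow(roots)) roots$residual[1] else NA_real_),
    class = "ess_result")
}

#' @export
print.ess_result <- function(x, ...) {
  cat(sprintf("<ess_result> %s vs %s: status = %s\n",
              x$focal_label, x$other_label, x$status))
  if (x$status == "degenerate") {
    cat("  payoff gap identically zero: every frequency is an equilibrium\n")
  } else {
    cat(sprintf("  p* (%s fraction) = %.10g, payoff = %.10g, %s\n",
                x$focal_label, x$p_star, x$payoff_at_eq,
                if (isTRUE(x$stable)) "stable" else "unstable"))
    if (nrow(x$roots) > 1) cat(sprintf("  (%d roots; see tidy())\n", nrow(x$roots)))
  }
  invisible(x)
}

#' Audit the common-payoff identity of the printed migraineur game
#'
#' The printed derivation asserts that both phenotypes' expected payoffs
#' simplify to the same line `1 - c_m (1 - p) + c_n`. For the
#' non-migraineur this is an exact algebraic identity; for the migraineur the
#' printed gap term leaves a residual `(1 - p)^2 (1 + p) (c_m - c_n)` which
#' vanishes only at `p = 1` or `c_m = c_n`. This diagnostic computes both
#' expected payoffs from the printed cells and reports both signed residuals,
#' surfacing the discrepancy without correcting it.
#'
#' @param params A [migraine_params()] object.
#' @param p Migraineur frequency, vectorised.
#' @return A tibble of class `identity_diagnostic` with columns `p`, `c_m`,
#'   `c_n`, `ev_m`, `ev_n`, `claimed`, `residual_m`, `residual_n`.
#' @export
#' @examples
#' verify_paper_identity(migraine_params(0.3, 0.2), p = 0.5)
verify_paper_identity <- function(params, p) {
  stopifnot(inherits(params, "migraine_params"))
  check_probability(p, "p")
  game <- migraine_game_printed(params)
  ev <- expected_payoffs(game, p)
  claimed <- 1 - params$c_m * (1 - p) + params$c_n
  out <- tibble::tibble(
    p = p, c_m = params$c_m, c_n = params$c_n,
    ev_m = ev$ev_focal, ev_n = ev$ev_other, claimed = claimed,
    residual_m = ev$ev_focal - claimed,
    residual_n = ev$ev_other - claimed)
  class(out) <- c("identity_diagnostic", class(out))
  out
}
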