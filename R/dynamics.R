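#' Replicator growth rate of the focal strategy
#'
#' Standard two-strategy replicator form: the focal frequency grows in
#' proportion to its payoff advantage over the population,
#' `dp/dt = p (1 - p) (EV_focal(p) - EV_other(p))`. Fixed points are the
#' boundaries and the mixed equilibria.
#'
#' @inheritParams expected_payoffs
#' @return Numeric vector of rates.
#' @export
#' @examples
#' replicator_derivative(hawk_dove_game(), p = 5 / 12)  # 0 at the ESS
replicator_derivative <- function(game, p) {
  check_probability(p, "p")
  p * (1 - p) * payoff_gap(game, p)
}

#' Integrate the replicator dynamics
#'
#' Fixed-step 4th-order Runge-Kutta integration of the replicator equation,
#' stopping once `|dp/dt| < tol` (converged) or at `t_max`. The state is
#' clamped to \[0, 1\] against round-off. Frequency-dependent payoff cells
#' are re-evaluated at the current frequency at every stage.
#'
#' @param game A [static_game()].
#' @param p0 Initial focal frequency.
#' @param t_max Maximum integration time, default `1e4`.
#' @param dt Step size, default `0.01`.
#' @param tol Convergence tolerance on `|dp/dt|`, default `1e-8`.
#' @param record_every Record one sample every this many steps (the initial
#'   and final states are always recorded), default 10.
#' @return A tibble of class `sens_trajectory` with columns `t`, `p`,
#'   `ev_focal`, `ev_other`, `mean_payoff`; attributes `converged`,
#'   `final_p`, `source = "replicator"`.
#' @export
#' @examples
#' tr <- simulate_replicator(hawk_dove_game(), p0 = 0.9)
#' attr(tr, "final_p")  # 5/12
simulate_replicator <- function(game, p0, t_max = 1e4, dt = 0.01,
                                tol = 1e-8, record_every = 10L) {
  stopifnot(inherits(game, "static_game"))
  check_probability(p0, "p0")
  check_positive(dt, "dt")
  check_positive(t_max, "t_max")
  # constant games have a linear payoff gap: precompute it so the inner RK4
  # loop costs microseconds rather than a full cell evaluation per stage
  if (!game$frequency_dependent) {
    cl <- game$cells_fun(0)
    a0 <- cl$fo - cl$oo
    a1 <- (cl$ff - cl$of) - (cl$fo - cl$oo)
    f <- function(p) p * (1 - p) * (a0 + a1 * p)
  } else {
    f <- function(p) p * (1 - p) * unname(payoff_gap(game, p))
  }

  n_steps <- ceiling(t_max / dt)
  ts <- ps <- numeric(0)
  p <- p0
  t <- 0
  converged <- FALSE
  keep <- function(t, p) { ts[[length(ts) + 1L]] <<- t; ps[[length(ps) + 1L]] <<- p }
  keep(t, p)
  for (i in seq_len(n_steps)) {
    k1 <- f(p)
    if (abs(k1) < tol) { converged <- TRUE; break }
    k2 <- f(min(1, max(0, p + dt / 2 * k1)))
    k3 <- f(min(1, max(0, p + dt / 2 * k2)))
    k4 <- f(min(1, max(0, p + dt * k3)))
    p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    p <- min(1, max(0, p))
    t <- t + dt
    if (i %% record_every == 0L) keep(t, p)
  }
  if (ts[length(ts)] != t) keep(t, p)

  ev <- expected_payoffs(game, ps)
  out <- tibble::tibble(
    t = ts, p = ps, ev_focal = ev$ev_focal, ev_other = ev$ev_other,
    mean_payoff = ps * ev$ev_focal + (1 - ps) * ev$ev_other)
  new_trajectory(out, converged = converged, final_p = p,
                 source = "replicator")
}

new_trajectory <- function(tbl, converged, final_p, source, seed = NULL,
                           N = NULL) {
  structure(tbl, class = c("sens_trajectory", class(tbl)),
            converged = converged, final_p = final_p, source = source,
            seed = seed, N = N)
}

#' Simulate a frequency-dependent Moran process
#'
#' Finite-population stochastic counterpart of the replicator dynamics. The
#' population holds `N` individuals; at each elementary step one individual
#' is chosen to reproduce with probability proportional to
#' `exp(intensity * payoff)` (the exponential mapping keeps fitness positive
#' for negative payoffs such as the hawk's -25), and one uniformly chosen
#' individual dies. Payoffs are the expected payoffs at the current
#' frequency, re-evaluated every step. One recorded generation is `N`
#' elementary steps. Without mutation the boundaries are absorbing; an
#' optional symmetric mutation rate flips the type of the offspring.
#'
#' @param game A [static_game()].
#' @param N Population size (>= 2).
#' @param p0 Initial focal frequency; `N * p0` is rounded to a count with a
#'   warning if not already integral.
#' @param generations Number of generations to simulate (> 0).
#' @param intensity Selection intensity of the exponential payoff-to-fitness
#'   mapping, default 0.1.
#' @param seed Integer RNG seed (required; the run is bit-reproducible).
#' @param mutation_rate Per-birth symmetric mutation probability, default 0.
#' @return A tibble of class `sens_trajectory` (one row per generation,
#'   including generation 0) with attributes `final_p`, `seed`, `N`,
#'   `source = "moran"`.
#' @export
simulate_moran <- function(game, N, p0, generations, intensity = 0.1,
                           seed, mutation_rate = 0) {
  stopifnot(inherits(game, "static_game"))
  check_probability(p0, "p0")
  if (!is.numeric(N) || N < 2) abort_config("`N` must be at least 2")
  if (!is.numeric(generations) || generations <= 0) {
    abort_config("`generations` must be positive")
  }
  if (intensity < 0) abort_config("`intensity` must be non-negative")
  check_probability(mutation_rate, "mutation_rate")
  if (missing(seed) || is.null(seed)) abort_config("`seed` is required")
  N <- as.integer(N)
  generations <- as.integer(generations)

  i0 <- N * p0
  if (abs(i0 - round(i0)) > 1e-9) {
    rlang::warn(sprintf("N * p0 = %g is not an integer; rounding to %d",
                        i0, round(i0)))
  }
  i0 <- as.integer(round(i0))

  # payoffs only depend on p = i/N: precompute lookup tables for i = 0..N
  pgrid <- seq(0L, N) / N
  ev <- expected_payoffs(game, pgrid)

  set.seed(seed)
  counts <- moran_chain(ev$ev_focal, ev$ev_other, i0, N, generations,
                        intensity, mutation_rate)
  idx <- counts + 1L
  out <- tibble::tibble(
    t = seq(0L, generations), p = counts / N,
    ev_focal = ev$ev_focal[idx], ev_other = ev$ev_other[idx],
    mean_payoff = (counts / N) * ev$ev_focal[idx] +
      (1 - counts / N) * ev$ev_other[idx])
  new_trajectory(out, converged = NA, final_p = counts[length(counts)] / N,
                 source = "moran", seed = seed, N = N)
}
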