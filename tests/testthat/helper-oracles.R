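# Independent oracles used across the suite.

# Expected Hawk-Dove cells by enumerating both outcomes of each symmetric
# contest at equal probability and averaging (independent of the package's
# constructor arithmetic).
enumerate_hawk_dove_cells <- function(win, loss, injury, time_cost) {
  hh <- mean(c(win, injury))                       # fight: win or be injured
  dd <- mean(c(win + time_cost, loss + time_cost)) # posture: both waste time
  list(hawk_hawk = hh, hawk_dove = win, dove_hawk = loss, dove_dove = dd)
}

# Independent grid-scan root of the payoff-gap sign change, written against
# expected_payoffs() only (not mixed_equilibrium()).
scan_root_oracle <- function(game, step = 1e-3, tol = 1e-12) {
  grid <- seq(0, 1, by = step)
  gap <- payoff_gap(game, grid)
  flips <- which(sign(gap[-1]) * sign(gap[-length(gap)]) < 0)
  vapply(flips, function(i) {
    stats::uniroot(function(q) payoff_gap(game, q),
                   lower = grid[i], upper = grid[i + 1], tol = tol)$root
  }, numeric(1))
}

# Closed-form interior equilibrium of the constant-fitness cooperation game.
closed_form_p_star <- function(g) {
  (g$d_m - g$d_n) / ((g$d_m - g$d_n) + (g$f_n - g$f_m))
}

default_abm_config <- function(seed = 1L, ...) {
  encounter_config(seed = seed, ...)
}
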