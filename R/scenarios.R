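#' Draw random valid parameter sets
#'
#' Fixture generator for property-style testing: draws parameter blocks
#' uniformly within documented ranges, by construction satisfying every
#' invariant of the requested form, reproducibly for a given seed.
#'
#' Ranges:
#' * `hawk_dove` — `win` U(10, 100), `loss` U(0, win), `injury`
#'   U(loss - 150, loss - 10), `time_cost` U(-20, 0).
#' * `migraine_general` — `d_n` U(0.6, 0.95); the three gaps `d_m - d_n`,
#'   `f_m - d_m`, `f_n - f_m` each U(0.05, 0.25); `d_m_prime`
#'   U(max(0, d_n - 0.3), d_n) (so `d_m_prime < d_n < d_m` by default).
#' * `migraine_printed` — `c_n` U(0.05, 0.4), `c_m = c_n +` U(0.02, 0.4),
#'   `d_m_prime` U(0, (1 - c_m) - 0.01) (so `1 - d_m_prime > c_m`).
#'
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @param form One of `"hawk_dove"`, `"migraine_general"`,
#'   `"migraine_printed"`.
#' @param n Number of parameter sets to draw.
#' @return For `n = 1` a single parameter object ([contest_rules()],
#'   [generalized_game()] or [migraine_params()]); otherwise a list of them.
#' @export
#' @examples
#' generate_random_scenario(seed = 1, form = "migraine_general")
generate_random_scenario <- function(seed = NULL,
                                     form = c("hawk_dove", "migraine_general",
                                              "migraine_printed"),
                                     n = 1L) {
  form <- match.arg(form)
  if (!is.null(seed)) set.seed(seed)
  draw_one <- switch(
    form,
    hawk_dove = function() {
      win <- stats::runif(1, 10, 100)
      loss <- stats::runif(1, 0, win)
      injury <- stats::runif(1, loss - 150, loss - 10)
      contest_rules(win, loss, injury, stats::runif(1, -20, 0))
    },
    migraine_general = function() {
      d_n <- stats::runif(1, 0.6, 0.95)
      d_m <- d_n + stats::runif(1, 0.05, 0.25)
      f_m <- d_m + stats::runif(1, 0.05, 0.25)
      f_n <- f_m + stats::runif(1, 0.05, 0.25)
      generalized_game(f_n, f_m, d_m, d_n,
                       d_m_prime = stats::runif(1, max(0, d_n - 0.3), d_n))
    },
    migraine_printed = function() {
      c_n <- stats::runif(1, 0.05, 0.4)
      c_m <- c_n + stats::runif(1, 0.02, 0.4)
      migraine_params(c_m, c_n,
                      d_m_prime = stats::runif(1, 0, 1 - c_m - 0.01))
    })
  out <- replicate(n, draw_one(), simplify = FALSE)
  if (n == 1L) out[[1]] else out
}
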