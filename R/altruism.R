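#' Configuration of the reciprocal-altruism encounter simulation
#'
#' Sets up the agent-based model of the exchange between migraineurs and
#' non-migraineurs: migraineurs detect predators early and warn their partner
#' at a personal cost; in return, a non-migraineur rescues a migraineur caught
#' mid-attack when a predator appears. The three classic preconditions of
#' reciprocal altruism — repeated interaction, individual recognition, and
#' memory of past behaviour — are independent toggles so each can be knocked
#' out ([condition_knockout()]).
#'
#' Fitness bookkeeping is additive per event, measured relative to the
#' no-agreement floors: a migraineur who is never rescued sits at the
#' betrayal level `d_m'` and a non-migraineur who is never warned sits at
#' `d_n`, both encoded as zero change. A warning moves `b_n` to the partner
#' at cost `c_m`; a rescue moves `b_m` to the migraineur at cost `c_n`
#' (costs and benefits from [derive_costs_benefits()] of `game`).
#'
#' @param n_agents Number of agents (>= 2), default 40.
#' @param p0 Initial migraineur fraction, default 0.5.
#' @param n_rounds Number of pairing rounds, default 2000.
#' @param predator_prob Per-pair per-round probability a predator appears,
#'   default 0.2.
#' @param attack_prob Probability a migraineur is mid-attack when the
#'   predator appears, default 0.3.
#' @param defect_prob Probability a non-migraineur betrays instead of
#'   rescuing, default 0.
#' @param agreement Is the mutual-help agreement in force? Default `TRUE`.
#' @param repeat_interaction,recognition,memory The three precondition
#'   toggles, all default `TRUE`. With `repeat_interaction = FALSE` the
#'   simulation runs a single round; with `recognition = FALSE` repayment is
#'   delivered to a uniformly random agent; with `memory = FALSE` debts are
#'   not recorded so repayment never happens (and warnings are not
#'   credit-capped).
#' @param game A [generalized_game()] supplying the payoff scale; default
#'   `generalized_game(1.2, 1.1, 1.0, 0.9, d_m_prime = 0.5)`.
#' @param seed Integer RNG seed (required for reproducibility).
#' @return An object of class `encounter_config`.
#' @export
encounter_config <- function(n_agents = 40, p0 = 0.5, n_rounds = 2000,
                             predator_prob = 0.2, attack_prob = 0.3,
                             defect_prob = 0, agreement = TRUE,
                             repeat_interaction = TRUE, recognition = TRUE,
                             memory = TRUE,
                             game = generalized_game(1.2, 1.1, 1.0, 0.9,
                                                     d_m_prime = 0.5),
                             seed = 1L) {
  if (!is.numeric(n_agents) || n_agents < 2) {
    abort_config("`n_agents` must be at least 2")
  }
  check_probability(p0, "p0")
  if (!is.numeric(n_rounds) || n_rounds < 1) {
    abort_config("`n_rounds` must be at least 1")
  }
  check_probability(predator_prob, "predator_prob")
  check_probability(attack_prob, "attack_prob")
  check_probability(defect_prob, "defect_prob")
  stopifnot(inherits(game, "generalized_game"))
  cb <- derive_costs_benefits(game)
  structure(
    list(n_agents = as.integer(n_agents), p0 = p0,
         n_rounds = as.integer(n_rounds),
         predator_prob = predator_prob, attack_prob = attack_prob,
         defect_prob = defect_prob, agreement = isTRUE(agreement),
         repeat_interaction = isTRUE(repeat_interaction),
         recognition = isTRUE(recognition), memory = isTRUE(memory),
         game = game, costs = cb, seed = as.integer(seed)),
    class = "encounter_config")
}

#' @export
print.encounter_config <- function(x, ...) {
  cat("<encounter_config>\n")
  cat(sprintf("  %d agents (p0 = %g), %d rounds, seed %d\n",
              x$n_agents, x$p0, x$n_rounds, x$seed))
  cat(sprintf("  predator %g, attack %g, defect %g; agreement %s\n",
              x$predator_prob, x$attack_prob, x$defect_prob, x$agreement))
  cat(sprintf("  conditions: repeat %s, recognition %s, memory %s\n",
              x$repeat_interaction, x$recognition, x$memory))
  cat(sprintf("  payoffs: b_m = %g, c_m = %g, b_n = %g, c_n = %g\n",
              x$costs$b_m, x$costs$c_m, x$costs$b_n, x$costs$c_n))
  invisible(x)
}

#' Initialise the agent population
#'
#' Creates `round(n_agents * p0)` migraineurs and the remainder
#' non-migraineurs, all at zero cumulative fitness, and seeds the RNG so the
#' subsequent pairing order is reproducible.
#'
#' @param config An [encounter_config()].
#' @return A tibble with columns `id`, `phenotype`, `fitness`.
#' @export
#' @examples
#' init_population(encounter_config(n_agents = 100, p0 = 0.14))
init_population <- function(config) {
  stopifnot(inherits(config, "encounter_config"))
  n <- config$n_agents
  n_m <- as.integer(round(n * config$p0))
  set.seed(config$seed)
  tibble::tibble(
    id = seq_len(n),
    phenotype = c(rep("migraineur", n_m),
                  rep("non_migraineur", n - n_m)),
    fitness = 0)
}

#' Simulate the reciprocal-altruism encounters
#'
#' Each round the agents are paired uniformly at random without replacement
#' (one agent sits out when `n_agents` is odd). With probability
#' `predator_prob` a predator threatens a pair. In a mixed pair under the
#' agreement:
#'
#' * the migraineur, when *not* mid-attack (probability `1 - attack_prob`),
#'   warns the partner: the migraineur pays `c_m`, the non-migraineur gains
#'   `b_n`, and (memory on) a repayment debt is recorded. A migraineur
#'   extends at most one open debt per partner, so credit and repayment
#'   balance over time; a partner remembered as a repeat betrayer (two or
#'   more betrayals) is no longer warned.
#' * the migraineur, when mid-attack, needs rescue. Repayment requires an
#'   open debt (memory on). The non-migraineur betrays with probability
#'   `defect_prob`, leaving the migraineur at the betrayal level (zero
#'   change); otherwise the non-migraineur pays `c_n` and the migraineur
#'   gains `b_m` (recognition on) — with recognition off the help is
#'   delivered to a uniformly random agent instead, benefiting a migraineur
#'   only by chance.
#'
#' Same-phenotype pairs exchange nothing: two migraineurs each detect the
#' danger themselves, two non-migraineurs each sit at their baseline.
#' Without the agreement no warning or rescue ever occurs, so both
#' phenotypes stay locked at their floors (`d_m'` and `d_n` levels; zero
#' recorded change).
#'
#' @param config An [encounter_config()]. `agreement = TRUE` requires
#'   `b_m - c_m > 0` and `b_n - c_n > 0`; otherwise the run is refused.
#' @return An object of class `encounter_sim`: list with `ledger` (tibble
#'   `round`, `agent_id`, `partner_id`, `event`, `delta_fitness`),
#'   `trajectory` (tibble of per-round cumulative mean fitness by
#'   phenotype), `agents` (final population tibble), `summary` (per-phenotype
#'   mean per-round fitness), and `config`.
#' @export
simulate_encounters <- function(config) {
  stopifnot(inherits(config, "encounter_config"))
  cb <- config$costs
  if (config$agreement && (!cb$bm_positive || !cb$bn_positive)) {
    abort_validation(
      "agreement requires b_m - c_m > 0 and b_n - c_n > 0",
      invariant = "b_m - c_m > 0, b_n - c_n > 0")
  }
  n_rounds <- if (config$repeat_interaction) config$n_rounds else 1L
  agents <- init_population(config)  # also seeds the RNG
  n <- config$n_agents
  is_m <- agents$phenotype == "migraineur"
  fitness <- agents$fitness
  b_m <- cb$b_m; c_m <- cb$c_m; b_n <- cb$b_n; c_n <- cb$c_n

  # debts[m, n] = open warning credits m holds against n;
  # betrayals[m, n] = times n betrayed m (>= 2 severs warnings to n)
  debts <- matrix(0L, n, n)
  betrayals <- matrix(0L, n, n)

  led_round <- integer(0); led_agent <- integer(0); led_partner <- integer(0)
  led_event <- character(0); led_delta <- numeric(0)
  log_event <- function(round, agent, partner, event, delta) {
    led_round[[length(led_round) + 1L]] <<- round
    led_agent[[length(led_agent) + 1L]] <<- agent
    led_partner[[length(led_partner) + 1L]] <<- partner
    led_event[[length(led_event) + 1L]] <<- event
    led_delta[[length(led_delta) + 1L]] <<- delta
    fitness[[agent]] <<- fitness[[agent]] + delta
  }

  n_pairs <- n %/% 2L
  mean_m <- mean_n <- numeric(n_rounds)

  for (round in seq_len(n_rounds)) {
    perm <- sample.int(n)
    a_side <- perm[seq_len(n_pairs)]
    b_side <- perm[n_pairs + seq_len(n_pairs)]
    predator <- stats::runif(n_pairs) < config$predator_prob
    if (config$agreement) {
      for (k in which(predator)) {
        a <- a_side[k]; b <- b_side[k]
        if (is_m[a] == is_m[b]) next  # same phenotype: no exchange
        m <- if (is_m[a]) a else b
        nn <- if (is_m[a]) b else a
        in_attack <- stats::runif(1) < config$attack_prob
        if (!in_attack) {
          # warning path, credit-capped per partner when memory is on
          can_warn <- if (config$memory) {
            debts[m, nn] == 0L && betrayals[m, nn] < 2L
          } else TRUE
          if (can_warn) {
            log_event(round, m, nn, "warn", -c_m)
            log_event(round, nn, m, "warned", b_n)
            if (config$memory) debts[m, nn] <- debts[m, nn] + 1L
          }
        } else {
          # rescue path: requires a remembered debt
          owed <- config$memory && debts[m, nn] > 0L
          if (owed) {
            if (stats::runif(1) < config$defect_prob) {
              log_event(round, m, nn, "betrayed", 0)
              log_event(round, nn, m, "defected", 0)
              betrayals[m, nn] <- betrayals[m, nn] + 1L
            } else if (config$recognition) {
              log_event(round, nn, m, "rescue_given", -c_n)
              log_event(round, m, nn, "rescued", b_m)
              debts[m, nn] <- debts[m, nn] - 1L
            } else {
              # repayment cannot be targeted: random recipient
              target <- sample.int(n, 1L)
              log_event(round, nn, m, "rescue_given", -c_n)
              if (is_m[target]) {
                log_event(round, target, nn, "rescued_misdirected", b_m)
                if (debts[target, nn] > 0L) {
                  debts[target, nn] <- debts[target, nn] - 1L
                }
              } else {
                log_event(round, target, nn, "help_wasted", 0)
              }
            }
          }
        }
      }
    }
    mean_m[round] <- mean(fitness[is_m])
    mean_n[round] <- mean(fitness[!is_m])
  }

  ledger <- tibble::tibble(
    round = led_round, agent_id = led_agent, partner_id = led_partner,
    event = led_event, delta_fitness = led_delta)
  agents$fitness <- fitness
  trajectory <- tibble::tibble(
    round = seq_len(n_rounds),
    mean_fitness_migraineur = mean_m,
    mean_fitness_non_migraineur = mean_n)
  summary <- tibble::tibble(
    phenotype = c("migraineur", "non_migraineur"),
    n_agents = c(sum(is_m), sum(!is_m)),
    mean_fitness = c(mean(fitness[is_m]), mean(fitness[!is_m])),
    mean_per_round = c(mean(fitness[is_m]), mean(fitness[!is_m])) / n_rounds)
  structure(
    list(ledger = ledger, trajectory = trajectory, agents = agents,
         summary = summary, config = config, n_rounds_run = n_rounds),
    class = "encounter_sim")
}

#' @export
print.encounter_sim <- function(x, ...) {
  cat(sprintf("<encounter_sim> %d agents, %d rounds, %d ledger events\n",
              x$config$n_agents, x$n_rounds_run, nrow(x$ledger)))
  print(x$summary)
  invisible(x)
}

#' Knock out each precondition of reciprocal altruism
#'
#' Reruns [simulate_encounters()] with each of the three preconditions —
#' repeated interaction, individual recognition, and memory of past
#' behaviour — disabled in turn, and reports the migraineur's mean per-round
#' fitness under each knockout against the full configuration. Disabling any
#' one of them prevents targeted repayment, so the migraineur's return on
#' warning collapses.
#'
#' @param config An [encounter_config()] with `agreement = TRUE`.
#' @return A tibble with columns `condition` (`"none"` for the full
#'   configuration), `mean_per_round_migraineur`,
#'   `mean_per_round_non_migraineur`, `drop_migraineur` (full minus
#'   knockout).
#' @export
condition_knockout <- function(config) {
  stopifnot(inherits(config, "encounter_config"))
  if (!config$agreement) {
    abort_config("condition_knockout requires agreement = TRUE")
  }
  run_with <- function(...) {
    cfg <- config
    mods <- list(...)
    cfg[names(mods)] <- mods
    sim <- simulate_encounters(cfg)
    sm <- sim$summary
    c(m = sm$mean_per_round[sm$phenotype == "migraineur"],
      n = sm$mean_per_round[sm$phenotype == "non_migraineur"])
  }
  full <- run_with()
  rows <- list(
    none = full,
    repeat_interaction = run_with(repeat_interaction = FALSE),
    recognition = run_with(recognition = FALSE),
    memory = run_with(memory = FALSE))
  tibble::tibble(
    condition = names(rows),
    mean_per_round_migraineur = unname(vapply(rows, `[[`, numeric(1), "m")),
    mean_per_round_non_migraineur = unname(vapply(rows, `[[`, numeric(1), "n")),
    drop_migraineur = full[["m"]] -
      unname(vapply(rows, `[[`, numeric(1), "m")))
}
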