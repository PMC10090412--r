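# Configuration I/O: JSON (read/write) and YAML (read-only) run
# configurations, schema validation with JSON-path error messages, and
# deterministic output writers that embed the config hash and seed.

config_defaults <- function() {
  list(
    dynamics = list(p0 = 0.5, dt = 0.01, t_max = 1e4, tol = 1e-8,
                    N = 1000L, generations = 500L, intensity = 0.1,
                    mutation_rate = 0),
    seed = 1L,
    log_level = "info")
}

config_schema <- function() {
  list(
    subcommand = "character",
    game = "character",
    contest_rules = list(win_value = "numeric", loss_value = "numeric",
                         injury_value = "numeric", time_cost = "numeric"),
    migraine_params = list(c_m = "numeric", c_n = "numeric",
                           d_m_prime = "numeric"),
    generalized_game = list(f_n = "numeric", f_m = "numeric",
                            d_m = "numeric", d_n = "numeric",
                            d_m_prime = "numeric"),
    dynamics = list(p0 = "numeric", dt = "numeric", t_max = "numeric",
                    tol = "numeric", N = "numeric", generations = "numeric",
                    intensity = "numeric", mutation_rate = "numeric"),
    abm = list(n_agents = "numeric", p0 = "numeric", n_rounds = "numeric",
               predator_prob = "numeric", attack_prob = "numeric",
               defect_prob = "numeric", agreement = "logical",
               repeat_interaction = "logical", recognition = "logical",
               memory = "logical"),
    sweep = list(parameter = "character", from = "numeric", to = "numeric",
                 steps = "numeric", values = "numeric"),
    seed = "numeric",
    out = "character",
    log_level = "character")
}

check_block <- function(value, schema, path) {
  if (is.character(schema)) {
    ok <- switch(schema,
                 numeric = is.numeric(value),
                 character = is.character(value),
                 logical = is.logical(value))
    if (!isTRUE(ok)) {
      abort_config(sprintf("field must be of type %s", schema),
                   json_path = path)
    }
    return(invisible(TRUE))
  }
  if (!is.list(value)) {
    abort_config("field must be a JSON object", json_path = path)
  }
  extra <- setdiff(names(value), names(schema))
  if (length(extra) > 0) {
    abort_config(sprintf("unknown field '%s'", extra[1]),
                 json_path = paste0(path, ".", extra[1]))
  }
  for (nm in names(value)) {
    check_block(value[[nm]], schema[[nm]], paste0(path, ".", nm))
  }
  invisible(TRUE)
}

#' Load and validate a run configuration
#'
#' Reads a JSON (or, read-only, YAML) configuration file, rejects unknown
#' keys, type-checks every field against the schema (errors name the JSON
#' path of the offending field), fills documented defaults (`dt = 0.01`,
#' `tol = 1e-8`, ...), and validates any parameter block by constructing it
#' (so e.g. `c_m < c_n` fails with the ordering invariant named). Exactly
#' one parameter block (`contest_rules`, `migraine_params` or
#' `generalized_game`) may be present.
#'
#' @param path Path to a `.json` (or `.yaml`/`.yml`) file.
#' @return A named list of class `run_config`, with defaults filled and
#'   `config_hash` attached.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (!is.list(raw)) abort_config("config must be a JSON object", json_path = "$")
  check_block(raw, config_schema(), "$")

  blocks <- intersect(names(raw),
                      c("contest_rules", "migraine_params", "generalized_game"))
  if (length(blocks) > 1) {
    abort_config("exactly one parameter block is allowed",
                 json_path = paste0("$.", blocks[2]))
  }
  # construct to validate; constructor errors are re-raised with the path
  if (length(blocks) == 1) {
    ctor <- switch(blocks, contest_rules = contest_rules,
                   migraine_params = migraine_params,
                   generalized_game = generalized_game)
    tryCatch(do.call(ctor, raw[[blocks]]),
             sensgame_validation_error = function(e) {
               abort_validation(conditionMessage(e), invariant = e$invariant,
                                json_path = paste0("$.", blocks))
             })
  }

  defaults <- config_defaults()
  cfg <- utils::modifyList(defaults, raw)
  # modifyList merges nested lists, giving block-level defaults for dynamics
  cfg$seed <- as.integer(cfg$seed)
  attr(cfg, "config_hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration back to JSON
#'
#' Inverse of [load_config()]: serialises the configuration so that
#' `load_config(write_config(cfg, f))` reproduces an equal configuration.
#'
#' @param config A `run_config` (or plain named list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  attr(x, "config_hash") <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

fmt12 <- function(x) {
  if (is.numeric(x)) sprintf("%.12g", x) else as.character(x)
}

#' Write a result object to disk
#'
#' Equilibrium results and identity diagnostics are written as JSON;
#' trajectories, encounter ledgers and sweep tables as CSV with numbers at
#' 12 significant digits. Every file embeds the configuration hash and the
#' seed (JSON fields, or `#`-prefixed header comments for CSV), so a run can
#' be reproduced exactly and determinism audited byte-for-byte.
#'
#' @param result An `ess_result`, `identity_diagnostic`, `sens_trajectory`,
#'   `encounter_sim` (its ledger is written), or `sens_sweep`.
#' @param path Output file path.
#' @param seed Integer seed to record.
#' @param config Optional configuration object to hash into the file.
#' @return `path`, invisibly.
#' @export
write_outputs <- function(result, path, seed = NA_integer_, config = NULL) {
  hash <- if (is.null(config)) NA_character_ else config_hash(unclass(config))
  if (inherits(result, "ess_result")) {
    payload <- list(
      seed = seed, config_hash = hash, status = result$status,
      p_star = result$p_star, payoff_at_eq = result$payoff_at_eq,
      stable = result$stable, focal_label = result$focal_label,
      roots = result$roots)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(path))
  }
  if (inherits(result, "identity_diagnostic")) {
    payload <- list(seed = seed, config_hash = hash,
                    diagnostic = as.data.frame(result))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(path))
  }
  tbl <- if (inherits(result, "encounter_sim")) result$ledger else result
  if (!is.data.frame(tbl)) {
    rlang::abort("unsupported result type", class = "sensgame_io_error")
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) {
                    rlang::abort(sprintf("cannot write to '%s'", path),
                                 class = "sensgame_io_error")
                  })
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# config_hash: %s", hash), con)
  writeLines(sprintf("# seed: %s", seed), con)
  writeLines(paste(names(tbl), collapse = ","), con)
  cols <- lapply(tbl, fmt12)
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}
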