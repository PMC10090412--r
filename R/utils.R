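# Internal validation helpers. All user-facing validation failures signal a
# condition of class "sensgame_validation_error" carrying the violated
# invariant (and, for config files, the JSON path of the offending field).

abort_validation <- function(message, invariant = NULL, json_path = NULL) {
  if (!is.null(json_path)) {
    message <- sprintf("%s (at %s)", message, json_path)
  }
  rlang::abort(message, class = "sensgame_validation_error",
               invariant = invariant, json_path = json_path)
}

abort_config <- function(message, json_path = NULL) {
  if (!is.null(json_path)) {
    message <- sprintf("%s (at %s)", message, json_path)
  }
  rlang::abort(message, class = "sensgame_config_error", json_path = json_path)
}

check_probability <- function(p, name = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    rlang::abort(sprintf("`%s` must lie in [0, 1]", name),
                 class = "sensgame_domain_error")
  }
  invisible(p)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_config(sprintf("`%s` must be a single positive number", name))
  }
  invisible(x)
}

# Canonical hash of an R configuration object: names are sorted recursively,
# the object is serialised to JSON, and the md5 of that text is returned.
config_hash <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v)) && any(nzchar(names(v)))) {
        v <- v[order(names(v))]
      }
      lapply(v, canon)
    } else v
  }
  txt <- jsonlite::toJSON(canon(x), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(txt), tf)
  unname(tools::md5sum(tf))
}
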