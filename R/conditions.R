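# Condition system shared by all modules.
#
# Three error classes map onto the CLI exit codes:
#   pcptiles_input_error    -> exit 2  (malformed data / unreadable files)
#   pcptiles_config_error   -> exit 3  (bad flags, unknown keys, invalid options)
#   pcptiles_contract_error -> exit 1  (programming errors: broken preconditions)

stop_input <- function(msg, ...) {
  stop(structure(
    class = c("pcptiles_input_error", "pcptiles_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_config <- function(msg, ...) {
  stop(structure(
    class = c("pcptiles_config_error", "pcptiles_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_contract <- function(msg, ...) {
  stop(structure(
    class = c("pcptiles_contract_error", "pcptiles_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Timestamped logging to stderr; stdout is reserved for machine output.
.log_level <- function(verbosity) if (isTRUE(verbosity)) "debug" else "info"

log_msg <- function(level = "info", msg, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  toupper(level), sprintf(msg, ...)))
}

# Evaluate expr under a private RNG state so generators never disturb the
# caller's random stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
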