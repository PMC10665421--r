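# Internal helpers: seed streams, config hashing, validation messages.

#' Derive a per-stage seed from the master seed
#'
#' All randomness in the pipeline flows from one master seed through named
#' streams, so each stage (population synthesis, tibia residuals, cohort
#' draws) is reproducible in isolation. The derived seed is kept below
#' 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param stream one of `"population"`, `"tibia"`, `"mechanics"`,
#'   `"algorithm_a"`, `"algorithm_b"`.
#' @return An integer seed.
#' @export
stream_seed <- function(master, stream) {
  offsets <- c(
    population = 1, tibia = 2, mechanics = 3,
    algorithm_a = 4, algorithm_b = 5
  )
  if (!stream %in% names(offsets)) {
    stop("unknown seed stream: ", stream, call. = FALSE)
  }
  # multiplicative spreading mod the Mersenne prime 2^31 - 1 (fits in double)
  as.integer((abs(as.numeric(master)) + offsets[[stream]] * 97561) %% 2147483647)
}

# Small deterministic hash of the configuration for the run manifest.
# Polynomial rolling hash over the serialized object; not cryptographic,
# only used to detect config drift between runs.
config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

# stop() with the offending config field in the message
abort_config <- function(field, msg) {
  stop(sprintf("invalid configuration: %s %s", field, msg), call. = FALSE)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(name, " must be a positive finite number", call. = FALSE)
  }
  invisible(x)
}
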