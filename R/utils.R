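# Internal helpers shared across the package.

# Physical constants (SI). Potentials elsewhere are millivolts vs SHE;
# conversion to volts happens only inside Gibbs-energy computations.
.R_GAS <- 8.314      # J mol^-1 K^-1
.FARADAY <- 96485    # C mol^-1
.R_KCAL <- 1.9872e-3 # kcal mol^-1 K^-1

#' @noRd
abort_invalid <- function(msg, class = "aptaredox_invalid_input") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
abort_usage <- function(msg) {
  abort_invalid(msg, class = c("aptaredox_usage_error", "aptaredox_invalid_input"))
}

#' Check a scalar is a finite number
#' @noRd
check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_invalid(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    abort_invalid(sprintf("`%s` must be > 0 (got %g)", name, x))
  }
  if (nonneg && x < 0) {
    abort_invalid(sprintf("`%s` must be >= 0 (got %g)", name, x))
  }
  invisible(x)
}

# Run `expr` under a given RNG seed without disturbing the caller's RNG
# state. `seed = NULL` leaves the RNG alone.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  check_number(seed, "seed")
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Stable hash of an R object for provenance records (md5 of its
# canonical JSON serialisation).
#' @noRd
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' @noRd
log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  paste0(...)))
}
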