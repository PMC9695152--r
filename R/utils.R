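# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_insufficient_data <- function(msg) {
  stop(errorCondition(msg, class = c("phototherm_insufficient_data", "error")))
}

stop_argument <- function(msg) {
  stop(errorCondition(msg, class = c("phototherm_argument_error", "error")))
}

stop_calibration <- function(msg) {
  stop(errorCondition(msg, class = c("phototherm_calibration_error", "error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
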