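# Internal helpers shared across modules.

#' Evaluate an expression with a temporarily seeded RNG
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that seeded package operations never disturb the user's
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Classed error constructor: every condition raised by the package carries a
# subclass so callers can distinguish, e.g., "eegbci_not_ready" from a crash.
eegbci_stop <- function(subclass, message, ...) {
  stop(errorCondition(message, ..., class = c(subclass, "eegbci_error")))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    eegbci_stop("eegbci_bad_argument", sprintf("`%s` must be a single number", name))
  }
  if (positive && x <= 0) {
    eegbci_stop("eegbci_bad_argument", sprintf("`%s` must be positive", name))
  }
  invisible(x)
}
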