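# Structured error conditions. Every user-facing failure mode has its own
# condition class so callers (and the CLI) can dispatch on it:
#   gait_format_error       malformed input file (wrong header, non-numeric)
#   gait_data_error         well-formed but unusable data (short span, NaN, ...)
#   gait_parameter_error    invalid user-supplied parameter
#   gait_contract_error     precondition between pipeline stages violated
#   gait_degenerate_error   degenerate signal/covariance (all-zero, singular)
#   gait_no_periodicity_error    no cadence peak in the search band
#   gait_insufficient_steps_error  too few detected steps for variability
abort_gait <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "gait_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' @noRd
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is_scalar_number(x)) {
    abort_gait(sprintf("`%s` must be a single finite number", name),
               "gait_parameter_error")
  }
  ok_lo <- if (open_lower) x > lower else x >= lower
  ok_hi <- if (open_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    abort_gait(sprintf(
      "`%s` = %g outside %s%g, %g%s", name, x,
      if (open_lower) "(" else "[", lower, upper,
      if (open_upper) ")" else "]"
    ), "gait_parameter_error")
  }
  invisible(x)
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators do not disturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}
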