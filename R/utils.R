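# Internal helpers shared across modules.

# Classed conditions so callers can distinguish failure modes
# (design-deficient data, schema errors, ...) without string matching.
nk_stop <- function(message, class) {
  stop(errorCondition(message, class = c(class, "nitrokin_error", "error")))
}

nk_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "nitrokin_warning", "warning")))
}

# 10^e with the exponent clamped to +/-300 decades.  Keeps Nernst terms
# finite for potentials anywhere within +/- tens of volts of a midpoint;
# the clamp is far outside any fitting or plotting range so it never
# changes a result there.
pow10 <- function(e) 10^pmin(pmax(e, -300), 300)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    nk_stop(sprintf("'%s' must be a single number", name),
            "nitrokin_parameter_error")
  }
  if (!allow_inf && !is.finite(x)) {
    nk_stop(sprintf("'%s' must be finite", name), "nitrokin_parameter_error")
  }
  if (positive && !(x > 0)) {
    nk_stop(sprintf("'%s' must be strictly positive", name),
            "nitrokin_parameter_error")
  }
  if (nonneg && x < 0) {
    nk_stop(sprintf("'%s' must be non-negative", name),
            "nitrokin_parameter_error")
  }
  invisible(x)
}

check_conc <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    nk_stop(sprintf("'%s' must be finite numeric", name),
            "nitrokin_input_error")
  }
  if (any(x < 0)) {
    nk_stop(sprintf("negative values in '%s': concentrations must be >= 0",
                    name), "nitrokin_input_error")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
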