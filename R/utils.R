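#' @keywords internal
"_PACKAGE"

# Shared argument checks used across modules. All errors are classed so tests
# can assert on condition class rather than message text.

stop_mm <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "micromendr_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

warn_mm <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "micromendr_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_mm("invalid_argument", "`%s` must be a single number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_mm("invalid_argument", "`%s` = %g is outside its allowed range", name, x)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_mm("invalid_argument", "`%s` must be an integer >= %d", name, min)
  as.integer(x)
}

# Quantile-matched seed stream: derive reproducible child seeds from one
# master seed without consuming the caller's RNG state unpredictably.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(index) * 1013) %%
               2147483629)
}
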