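# internal helpers shared across modules

# Round to pennies, half away from zero. base::round() rounds half to even,
# which does not match how currency tables are conventionally printed.
round_pennies <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100

# stopifnot-style check with a formatted message
check <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# bounds helpers for uniform-draw configuration entries
check_bounds <- function(b, name, min_allowed = -Inf) {
  check(is.numeric(b) && length(b) == 2L && all(is.finite(b)),
        "'%s' must be a numeric vector of two finite bounds", name)
  check(b[1] <= b[2], "'%s' bounds must satisfy low <= high", name)
  check(b[1] >= min_allowed, "'%s' lower bound must be >= %s", name, min_allowed)
  invisible(TRUE)
}
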