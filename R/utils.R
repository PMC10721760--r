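# Internal validators shared across modules.

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_field(field, "must be a single non-missing number")
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_field(field, sprintf("must lie in %s%s, %s%s",
                              if (strict_lower) "(" else "[", lower, upper,
                              if (strict_upper) ")" else "]"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic lexicographic (C-locale) ordering for ids, so tie-breaks do not
# depend on the session locale.
lex_order <- function(...) {
  keys <- lapply(list(...), function(a) {
    if (is.character(a))
      xtfrm(factor(a, levels = sort(unique(a), method = "radix")))
    else a
  })
  do.call(order, keys)
}

lex_sort <- function(x) sort(x, method = "radix")
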