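# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

# Node identity throughout the package: upper-cased, whitespace-trimmed
# gene symbol (public catalogs mix casings such as IL-6 vs il6).
canon_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

# INFO-level progress log to stderr; every filter reports counts in/out.
log_info <- function(fmt, ...) {
  message(sprintf(paste0("[comorbnet] ", fmt), ...))
}

# Derive a stream-specific sub-seed from a master seed, staying within
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% .Machine$integer.max)
}
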