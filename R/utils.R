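#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov pf pt rexp rnorm runif sd var
#' @importFrom utils head
NULL

# Argument checks used throughout; stop() with the caller's argument name so
# messages point at user-facing functions.

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    stop_invalid(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_invalid(sprintf("`%s` must be a single positive number", name))
  }
  as.numeric(x)
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level != floor(level) || level < 1 || level > 4) {
    stop_invalid("`level` must be an integer between 1 and 4")
  }
  as.integer(level)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(sprintf("`%s` must be TRUE or FALSE", name))
  }
  x
}

# Derive a child seed from a master seed; keeps all derived seeds below
# 2^31 - 1 so they remain valid R integers.
child_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
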