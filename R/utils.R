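#' @keywords internal
"_PACKAGE"

# Shared small helpers. Everything is SI unless a name says otherwise.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("`%s` must be a single positive finite number (got %s)", name,
          paste(format(x), collapse = ", "))
  invisible(x)
}

deg2rad <- function(deg) deg * pi / 180

#' Linear interpolation of a crossing time
#' @noRd
cross_interp <- function(t0, t1, x0, x1, target) {
  if (x1 == x0) return(t0)
  t0 + (target - x0) * (t1 - t0) / (x1 - x0)
}
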