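clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

check_same_shape <- function(a, b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(da, db)) {
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw from a range c(lo, hi)
runif_range <- function(n, range) stats::runif(n, range[1], range[2])

check_range <- function(range, field, lo = -Inf, hi = Inf) {
  if (!is.numeric(range) || length(range) != 2L || range[1] > range[2] ||
      range[1] < lo || range[2] > hi) {
    stop(sprintf("invalid range for `%s`: expected lo <= hi within [%s, %s]",
                 field, format(lo), format(hi)), call. = FALSE)
  }
  invisible(range)
}
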