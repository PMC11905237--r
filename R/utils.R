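# Internal helpers shared across modules. All lengths are millimetres and all
# doses Gray unless a function says otherwise.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_seccheck <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "seccheck_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x))) {
    stop_seccheck(sprintf("'%s' must be a single finite number", name),
                  "seccheck_domain_error")
  }
  if (positive && x <= 0) {
    stop_seccheck(sprintf("'%s' must be > 0 (got %g)", name, x),
                  "seccheck_domain_error")
  }
  invisible(x)
}

# Linear interpolation that is bit-exact at grid nodes.
lin_interp <- function(x, y, xq) {
  i <- match(xq, x)
  if (!is.na(i)) return(y[[i]])
  if (xq < x[1L] || xq > x[length(x)]) {
    stop_seccheck(
      sprintf("query %g outside table range [%g, %g]", xq, x[1L], x[length(x)]),
      "seccheck_range_error"
    )
  }
  stats::approx(x, y, xout = xq, method = "linear", ties = "ordered")$y
}

is_ascending <- function(x) length(x) < 2L || all(diff(x) > 0)
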