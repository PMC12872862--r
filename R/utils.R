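# internal helpers shared across modules

stopf <- function(fmt, ..., class = "pvloopr_error") {
  stop(errorCondition(sprintf(fmt, ...),
                      class = unique(c(class, "pvloopr_error", "error")),
                      call = sys.call(-1)))
}

io_stopf <- function(fmt, ...) stopf(fmt, ..., class = "pvloopr_io_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# uniformity check relative to the mean step
is_uniform_grid <- function(t, tol = 1e-6) {
  if (length(t) < 3) return(TRUE)
  dt <- diff(t)
  max(abs(dt - mean(dt))) <= tol * max(mean(dt), .Machine$double.eps)
}

# monotone Fritsch-Carlson Hermite interpolant: no overshoot beyond knot
# extrema, exact at knots
mono_fun <- function(x, y) stats::splinefun(x, y, method = "monoH.FC")

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("`%s` = %g outside allowed range [%g, %g]", name, x, lower, upper)
  invisible(as.numeric(x))
}
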