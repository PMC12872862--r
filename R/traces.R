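#' Physiological signal containers
#'
#' Light S3 containers for uniformly (or nearly uniformly) sampled signals
#' spanning one cardiac cycle, with the cycle starting at the R wave
#' (t = 0). Loop closure joins the last sample back to the first.
#'
#' @param time numeric vector of sample times in seconds, strictly
#'   increasing, starting at (or near) 0.
#' @param pressure,volume numeric sample values (mmHg, mL).
#' @return An object of class `pressure_trace` or `volume_trace`: a list
#'   with elements `time` and `pressure`/`volume`.
#' @examples
#' v <- volume_trace(seq(0, 0.9, by = 0.005),
#'                   150 - 40 * sin(pi * seq(0, 0.9, by = 0.005) / 0.9)^2)
#' range(v$volume)
#' @name traces
NULL

new_trace <- function(time, value, value_name, cls) {
  if (!is.numeric(time) || !is.numeric(value))
    stopf("time and %s must be numeric", value_name)
  if (length(time) != length(value))
    stopf("time (%d) and %s (%d) differ in length",
          length(time), value_name, length(value))
  bad <- which(!is.finite(time) | !is.finite(value))
  if (length(bad))
    stopf("non-finite value at row %d", bad[1])
  nonmono <- which(diff(time) <= 0)
  if (length(nonmono))
    stopf("time not strictly increasing at row %d (t = %g)",
          nonmono[1] + 1L, time[nonmono[1] + 1L])
  out <- list(time = as.numeric(time))
  out[[value_name]] <- as.numeric(value)
  structure(out, class = cls, uniform = is_uniform_grid(time))
}

#' @rdname traces
#' @export
pressure_trace <- function(time, pressure) {
  out <- new_trace(time, pressure, "pressure", "pressure_trace")
  if (any(out$pressure < 0))
    stopf("pressure must be non-negative (min %g mmHg)", min(out$pressure))
  out
}

#' @rdname traces
#' @export
volume_trace <- function(time, volume) {
  out <- new_trace(time, volume, "volume", "volume_trace")
  if (any(out$volume <= 0))
    stopf("volume must be positive everywhere (min %g mL)", min(out$volume))
  if (max(out$volume) - min(out$volume) <= 0)
    stopf("volume trace is constant; no cycle")
  out
}

#' Segmental strain trace set
#'
#' Strain traces (%) for several myocardial segments on a shared time grid.
#' Strain is re-referenced so every segment starts at 0 at cycle start.
#'
#' @param time shared time grid (s).
#' @param strain numeric matrix, one column per segment (%).
#' @param segment_ids optional character vector of segment names.
#' @return Object of class `strain_traces`.
#' @export
strain_traces <- function(time, strain, segment_ids = NULL) {
  strain <- as.matrix(strain)
  if (!is.numeric(strain)) stopf("strain must be numeric")
  if (nrow(strain) != length(time))
    stopf("strain has %d rows but time has %d samples",
          nrow(strain), length(time))
  if (any(!is.finite(strain))) stopf("strain contains non-finite values")
  segment_ids <- segment_ids %||% colnames(strain) %||%
    sprintf("seg%02d", seq_len(ncol(strain)))
  # reference at cycle start
  strain <- sweep(strain, 2L, strain[1L, ])
  colnames(strain) <- segment_ids
  structure(list(time = as.numeric(time), strain = strain,
                 segment_ids = segment_ids),
            class = "strain_traces", uniform = is_uniform_grid(time))
}

#' Read a trace from CSV
#'
#' Dialects: `time_s,volume_ml`; `time_s,pressure_mmhg`;
#' `time_s,seg01,...,segNN` (strain, %). Comma separated, dot decimal,
#' header required. Column names are not enforced beyond the first column
#' being time; `kind` decides the interpretation.
#'
#' @param path CSV file path.
#' @param kind one of `"volume"`, `"pressure"`, `"strain"`.
#' @return A [volume_trace()], [pressure_trace()] or [strain_traces()].
#'   Non-uniform input is accepted and flagged (attribute `uniform`) for
#'   later [resample()].
#' @export
read_trace <- function(path, kind = c("volume", "pressure", "strain")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) io_stopf("trace file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (ncol(df) < 2L) io_stopf("%s: expected >= 2 columns, got %d", path, ncol(df))
  if (nrow(df) < 10L) io_stopf("%s: expected >= 10 samples, got %d", path, nrow(df))
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]]))
      io_stopf("%s: column %d (%s) is not numeric", path, j, names(df)[j])
    bad <- which(!is.finite(df[[j]]))
    if (length(bad))
      io_stopf("%s: non-finite value in column %s at data row %d",
               path, names(df)[j], bad[1])
  }
  tm <- df[[1]]
  nonmono <- which(diff(tm) <= 0)
  if (length(nonmono))
    io_stopf("%s: time not strictly increasing at data row %d (t = %g)",
             path, nonmono[1] + 1L, tm[nonmono[1] + 1L])
  switch(kind,
    volume   = volume_trace(tm, df[[2]]),
    pressure = pressure_trace(tm, df[[2]]),
    strain   = strain_traces(tm, as.matrix(df[-1]), names(df)[-1]))
}

#' Write a trace to CSV
#'
#' Inverse of [read_trace()], using the package CSV dialects.
#' @param trace a trace object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- if (inherits(trace, "strain_traces")) {
    data.frame(time_s = trace$time, trace$strain, check.names = FALSE)
  } else if (inherits(trace, "pressure_trace")) {
    data.frame(time_s = trace$time, pressure_mmhg = trace$pressure)
  } else if (inherits(trace, "volume_trace")) {
    data.frame(time_s = trace$time, volume_ml = trace$volume)
  } else stopf("unsupported trace class: %s", paste(class(trace), collapse = "/"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Resample a trace onto a uniform grid
#'
#' Monotone piecewise-cubic (Fritsch-Carlson) interpolation onto a uniform
#' grid spanning the same cycle. Endpoints are preserved exactly; the
#' operation is idempotent at a fixed rate, and exact on linear input.
#'
#' @param trace a trace object.
#' @param rate_hz target sampling rate (Hz).
#' @return A trace of the same class on the uniform grid.
#' @export
resample <- function(trace, rate_hz) UseMethod("resample")

resample_grid <- function(time, rate_hz) {
  check_scalar(rate_hz, "rate_hz", lower = 1e-6)
  if (length(time) < 2L) stopf("cannot resample a trace with < 2 samples")
  t0 <- time[1]; t1 <- time[length(time)]
  n <- max(2L, as.integer(round((t1 - t0) * rate_hz)) + 1L)
  seq(t0, t1, length.out = n)
}

#' @export
resample.pressure_trace <- function(trace, rate_hz) {
  g <- resample_grid(trace$time, rate_hz)
  out <- pressure_trace(g, pmax(0, mono_fun(trace$time, trace$pressure)(g)))
  for (a in c("events", "cuff", "mean_gradient", "anchors"))
    attr(out, a) <- attr(trace, a)
  out
}

#' @export
resample.volume_trace <- function(trace, rate_hz) {
  g <- resample_grid(trace$time, rate_hz)
  volume_trace(g, mono_fun(trace$time, trace$volume)(g))
}

#' @export
resample.strain_traces <- function(trace, rate_hz) {
  g <- resample_grid(trace$time, rate_hz)
  s <- vapply(seq_len(ncol(trace$strain)),
              function(j) mono_fun(trace$time, trace$strain[, j])(g),
              numeric(length(g)))
  strain_traces(g, s, trace$segment_ids)
}

#' Synchronize a pressure and a volume trace
#'
#' Places both traces on one shared uniform grid. If the cycle lengths
#' differ by no more than `tol` (fractional), the pressure cycle is
#' linearly rescaled in time to the volume cycle length (the volume trace
#' carries the reference ECG timing); a larger mismatch is an error.
#'
#' @param p a [pressure_trace()].
#' @param v a [volume_trace()].
#' @param tol maximal fractional cycle-length mismatch (default 0.05).
#' @param rate_hz grid rate; default is the volume trace's own rate.
#' @return list with elements `pressure` and `volume` on an identical grid.
#' @export
synchronize <- function(p, v, tol = 0.05, rate_hz = NULL) {
  if (!inherits(p, "pressure_trace") || !inherits(v, "volume_trace"))
    stopf("synchronize() needs a pressure_trace and a volume_trace")
  if (length(p$time) == length(v$time) &&
      max(abs(p$time - v$time)) < 1e-9 && isTRUE(attr(v, "uniform")))
    return(list(pressure = p, volume = v))
  lp <- diff(range(p$time)); lv <- diff(range(v$time))
  if (abs(lp / lv - 1) > tol)
    stopf("cycle-length mismatch beyond tolerance: pressure %.4g s vs volume %.4g s (tol %g)",
          lp, lv, tol, class = "pvloopr_alignment_error")
  rate_hz <- rate_hz %||% ((length(v$time) - 1) / lv)
  g <- seq(0, lv, length.out = max(2L, as.integer(round(lv * rate_hz)) + 1L))
  # shift both cycles to start at 0, rescale pressure time to volume length
  tp <- (p$time - p$time[1]) * (lv / lp)
  tv <- v$time - v$time[1]
  list(
    pressure = pressure_trace(g, pmax(0, mono_fun(tp, p$pressure)(g))),
    volume   = volume_trace(g, mono_fun(tv, v$volume)(g))
  )
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("<pressure_trace> %d samples over %.3f s, %.1f-%.1f mmHg%s\n",
              length(x$time), diff(range(x$time)),
              min(x$pressure), max(x$pressure),
              if (isTRUE(attr(x, "uniform"))) "" else " (non-uniform)"))
  invisible(x)
}

#' @export
print.volume_trace <- function(x, ...) {
  cat(sprintf("<volume_trace> %d samples over %.3f s, %.1f-%.1f mL%s\n",
              length(x$time), diff(range(x$time)),
              min(x$volume), max(x$volume),
              if (isTRUE(attr(x, "uniform"))) "" else " (non-uniform)"))
  invisible(x)
}

#' @export
print.strain_traces <- function(x, ...) {
  cat(sprintf("<strain_traces> %d segments x %d samples over %.3f s\n",
              ncol(x$strain), length(x$time), diff(range(x$time))))
  invisible(x)
}
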