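#' Build a pressure-volume loop
#'
#' Pairs synchronized pressure and volume samples into a closed polygon in
#' the (volume, pressure) plane. Traversal orientation is normalized to
#' counter-clockwise (the physiological direction: isovolumic contraction
#' up the right edge, ejection right to left along the top); the original
#' orientation is recorded.
#'
#' @param p a [pressure_trace()] or numeric pressure vector (mmHg).
#' @param v a [volume_trace()] or numeric volume vector (mL), same length.
#' @param time optional sample times (s); taken from the traces when
#'   available. Used for end-systolic timing and tie-breaking.
#' @return Object of class `pv_loop`: list with `volume`, `pressure`,
#'   `time` (may be `NULL`), attribute `reversed`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 361)[-361]
#' loop <- pv_loop(100 + 50 * sin(th), 100 - 40 * cos(th))
#' loop_area(loop)  # ~ pi * 50 * 40
#' @export
pv_loop <- function(p, v, time = NULL) {
  if (inherits(p, "pressure_trace")) {
    time <- time %||% p$time
    if (inherits(v, "volume_trace") &&
        (length(p$time) != length(v$time) ||
         max(abs(p$time - v$time)) > 1e-9))
      stopf("traces are not on a shared grid; call synchronize() first")
    p <- p$pressure
  }
  if (inherits(v, "volume_trace")) v <- v$volume
  if (length(p) != length(v))
    stopf("pressure (%d) and volume (%d) differ in length", length(p), length(v))
  if (length(p) < 4L) stopf("a loop needs >= 4 vertices, got %d", length(p))
  if (any(v <= 0)) stopf("volume must be positive")
  if (any(p < 0)) stopf("pressure must be non-negative")
  sa <- signed_area(v, p)
  scale <- (max(v) - min(v)) * (max(p) - min(p))
  if (abs(sa) <= 1e-9 * max(scale, .Machine$double.eps))
    stopf("degenerate loop: enclosed area is zero",
          class = "pvloopr_degenerate_loop")
  reversed <- sa < 0
  if (reversed) {
    idx <- rev(seq_along(p))
    p <- p[idx]; v <- v[idx]
    if (!is.null(time)) time <- time[idx]
  }
  structure(list(volume = as.numeric(v), pressure = as.numeric(p),
                 time = time),
            class = "pv_loop", reversed = reversed)
}

# shoelace signed area of the implicitly closed polygon (x = V, y = P);
# positive = counter-clockwise
signed_area <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

#' Stroke work: area enclosed by the PV loop
#'
#' Absolute shoelace area of the closed polygon, in mmHg*mL.
#'
#' @param loop a [pv_loop()].
#' @return enclosed area (mmHg*mL).
#' @export
loop_area <- function(loop) {
  stopifnot(inherits(loop, "pv_loop"))
  abs(signed_area(loop$volume, loop$pressure))
}

#' Locate the end-systolic point on a PV loop
#'
#' The end-systolic point is the vertex in the upper-left region of the
#' loop with the greatest normalized distance from the loop's geometric
#' center: with volume and pressure each min-max normalized to `[0, 1]`
#' and the center taken as the vertex mean, the candidate set is the
#' vertices left of (below in volume) and above (in pressure) the center,
#' and the detected vertex maximizes the Euclidean distance to the center.
#' Ties are broken by earliest time (first vertex in traversal order when
#' no time vector is present).
#'
#' @param loop a [pv_loop()].
#' @return vertex index (integer), with attribute `time` when available.
#' @export
end_systolic_point <- function(loop) {
  stopifnot(inherits(loop, "pv_loop"))
  vh <- norm01(loop$volume); ph <- norm01(loop$pressure)
  cv <- mean(vh); cp <- mean(ph)
  cand <- which(vh < cv & ph > cp)
  if (!length(cand))
    stopf("no vertex in the upper-left region of the loop",
          class = "pvloopr_detection_error")
  d2 <- (vh[cand] - cv)^2 + (ph[cand] - cp)^2
  best <- cand[d2 > max(d2) - 1e-12]
  idx <- if (length(best) > 1L && !is.null(loop$time)) {
    best[which.min(loop$time[best])]
  } else best[1L]
  structure(as.integer(idx),
            time = if (!is.null(loop$time)) loop$time[idx] else NULL)
}

norm01 <- function(x) (x - min(x)) / (max(x) - min(x))

#' Pressure-volume loop metrics
#'
#' Derives the full single-beat metric set from one loop:
#' * `SW` stroke work, the enclosed loop area (mmHg*mL);
#' * `ESP`, `V_es` pressure and volume at the detected end-systolic point;
#' * `Ees = ESP / (V_es - V0)` single-beat end-systolic elastance with the
#'   ESPVR intercept fixed at `V0` (default 0 mL; with `V0 = 0` the value
#'   is a lower bound on the true-intercept elastance);
#' * `EDV = max(volume)`, `ESV = min(volume)`, `SV = EDV - ESV`;
#' * `Ea = ESP / SV` arterial elastance; `VAC = Ea / Ees` coupling;
#' * `PE = 0.5 * ESP * (V_es - V0)` potential energy: the triangle under
#'   the ESPVR line down to the volume axis, with the end-diastolic
#'   relationship taken as zero (the diastolic limb is not modelled);
#' * `PVA = SW + PE`; `efficiency = 100 * SW / PVA` (%);
#' * `ESP_over_EDV`, `Pmax_over_EDV` single-beat contractility indices.
#'
#' @param loop a [pv_loop()].
#' @param v0 ESPVR volume intercept (mL), default 0.
#' @return Object of class `pv_metrics` (named list of scalars).
#' @export
pv_metrics <- function(loop, v0 = 0) {
  stopifnot(inherits(loop, "pv_loop"))
  check_scalar(v0, "v0", lower = 0)
  sw <- loop_area(loop)
  ies <- end_systolic_point(loop)
  esp <- loop$pressure[ies]
  ves <- loop$volume[ies]
  edv <- max(loop$volume); esv <- min(loop$volume)
  sv <- edv - esv
  if (sv <= 0) stopf("non-positive stroke volume", class = "pvloopr_degenerate_loop")
  if (esp <= 0) stopf("non-positive end-systolic pressure",
                      class = "pvloopr_degenerate_loop")
  if (ves <= v0)
    stopf("end-systolic volume %.3g mL <= V0 = %.3g mL", ves, v0,
          class = "pvloopr_degenerate_loop")
  ees <- esp / (ves - v0)
  ea <- esp / sv
  en <- pv_energetics(sw, 0.5 * esp * (ves - v0))
  structure(list(
    SW = sw, PE = en$pe, PVA = en$pva, efficiency = en$efficiency,
    Ees = ees, Ea = ea, VAC = ea / ees,
    ESP = esp, V_es = ves, EDV = edv, ESV = esv, SV = sv,
    ESP_over_EDV = esp / edv,
    Pmax_over_EDV = max(loop$pressure) / edv,
    V0 = v0,
    es_index = unclass(ies)[1L],
    es_time = attr(ies, "time") %||% NA_real_
  ), class = "pv_metrics")
}

#' Loop energetics from stroke work and potential energy
#'
#' The arithmetic shared by [pv_metrics()] and cohort-level summaries:
#' `PVA = SW + PE` by construction and `efficiency = 100 * SW / PVA` (%).
#'
#' @param sw stroke work (mmHg*mL).
#' @param pe potential energy (mmHg*mL).
#' @return list with `sw`, `pe`, `pva`, `efficiency`.
#' @examples
#' pv_energetics(13182, 11374)$pva   # 24556
#' @export
pv_energetics <- function(sw, pe) {
  if (any(sw < 0) || any(pe < 0)) stopf("sw and pe must be non-negative")
  pva <- sw + pe
  list(sw = sw, pe = pe, pva = pva, efficiency = 100 * sw / pva)
}

#' Change between two visits
#'
#' Follow-up minus baseline for every shared numeric element, with the
#' relative change in percent of baseline.
#'
#' @param baseline,followup named numeric vectors, named lists of scalars,
#'   or `pv_metrics` objects.
#' @return data.frame with columns `metric`, `baseline`, `followup`,
#'   `change`, `relative_change_pct`.
#' @export
visit_change <- function(baseline, followup) {
  b <- unlist(baseline); f <- unlist(followup)
  shared <- intersect(names(b), names(f))
  shared <- shared[!shared %in% c("es_index", "es_time", "V0")]
  if (!length(shared)) stopf("no shared metric names between visits")
  data.frame(metric = shared,
             baseline = unname(b[shared]),
             followup = unname(f[shared]),
             change = unname(f[shared] - b[shared]),
             relative_change_pct = unname(100 * (f[shared] - b[shared]) / b[shared]),
             row.names = NULL)
}

#' @export
print.pv_metrics <- function(x, ...) {
  cat("Pressure-volume loop metrics (single beat, V0 =",
      format(x$V0), "mL)\n")
  fmt <- function(v, u) sprintf("%10.4g %s", v, u)
  rows <- c(
    "Stroke work (SW)"          = fmt(x$SW, "mmHg*mL"),
    "Potential energy (PE)"     = fmt(x$PE, "mmHg*mL"),
    "Pressure-volume area"      = fmt(x$PVA, "mmHg*mL"),
    "Ventricular efficiency"    = fmt(x$efficiency, "%"),
    "End-systolic elastance"    = fmt(x$Ees, "mmHg/mL"),
    "Arterial elastance (Ea)"   = fmt(x$Ea, "mmHg/mL"),
    "VA coupling (Ea/Ees)"      = fmt(x$VAC, ""),
    "ESP"                       = fmt(x$ESP, "mmHg"),
    "EDV / ESV / SV"            = sprintf("%.4g / %.4g / %.4g mL",
                                          x$EDV, x$ESV, x$SV),
    "ESP/EDV"                   = fmt(x$ESP_over_EDV, "mmHg/mL"),
    "Pmax/EDV"                  = fmt(x$Pmax_over_EDV, "mmHg/mL"))
  for (nm in names(rows)) cat(sprintf("  %-26s %s\n", nm, rows[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.pv_metrics <- function(x, ...) {
  keep <- setdiff(names(x), c("es_index", "es_time"))
  as.data.frame(unclass(x)[keep], ...)
}

#' @export
plot.pv_loop <- function(x, ..., main = "Pressure-volume loop") {
  graphics::plot(c(x$volume, x$volume[1]), c(x$pressure, x$pressure[1]),
                 type = "l", xlab = "Volume (mL)", ylab = "Pressure (mmHg)",
                 main = main, ...)
  ies <- tryCatch(end_systolic_point(x), error = function(e) NULL)
  if (!is.null(ies))
    graphics::points(x$volume[ies], x$pressure[ies], pch = 19,
                     col = "firebrick")
  invisible(x)
}

#' Write loop metrics to JSON and CSV
#'
#' JSON keeps full double precision (round-trips exactly); CSV is rounded
#' to 6 significant digits with units in the header names.
#'
#' @param metrics a `pv_metrics` object (or named list of scalars).
#' @param json,csv output paths (either may be `NULL` to skip).
#' @return invisible list of the paths written.
#' @export
write_metrics <- function(metrics, json = NULL, csv = NULL) {
  vals <- unclass(metrics)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (!is.null(json))
    jsonlite::write_json(vals, json, auto_unbox = TRUE, digits = I(17))
  if (!is.null(csv)) {
    df <- as.data.frame(lapply(vals, function(v)
      if (is.numeric(v)) signif(v, 6) else v))
    utils::write.csv(df, csv, row.names = FALSE)
  }
  invisible(list(json = json, csv = csv))
}
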