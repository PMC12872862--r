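#' Valvular event times
#'
#' The four valvular events of one cardiac cycle, in seconds from cycle
#' start (R wave): mitral valve closure (MVC), aortic valve opening (AVO),
#' aortic valve closure (AVC), mitral valve opening (MVO). Ordering
#' 0 <= MVC < AVO < AVC < MVO < cycle_length is enforced.
#'
#' @param t_mvc,t_avo,t_avc,t_mvo event times (s).
#' @param cycle_length RR interval (s).
#' @return Object of class `valve_events`.
#' @examples
#' valve_events(0, 0.07, 0.36, 0.42, 0.9)
#' @export
valve_events <- function(t_mvc, t_avo, t_avc, t_mvo, cycle_length) {
  for (nm in c("t_mvc", "t_avo", "t_avc", "t_mvo", "cycle_length"))
    check_scalar(get(nm), nm)
  if (!(t_mvc >= 0 && t_mvc < t_avo && t_avo < t_avc &&
        t_avc < t_mvo && t_mvo < cycle_length))
    stopf(paste0("valve events must satisfy 0 <= MVC < AVO < AVC < MVO < ",
                 "cycle_length; got %.4g, %.4g, %.4g, %.4g, %.4g"),
          t_mvc, t_avo, t_avc, t_mvo, cycle_length,
          class = "pvloopr_invalid_events")
  structure(list(t_mvc = t_mvc, t_avo = t_avo, t_avc = t_avc,
                 t_mvo = t_mvo, cycle_length = cycle_length),
            class = "valve_events")
}

#' Brachial cuff pressure
#'
#' @param systolic,diastolic sphygmomanometer pressures (mmHg),
#'   `systolic > diastolic > 0`.
#' @return Object of class `cuff_pressure`.
#' @export
cuff_pressure <- function(systolic, diastolic) {
  check_scalar(systolic, "systolic", lower = 1e-9)
  check_scalar(diastolic, "diastolic", lower = 1e-9)
  if (systolic <= diastolic)
    stopf("systolic (%g) must exceed diastolic (%g)", systolic, diastolic)
  structure(list(systolic = systolic, diastolic = diastolic),
            class = "cuff_pressure")
}

#' Generic normalized LV pressure reference curve
#'
#' A reference curve holds a normalized LV pressure shape on a uniform
#' phase grid over `[0, 1]` (phase 0 = MVC, phase 1 = next MVC), with the
#' normalized phases of the valvular landmarks. Pressure is normalized so
#' the maximum is exactly 1, attained once, between the AVO and AVC
#' landmarks.
#'
#' `default_reference()` builds the package's parametric template: a
#' raised-cosine systolic limb peaking mid-ejection and a low flat
#' diastolic limb. A site that possesses an averaged multi-patient curve
#' can substitute it via [read_reference()].
#'
#' @param phase uniform grid on `[0, 1]`.
#' @param p_norm normalized pressure, `>= 0`, max exactly 1.
#' @param landmarks named numeric vector with elements `mvc` (= 0), `avo`,
#'   `avc`, `mvo`, `end` (= 1); a `peak` element is recomputed.
#' @return Object of class `reference_curve`.
#' @export
reference_curve <- function(phase, p_norm, landmarks) {
  if (length(phase) != length(p_norm) || length(phase) < 100L)
    stopf("reference curve needs >= 100 paired samples")
  if (!is_uniform_grid(phase) || abs(phase[1]) > 1e-12 ||
      abs(phase[length(phase)] - 1) > 1e-12)
    stopf("phase must be a uniform grid spanning [0, 1]")
  if (any(p_norm < 0)) stopf("p_norm must be non-negative")
  need <- c("mvc", "avo", "avc", "mvo", "end")
  if (!all(need %in% names(landmarks)))
    stopf("landmarks must name %s", paste(need, collapse = ", "))
  lm <- landmarks[need]
  if (abs(lm[["mvc"]]) > 1e-12 || abs(lm[["end"]] - 1) > 1e-12 ||
      any(diff(unname(lm)) <= 0))
    stopf("landmarks must satisfy 0 = mvc < avo < avc < mvo < end = 1")
  # normalize so the sampled maximum is exactly 1, attained once
  p_norm <- p_norm / max(p_norm)
  imax <- which(p_norm == max(p_norm))
  if (length(imax) != 1L)
    stopf("p_norm attains its maximum %d times; expected once", length(imax))
  peak <- phase[imax]
  if (peak <= lm[["avo"]] || peak >= lm[["avc"]])
    stopf("pressure peak (phase %.3f) must lie between AVO and AVC", peak)
  structure(list(phase = as.numeric(phase), p_norm = as.numeric(p_norm),
                 landmarks = c(lm, peak = peak)),
            class = "reference_curve")
}

raised_cosine <- function(s) (1 - cos(pi * s)) / 2

#' @rdname reference_curve
#' @param n_samples grid size (>= 100; default 501 puts the default
#'   landmarks exactly on the grid).
#' @param p_avo normalized pressure at aortic valve opening (default 0.45).
#' @param p_avc normalized pressure at aortic valve closure (default 0.38).
#' @param p_ed normalized end-diastolic pressure, used at both cycle ends
#'   (default 0.08).
#' @param p_min normalized early-diastolic minimum at MVO (default 0.05).
#' @param avo,avc,mvo normalized landmark phases.
#' @param peak_frac position of the pressure peak within the AVO-AVC
#'   segment (default 0.45, i.e. just before mid-ejection).
#' @export
default_reference <- function(n_samples = 501L, p_avo = 0.45, p_avc = 0.38,
                              p_ed = 0.08, p_min = 0.05,
                              avo = 0.08, avc = 0.40, mvo = 0.47,
                              peak_frac = 0.45) {
  if (n_samples < 100L) stopf("n_samples must be >= 100")
  for (nm in c("p_avo", "p_avc", "p_ed", "p_min"))
    check_scalar(get(nm), nm, lower = 0, upper = 0.99)
  check_scalar(peak_frac, "peak_frac", lower = 0.05, upper = 0.95)
  peak <- avo + peak_frac * (avc - avo)
  anchors_ph <- c(0, avo, peak, avc, mvo, 1)
  anchors_p  <- c(p_ed, p_avo, 1, p_avc, p_min, p_ed)
  g <- seq(0, 1, length.out = as.integer(n_samples))
  seg <- findInterval(g, anchors_ph, rightmost.closed = TRUE)
  s <- (g - anchors_ph[seg]) / (anchors_ph[seg + 1L] - anchors_ph[seg])
  p <- anchors_p[seg] + (anchors_p[seg + 1L] - anchors_p[seg]) * raised_cosine(s)
  reference_curve(g, p, c(mvc = 0, avo = avo, avc = avc, mvo = mvo, end = 1))
}

#' Read / write a reference curve CSV
#'
#' Format: a comment header line `# landmarks: avo=<phase> avc=<phase>
#' mvo=<phase>` followed by a `phase,p_norm` CSV table.
#'
#' @param path file path.
#' @return [read_reference()] returns a `reference_curve`;
#'   [write_reference()] returns `path` invisibly.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) io_stopf("reference file not found: %s", path)
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  lmline <- grep("landmarks:", hdr, value = TRUE)
  if (!length(lmline))
    io_stopf("%s: missing '# landmarks: avo=... avc=... mvo=...' header", path)
  kv <- regmatches(lmline[1],
                   gregexpr("(avo|avc|mvo)\\s*=\\s*[0-9.eE+-]+", lmline[1]))[[1]]
  vals <- as.numeric(sub(".*=\\s*", "", kv))
  names(vals) <- sub("\\s*=.*", "", kv)
  if (!all(c("avo", "avc", "mvo") %in% names(vals)))
    io_stopf("%s: landmark header must define avo, avc and mvo", path)
  df <- utils::read.csv(path, comment.char = "#")
  reference_curve(df[[1]], df[[2]],
                  c(mvc = 0, avo = vals[["avo"]], avc = vals[["avc"]],
                    mvo = vals[["mvo"]], end = 1))
}

#' @rdname read_reference
#' @param ref a `reference_curve`.
#' @export
write_reference <- function(ref, path) {
  lm <- ref$landmarks
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# landmarks: avo=%.10g avc=%.10g mvo=%.10g",
                     lm[["avo"]], lm[["avc"]], lm[["mvo"]]), con)
  utils::write.csv(data.frame(phase = ref$phase, p_norm = ref$p_norm),
                   con, row.names = FALSE)
  invisible(path)
}

#' Estimate an individualized LV pressure waveform
#'
#' Scales a normalized reference LV pressure curve horizontally to the
#' measured valvular event times and vertically to the cuff pressures:
#' peak LV pressure is anchored at `systolic + mean_gradient` (for
#' patients without outflow obstruction the gradient is 0 and the peak is
#' the systolic cuff pressure alone) and the pressure at aortic valve
#' opening is anchored at the diastolic cuff pressure. The time warp is a
#' strictly increasing piecewise-linear bijection mapping the reference
#' landmarks exactly onto the measured events; the vertical map is the
#' affine transform through the two pressure anchors.
#'
#' The returned trace is sampled on a uniform grid, and carries the warped
#' anchor points of the underlying continuous waveform as attribute
#' `anchors`; [pressure_at()] and [peak_pressure()] evaluate that
#' continuous model, for which the two anchor constraints hold exactly.
#'
#' @param events a [valve_events()].
#' @param cuff a [cuff_pressure()].
#' @param mean_gradient mean transaortic pressure gradient (mmHg, >= 0;
#'   0 when there is no outflow obstruction).
#' @param ref a [reference_curve()]; default [default_reference()].
#' @param rate_hz output sampling rate (default 200 Hz).
#' @param floor_mmHg lower clamp for the scaled diastolic limb (default
#'   2 mmHg); the two-anchor scaling does not promise diastolic fidelity.
#' @return A [pressure_trace()] on `[0, cycle_length]`.
#' @examples
#' ev <- valve_events(0, 0.07, 0.36, 0.42, 0.9)
#' p <- estimate_pressure(ev, cuff_pressure(159, 73), mean_gradient = 51)
#' peak_pressure(p)            # 159 + 51 = 210 mmHg
#' pressure_at(p, 0.07)        # 73 mmHg at AVO
#' @export
estimate_pressure <- function(events, cuff, mean_gradient = 0,
                              ref = default_reference(), rate_hz = 200,
                              floor_mmHg = 2) {
  if (!inherits(events, "valve_events")) stopf("`events` must be valve_events")
  if (!inherits(cuff, "cuff_pressure")) stopf("`cuff` must be cuff_pressure")
  if (!inherits(ref, "reference_curve")) stopf("`ref` must be a reference_curve")
  check_scalar(mean_gradient, "mean_gradient", lower = 0)
  check_scalar(rate_hz, "rate_hz", lower = 10)
  lm <- ref$landmarks
  # knots: reference grid plus the landmark phases (so landmark values are
  # knots of the interpolant and anchoring is exact)
  ph <- sort(unique(c(ref$phase, lm[c("avo", "avc", "mvo", "peak")])))
  pn <- mono_fun(ref$phase, ref$p_norm)(ph)
  p_avo_ref <- pn[which.min(abs(ph - lm[["avo"]]))]
  peak_target <- cuff$systolic + mean_gradient
  a <- (peak_target - cuff$diastolic) / (1 - p_avo_ref)
  b <- peak_target - a
  if (a <= 0 || peak_target <= 0)
    stopf("degenerate vertical scale: peak %g mmHg <= diastolic %g mmHg",
          peak_target, cuff$diastolic, class = "pvloopr_degenerate_input")
  pr <- pmax(a * pn + b, floor_mmHg)
  if (max(pr) <= floor_mmHg)
    stopf("pressure floor %g mmHg swallows the waveform", floor_mmHg,
          class = "pvloopr_degenerate_input")
  # piecewise-linear warp of phase onto time, MVC-relative
  L <- events$cycle_length
  src <- c(0, lm[["avo"]], lm[["avc"]], lm[["mvo"]], 1)
  dst <- c(events$t_mvc, events$t_avo, events$t_avc, events$t_mvo,
           events$t_mvc + L)
  tw <- stats::approx(src, dst, xout = ph)$y
  # continuous waveform, periodic in the cycle, MVC at t_mvc
  rel <- tw - events$t_mvc               # in [0, L]; rel[1]=0, rel[n]=L
  # landmark phases may coincide with grid phases: drop duplicate knots
  keep <- c(TRUE, diff(rel) > 1e-12)
  rel <- rel[keep]; pr <- pr[keep]
  S <- mono_fun(rel, pr)
  eval_cycle <- function(t) S((t - events$t_mvc) %% L)
  g <- seq(0, L, length.out = max(2L, as.integer(round(L * rate_hz)) + 1L))
  out <- pressure_trace(g, eval_cycle(g))
  attr(out, "events") <- events
  attr(out, "cuff") <- cuff
  attr(out, "mean_gradient") <- mean_gradient
  attr(out, "anchors") <- list(t_rel = rel, pressure = pr,
                               t_mvc = events$t_mvc, cycle_length = L)
  out
}

#' Evaluate an estimated pressure waveform
#'
#' For traces produced by [estimate_pressure()] these accessors evaluate
#' the continuous monotone-cubic model through the warped anchor points
#' (exact at the valvular landmarks and the pressure peak); for plain
#' traces they fall back to interpolating / scanning the samples.
#'
#' @param trace a [pressure_trace()].
#' @param t time(s) within the cycle (s).
#' @return `pressure_at()`: pressure (mmHg) at `t`; `peak_pressure()`: the
#'   waveform maximum (mmHg).
#' @export
pressure_at <- function(trace, t) {
  an <- attr(trace, "anchors")
  if (!is.null(an)) {
    mono_fun(an$t_rel, an$pressure)((t - an$t_mvc) %% an$cycle_length)
  } else {
    mono_fun(trace$time, trace$pressure)(t)
  }
}

#' @rdname pressure_at
#' @export
peak_pressure <- function(trace) {
  an <- attr(trace, "anchors")
  # monoH.FC is monotone between knots, so the knot maximum is the global
  # maximum of the continuous waveform
  if (!is.null(an)) max(an$pressure) else max(trace$pressure)
}
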