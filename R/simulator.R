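#' Parameters of the time-varying-elastance beat simulator
#'
#' The simulator is kinematic: the volume waveform is prescribed (flat
#' during the isovolumic phases, raised-cosine ejection and filling limbs)
#' and LV pressure follows from a double-Hill time-varying elastance,
#' `P(t) = E(t) * (V(t) - V0)`. An aortic stenosis is modelled as an
#' instantaneous transvalvular gradient `dP = c_sten * Q^2` with
#' `Q = -dV/dt` during ejection; central aortic pressure during ejection
#' is LV pressure minus the gradient, and the cuff readings are equated to
#' the aortic extremes (systolic = maximal aortic pressure, diastolic =
#' aortic pressure at aortic valve opening; no peripheral amplification).
#'
#' Defaults emulate a severe-AS, preserved-EF patient: EDV 165 mL,
#' SV 93 mL, heart rate about 67 bpm, mean gradient about 51 mmHg,
#' systolic cuff pressure around 160 mmHg.
#'
#' @param EDV end-diastolic volume (mL).
#' @param SV stroke volume (mL), `0 < SV < EDV`.
#' @param E_max,E_min elastance extremes (mmHg/mL), `E_max > E_min > 0`.
#' @param V0_sim true ESPVR volume intercept of the simulated ventricle
#'   (mL); must stay below the minimal volume.
#' @param cycle_length RR interval (s).
#' @param frac_avo,frac_avc,frac_mvo valvular event times as fractions of
#'   the cycle (MVC is at t = 0).
#' @param stenosis_coefficient `c_sten` (mmHg s^2 / mL^2); 0 = no AS.
#' @param ejection_skew exponent `a` of the ejection limb
#'   `V = EDV - SV * rc(s^a)` with `s` the normalized ejection time and
#'   `rc` the raised cosine; `a < 1` makes transvalvular flow peak early
#'   in ejection as it physiologically does (default 0.8; 1 = symmetric).
#' @param filling_skew exponent of the filling limb, analogous; the
#'   default 0.45 reproduces rapid early (E-wave) filling followed by
#'   diastasis near end-diastolic volume.
#' @param rate_hz sampling rate of the generated traces (default 200).
#' @param tau1_frac,n1,tau2_frac,n2 double-Hill shape constants (time
#'   constants as fractions of the cycle). Defaults place peak elastance
#'   at end-ejection, where end-systole physiologically occurs.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(EDV = 165, SV = 93, E_max = 2.6, E_min = 0.07,
                       V0_sim = 10, cycle_length = 0.9,
                       frac_avo = 0.08, frac_avc = 0.40, frac_mvo = 0.47,
                       stenosis_coefficient = 4e-4, ejection_skew = 0.8,
                       filling_skew = 0.45, rate_hz = 200,
                       tau1_frac = 0.269, n1 = 1.9,
                       tau2_frac = 0.45, n2 = 21.9) {
  check_scalar(EDV, "EDV", lower = 1e-6)
  check_scalar(SV, "SV", lower = 1e-6, upper = EDV - 1e-6)
  check_scalar(E_max, "E_max", lower = 1e-9)
  check_scalar(E_min, "E_min", lower = 1e-9, upper = E_max - 1e-12)
  check_scalar(V0_sim, "V0_sim", lower = 0, upper = EDV - SV - 1e-9)
  check_scalar(cycle_length, "cycle_length", lower = 0.2, upper = 3)
  check_scalar(stenosis_coefficient, "stenosis_coefficient", lower = 0)
  check_scalar(ejection_skew, "ejection_skew", lower = 0.51, upper = 1.5)
  check_scalar(filling_skew, "filling_skew", lower = 0.2, upper = 1.5)
  check_scalar(rate_hz, "rate_hz", lower = 20)
  if (!(0 < frac_avo && frac_avo < frac_avc && frac_avc < frac_mvo &&
        frac_mvo < 1))
    stopf("event fractions must satisfy 0 < avo < avc < mvo < 1")
  structure(as.list(environment()), class = "sim_params")
}

# normalized double-Hill activation, t in seconds from MVC
elastance_norm <- function(t, L, tau1_frac, n1, tau2_frac, n2) {
  shape <- function(u) {
    h1 <- (u / (tau1_frac * L))^n1
    (h1 / (1 + h1)) / (1 + (u / (tau2_frac * L))^n2)
  }
  tt <- seq(0, L, length.out = 2001)
  mx <- max(shape(tt))
  list(f = function(u) shape(u) / mx,
       t_peak = tt[which.max(shape(tt))])
}

#' Simulate one ground-truth beat
#'
#' Generates the paired true LV pressure and volume traces of one cardiac
#' cycle, together with everything the non-invasive estimator needs (cuff
#' pressures, mean transvalvular gradient, valvular event times) and the
#' true loop metrics, enabling validation by parameter recovery.
#'
#' @param params a [sim_params()].
#' @return Object of class `sim_beat`: list with `true_pressure`
#'   ([pressure_trace()]), `volume` ([volume_trace()]), `cuff`
#'   ([cuff_pressure()]), `mean_gradient` (mmHg), `events`
#'   ([valve_events()]), `true_metrics` ([pv_metrics()]), `t_emax`
#'   (time of maximal elastance, s) and `params`.
#' @examples
#' beat <- simulate_beat(sim_params(stenosis_coefficient = 0))
#' beat$mean_gradient  # 0: no outflow obstruction
#' @export
simulate_beat <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  L <- p$cycle_length
  t_avo <- p$frac_avo * L; t_avc <- p$frac_avc * L; t_mvo <- p$frac_mvo * L
  Te <- t_avc - t_avo          # ejection duration
  Tf <- L - t_mvo              # filling duration
  n <- max(2L, as.integer(round(L * p$rate_hz)) + 1L)
  tt <- seq(0, L, length.out = n)

  vol <- numeric(n) + p$EDV
  ej <- tt > t_avo & tt <= t_avc
  ivr <- tt > t_avc & tt <= t_mvo
  fil <- tt > t_mvo
  s_ej <- (tt[ej] - t_avo) / Te
  vol[ej] <- p$EDV - p$SV * raised_cosine(s_ej^p$ejection_skew)
  vol[ivr] <- p$EDV - p$SV
  vol[fil] <- p$EDV - p$SV +
    p$SV * raised_cosine(((tt[fil] - t_mvo) / Tf)^p$filling_skew)

  en <- elastance_norm(tt, L, p$tau1_frac, p$n1, p$tau2_frac, p$n2)
  E <- p$E_min + (p$E_max - p$E_min) * en$f(tt)
  pressure <- E * (vol - p$V0_sim)
  if (any(pressure <= 0))
    stopf("parameters yield non-positive LV pressure (min %.3g mmHg)",
          min(pressure), class = "pvloopr_degenerate_input")

  # transvalvular flow and gradient during ejection
  flow <- ejection_flow(p$SV, Te, p$ejection_skew)
  Q <- numeric(n)
  Q[ej] <- flow$Q(s_ej)
  dp <- p$stenosis_coefficient * Q^2
  pao_ej <- pressure[ej] - dp[ej]
  if (any(pao_ej <= 0))
    stopf("stenosis coefficient yields non-positive aortic pressure",
          class = "pvloopr_degenerate_input")
  sbp <- max(pao_ej)
  e_avo <- p$E_min + (p$E_max - p$E_min) * en$f(t_avo)
  dbp <- e_avo * (p$EDV - p$V0_sim)      # Q(t_avo) = 0, no gradient yet
  # ejection-time average of the instantaneous gradient
  mean_gradient <- p$stenosis_coefficient * flow$mean_q2

  events <- valve_events(0, t_avo, t_avc, t_mvo, L)
  ptrace <- pressure_trace(tt, pressure)
  vtrace <- volume_trace(tt, vol)
  structure(list(
    true_pressure = ptrace, volume = vtrace,
    cuff = cuff_pressure(sbp, dbp), mean_gradient = mean_gradient,
    events = events,
    true_metrics = pv_metrics(pv_loop(ptrace, vtrace)),
    t_emax = en$t_peak, params = p
  ), class = "sim_beat")
}

#' Simulate a reproducible cohort of beats
#'
#' Draws physiological parameters independently and uniformly from the
#' given ranges and simulates one beat per subject. Identical seeds give
#' identical cohorts.
#'
#' @param n number of beats (>= 1).
#' @param seed RNG seed (integer).
#' @param param_ranges named list of `c(min, max)` ranges for `EDV`, `EF`
#'   (ejection fraction, converted to SV), `E_max`, `E_min`,
#'   `cycle_length` and `mean_gradient` (mmHg; the per-beat stenosis
#'   coefficient is solved from it via [stenosis_for_gradient()]).
#'   Defaults emulate a severe-AS, preserved-EF cohort with mean
#'   gradients spanning 30-80 mmHg.
#' @param ... fixed parameters forwarded to [sim_params()].
#' @return Object of class `sim_cohort`: list of [simulate_beat()] results.
#' @export
simulate_cohort <- function(n, seed = 1L,
                            param_ranges = list(
                              EDV = c(140, 200), EF = c(0.50, 0.62),
                              E_max = c(2.2, 3.2), E_min = c(0.05, 0.09),
                              cycle_length = c(0.75, 1.05),
                              mean_gradient = c(30, 80)),
                            ...) {
  if (n < 1L) stopf("n must be >= 1")
  set.seed(as.integer(seed))
  draw1 <- function(nm) {
    r <- param_ranges[[nm]]
    if (is.null(r)) stopf("param_ranges lacks `%s`", nm)
    stats::runif(1, r[1], r[2])
  }
  fixed <- list(...)
  frac_avo <- fixed$frac_avo %||% formals(sim_params)$frac_avo
  frac_avc <- fixed$frac_avc %||% formals(sim_params)$frac_avc
  skew <- fixed$ejection_skew %||% formals(sim_params)$ejection_skew
  # rejection sampling: hemodynamically inconsistent draws (a gradient the
  # drawn ventricle cannot generate) are discarded and redrawn
  beats <- vector("list", n)
  for (i in seq_len(n)) {
    for (attempt in 1:100) {
      edv <- draw1("EDV"); ef <- draw1("EF"); emax <- draw1("E_max")
      emin <- draw1("E_min"); cl <- draw1("cycle_length")
      grad <- draw1("mean_gradient")
      sv <- ef * edv
      te <- (frac_avc - frac_avo) * cl
      beat <- tryCatch(
        simulate_beat(sim_params(EDV = edv, SV = sv, E_max = emax,
                                 E_min = emin, cycle_length = cl,
                                 stenosis_coefficient =
                                   stenosis_for_gradient(grad, sv, te, skew),
                                 ...)),
        pvloopr_degenerate_input = function(e) NULL)
      if (!is.null(beat)) break
    }
    if (is.null(beat))
      stopf("could not draw a consistent beat within 100 attempts")
    beats[[i]] <- beat
  }
  structure(beats, class = "sim_cohort", seed = as.integer(seed))
}

# transvalvular flow of the skewed raised-cosine ejection limb:
# Q(s) = -dV/dt = SV * (pi/2) * sin(pi s^a) * a * s^(a-1) / Te, s in (0,1];
# mean_q2 is the ejection-time average of Q^2 (fine trapezoid quadrature)
ejection_flow <- function(SV, Te, skew) {
  Qf <- function(s) {
    out <- numeric(length(s))
    pos <- s > 0
    out[pos] <- SV * (pi / 2) * sin(pi * s[pos]^skew) *
      skew * s[pos]^(skew - 1) / Te
    out
  }
  sg <- seq(0, 1, length.out = 4001)
  list(Q = Qf, mean_q2 = pracma::trapz(sg, Qf(sg)^2))
}

#' Stenosis coefficient producing a target mean gradient
#'
#' Solves `c_sten` such that the ejection-time average of the
#' instantaneous gradient `c_sten * Q(t)^2` equals the requested mean
#' transvalvular gradient, for the simulator's skewed raised-cosine
#' ejection limb.
#'
#' @param mean_gradient target mean transvalvular gradient (mmHg, >= 0).
#' @param SV stroke volume (mL).
#' @param Te ejection duration (s).
#' @param skew ejection-skew exponent (see [sim_params()]).
#' @return stenosis coefficient (mmHg s^2 / mL^2).
#' @export
stenosis_for_gradient <- function(mean_gradient, SV, Te, skew = 0.6) {
  check_scalar(mean_gradient, "mean_gradient", lower = 0)
  mean_gradient / ejection_flow(SV, Te, skew)$mean_q2
}

#' Run the non-invasive estimator on a simulated beat
#'
#' Convenience wrapper for recovery experiments: estimates the pressure
#' waveform from the beat's cuff pressures, gradient and valve events,
#' synchronizes it with the beat's volume trace, and returns the
#' non-invasive loop metrics next to the ground truth.
#'
#' @param beat a [simulate_beat()] result.
#' @param ref reference curve for the estimator.
#' @return list with `estimated` and `true` ([pv_metrics()]), and `loop`.
#' @export
recover_beat <- function(beat, ref = default_reference()) {
  stopifnot(inherits(beat, "sim_beat"))
  est_p <- estimate_pressure(beat$events, beat$cuff, beat$mean_gradient,
                             ref = ref, rate_hz = beat$params$rate_hz)
  sync <- synchronize(est_p, beat$volume)
  loop <- pv_loop(sync$pressure, sync$volume)
  list(estimated = pv_metrics(loop), true = beat$true_metrics, loop = loop)
}

#' Write a simulated cohort to disk
#'
#' One pressure and one volume CSV per beat (package CSV dialects) plus a
#' `manifest.json` holding the per-beat inputs (cuff, gradient, events),
#' true parameters and true metrics, and file names.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(cohort), function(i) {
    b <- cohort[[i]]
    pf <- sprintf("beat%03d_pressure.csv", i)
    vf <- sprintf("beat%03d_volume.csv", i)
    write_trace(b$true_pressure, file.path(dir, pf))
    write_trace(b$volume, file.path(dir, vf))
    list(pressure_csv = pf, volume_csv = vf,
         systolic_mmHg = b$cuff$systolic, diastolic_mmHg = b$cuff$diastolic,
         mean_gradient_mmHg = b$mean_gradient,
         events = unclass(b$events),
         true_params = unclass(b$params),
         true_metrics = unclass(b$true_metrics))
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = attr(cohort, "seed"), beats = entries),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Synthetic segmental strain from a volume trace
#'
#' Builds a synchronous (or optionally dyssynchronous) segmental strain
#' set whose shape follows the relative volume excursion, for exercising
#' the myocardial work pipeline without speckle-tracking input.
#'
#' @param v a [volume_trace()].
#' @param peak_strain magnitude of peak systolic shortening (%, positive;
#'   default 17, i.e. strain reaches -17%).
#' @param n_segments number of segments (default 18).
#' @param delay_s per-segment onset delay applied to the second half of
#'   the segments (s, default 0 = synchronous).
#' @return a [strain_traces()] on the volume grid.
#' @export
strain_from_volume <- function(v, peak_strain = 17, n_segments = 18,
                               delay_s = 0) {
  stopifnot(inherits(v, "volume_trace"))
  base <- peak_strain * (v$volume - max(v$volume)) /
    (max(v$volume) - min(v$volume))
  L <- diff(range(v$time))
  f <- mono_fun(v$time, base)
  s <- vapply(seq_len(n_segments), function(j) {
    d <- if (j > n_segments / 2) delay_s else 0
    f(pmin(pmax(v$time - d, 0), L))
  }, numeric(length(v$time)))
  strain_traces(v$time, s)
}
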