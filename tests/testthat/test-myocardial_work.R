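# shared grid and events for constructed strain cases
mw_grid <- function() {
  ev <- valve_events(0, 0.07, 0.36, 0.42, 0.9)
  tt <- seq(0, 0.9, by = 0.0025)
  list(ev = ev, tt = tt,
       p_const = pressure_trace(tt, rep(100, length(tt))))
}

# smooth monotone strain ramp from 0 to `to` between t0 and t1, flat outside
strain_ramp <- function(tt, t0, t1, to) {
  s <- pmin(pmax((tt - t0) / (t1 - t0), 0), 1)
  to * (1 - cos(pi * s)) / 2
}

test_that("segment work components follow the sign conventions", {
  g <- mw_grid()
  # constant strain: no deformation, no work
  w0 <- segment_work(g$p_const, rep(3, length(g$tt)), g$ev)
  expect_equal(w0$constructive, 0)
  expect_equal(w0$wasted, 0)
  # shortening 0 -> -20% during systole at P = 100, flat in IVR:
  # constructive = 100 mmHg * 20% = 2000 mmHg%
  sh <- strain_ramp(g$tt, 0, g$ev$t_avc, -20)
  w <- segment_work(g$p_const, sh, g$ev)
  expect_equal(w$constructive, 2000, tolerance = 1e-3)
  expect_equal(w$wasted, 0)
  expect_equal(w$net, 2000, tolerance = 1e-3)
  # lengthening 0 -> +10% during systole: all wasted
  le <- strain_ramp(g$tt, 0, g$ev$t_avc, 10)
  wl <- segment_work(g$p_const, le, g$ev)
  expect_equal(wl$constructive, 0)
  expect_equal(wl$wasted, 1000, tolerance = 1e-3)
  # lengthening during isovolumic relaxation counts as constructive
  # (the phase-boundary sample smears < 0.2% into the wasted bin)
  ivr <- strain_ramp(g$tt, g$ev$t_avc, g$ev$t_mvo, 5)
  wi <- segment_work(g$p_const, ivr, g$ev)
  expect_equal(wi$constructive, 500, tolerance = 1e-2)
  expect_lt(wi$wasted, 1)
})

test_that("global indices average segments; identical segments collapse", {
  g <- mw_grid()
  sh <- strain_ramp(g$tt, 0, g$ev$t_avc, -18)
  st <- strain_traces(g$tt, matrix(rep(sh, 18), ncol = 18))
  m <- global_mwi(g$p_const, st, g$ev)
  one <- segment_work(g$p_const, sh, g$ev)
  expect_equal(m$GWI, one$net)
  expect_equal(m$GCW, one$constructive)
  expect_equal(m$GWE, 100)
  expect_equal(m$GWW, 0)
  # segment order does not matter
  mixed <- strain_traces(g$tt, cbind(sh, 0.5 * sh, 2 * sh))
  shuf <- strain_traces(g$tt, cbind(2 * sh, sh, 0.5 * sh))
  expect_equal(global_mwi(g$p_const, mixed, g$ev)$GWI,
               global_mwi(g$p_const, shuf, g$ev)$GWI)
})

test_that("work scales with pressure; efficiency does not", {
  g <- mw_grid()
  # shortening then frank lengthening during late systole
  sh <- strain_ramp(g$tt, 0, 0.2, -15) +
    strain_ramp(g$tt, 0.2, g$ev$t_avc, 4)
  st <- strain_traces(g$tt, cbind(sh, 0.8 * sh))
  m1 <- global_mwi(g$p_const, st, g$ev)
  p2 <- pressure_trace(g$tt, rep(200, length(g$tt)))
  m2 <- global_mwi(p2, st, g$ev)
  expect_equal(m2$GWI, 2 * m1$GWI, tolerance = 1e-9)
  expect_equal(m2$GCW, 2 * m1$GCW, tolerance = 1e-9)
  expect_equal(m2$GWW, 2 * m1$GWW, tolerance = 1e-9)
  expect_equal(m2$GWE, m1$GWE, tolerance = 1e-9)
  expect_true(m1$GWW > 0 && m1$GWE < 100)
})

test_that("grid refinement changes global work by less than 0.5%", {
  ev <- valve_events(0, 0.07, 0.36, 0.42, 0.9)
  f_p <- function(tt) 70 + 60 * sin(pi * pmin(tt / 0.42, 1))^2
  f_s <- function(tt) strain_ramp(tt, 0, 0.36, -17)
  t1 <- seq(0, 0.9, by = 0.005); t2 <- seq(0, 0.9, by = 0.001)
  m1 <- global_mwi(pressure_trace(t1, f_p(t1)),
                   strain_traces(t1, cbind(f_s(t1))), ev)
  m2 <- global_mwi(pressure_trace(t2, f_p(t2)),
                   strain_traces(t2, cbind(f_s(t2))), ev)
  expect_equal(m1$GWI, m2$GWI, tolerance = 5e-3)
})

test_that("dyssynchronous shortening wastes work on a simulated beat", {
  beat <- simulate_beat(sim_params())
  p_est <- estimate_pressure(beat$events, beat$cuff, beat$mean_gradient,
                             rate_hz = beat$params$rate_hz)
  sync_strain <- strain_from_volume(beat$volume)
  m_sync <- global_mwi(p_est, sync_strain, beat$events)
  expect_equal(m_sync$GWE, 100, tolerance = 1e-6)
  dys <- strain_from_volume(beat$volume, delay_s = 0.09)
  m_dys <- global_mwi(p_est, dys, beat$events)
  expect_lt(m_dys$GWE, 100)
  expect_gt(m_dys$GWW, 0)
  expect_lt(m_dys$GWI, m_sync$GWI)
})

test_that("misaligned strain grids are rejected", {
  g <- mw_grid()
  expect_error(segment_work(g$p_const, rep(0, 10), g$ev),
               class = "pvloopr_alignment_error")
  st <- strain_traces(seq(0, 0.8, by = 0.0025),
                      cbind(rep(0, 321)))
  expect_error(global_mwi(g$p_const, st, g$ev),
               class = "pvloopr_alignment_error")
})
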