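test_that("rectangle loop reproduces closed-form metrics", {
  loop <- rect_loop()                     # V 60-140 mL, P 10-110 mmHg
  expect_equal(loop_area(loop), 8000, tolerance = 1e-12)
  ies <- end_systolic_point(loop)
  expect_equal(loop$volume[ies], 60)
  expect_equal(loop$pressure[ies], 110)
  m <- pv_metrics(loop)
  expect_equal(m$SW, 8000)
  expect_equal(m$EDV, 140); expect_equal(m$ESV, 60); expect_equal(m$SV, 80)
  expect_equal(m$Ea, 110 / 80)                 # 1.375
  expect_equal(m$Ees, 110 / 60, tolerance = 1e-12)   # 1.8333
  expect_equal(m$VAC, (110 / 80) / (110 / 60))       # 0.75
  expect_equal(m$PE, 0.5 * 110 * 60)                 # 3300
  expect_equal(m$PVA, 11300)
  expect_equal(m$efficiency, 100 * 8000 / 11300)     # 70.80%
  expect_equal(m$ESP_over_EDV, 110 / 140)            # 0.7857
  expect_equal(m$Pmax_over_EDV, 110 / 140)
})

test_that("loop orientation is normalized and degenerate loops rejected", {
  loop <- rect_loop()
  rev_loop <- pv_loop(rev(loop$pressure), rev(loop$volume))
  expect_true(attr(rev_loop, "reversed"))
  expect_equal(as.data.frame(pv_metrics(rev_loop))[
                 c("SW", "Ees", "Ea", "efficiency")],
               as.data.frame(pv_metrics(loop))[
                 c("SW", "Ees", "Ea", "efficiency")])
  # constant volume: zero enclosed area
  expect_error(pv_loop(seq(10, 110, length.out = 60), rep(100, 60)),
               class = "pvloopr_degenerate_loop")
})

test_that("shoelace area matches the analytic ellipse to 0.1%", {
  loop <- ellipse_loop(a = 40, b = 50, n = 720)
  expect_equal(loop_area(loop), pi * 40 * 50, tolerance = 1e-3)
})

test_that("shoelace area agrees with the trapezoid work integral on a beat", {
  beat <- simulate_beat(sim_params())
  loop <- pv_loop(beat$true_pressure, beat$volume)
  sw_shoelace <- loop_area(loop)
  # independent route: W = -integral P dV/dt dt over the cycle
  tt <- beat$volume$time
  dvdt <- pracma::gradient(beat$volume$volume, tt)
  w <- -pracma::trapz(tt, beat$true_pressure$pressure * dvdt)
  expect_equal(sw_shoelace, abs(w), tolerance = 5e-3)
})

test_that("equidistant upper-left candidates resolve to the earliest time", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]      # 1-degree circle
  # V = 100 + 50 cos(th), P = 100 + 50 sin(th): counter-clockwise circle
  loop <- pv_loop(100 + 50 * sin(th), 100 + 50 * cos(th),
                  time = seq_along(th) * 1e-3)
  ies <- end_systolic_point(loop)
  # candidates are the open upper-left quarter arc (91..179 degrees), all
  # exactly equidistant from the center; earliest time wins
  expect_equal(unclass(ies)[1], 92L, ignore_attr = TRUE)
})

test_that("energetic identities and homogeneity hold on arbitrary loops", {
  set.seed(7)
  beats <- simulate_cohort(5, seed = 11)
  for (b in beats) {
    m <- b$true_metrics
    expect_equal(m$PVA, m$SW + m$PE, tolerance = 1e-15)
    expect_identical(m$efficiency, 100 * m$SW / m$PVA)
    expect_identical(m$VAC, m$Ea / m$Ees)
    expect_identical(m$SV, m$EDV - m$ESV)
    expect_true(m$efficiency > 0 && m$efficiency < 100)
    # pressure scaling: energies and elastances scale, ratios do not
    k <- 1.7
    loop <- pv_loop(b$true_pressure$pressure * k, b$volume$volume,
                    time = b$volume$time)
    mk <- pv_metrics(loop)
    expect_equal(mk$SW, k * m$SW, tolerance = 1e-9)
    expect_equal(mk$PE, k * m$PE, tolerance = 1e-9)
    expect_equal(mk$Ees, k * m$Ees, tolerance = 1e-9)
    expect_equal(mk$Ea, k * m$Ea, tolerance = 1e-9)
    expect_equal(mk$VAC, m$VAC, tolerance = 1e-9)
    expect_equal(mk$efficiency, m$efficiency, tolerance = 1e-9)
  }
})

test_that("V0 = 0 elastance is a lower bound on the true-intercept slope", {
  beat <- simulate_beat(sim_params())
  loop <- pv_loop(beat$true_pressure, beat$volume)
  m0 <- pv_metrics(loop, v0 = 0)
  mv <- pv_metrics(loop, v0 = beat$params$V0_sim)
  expect_lt(m0$Ees, mv$Ees)
})

test_that("energetics helper enforces PVA = SW + PE", {
  en <- pv_energetics(13182, 11374)
  expect_identical(en$pva, 24556)
  expect_equal(en$efficiency, 100 * 13182 / 24556)
  expect_error(pv_energetics(-1, 5), "non-negative")
})
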