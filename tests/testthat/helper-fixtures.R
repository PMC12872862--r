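# geometric loop fixtures built in code

# dense axis-aligned rectangle traversed counter-clockwise in (V, P),
# starting at the lower-right corner (EDV, P_low)
rect_loop <- function(v_lo = 60, v_hi = 140, p_lo = 10, p_hi = 110,
                      m = 50, time = TRUE) {
  e <- seq(0, 1, length.out = m + 1)[-(m + 1)]
  v <- c(rep(v_hi, m), v_hi - (v_hi - v_lo) * e, rep(v_lo, m),
         v_lo + (v_hi - v_lo) * e)
  p <- c(p_lo + (p_hi - p_lo) * e, rep(p_hi, m), p_hi - (p_hi - p_lo) * e,
         rep(p_lo, m))
  tm <- if (time) seq_along(v) * 1e-3 else NULL
  pv_loop(p, v, time = tm)
}

# ellipse with semi-axes a (volume) and b (pressure)
ellipse_loop <- function(a = 40, b = 50, v0 = 100, p0 = 60, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  pv_loop(p0 + b * sin(th), v0 + a * cos(th), time = seq_len(n) * 1e-3)
}

# random but valid estimator inputs
random_config <- function() {
  L <- runif(1, 0.6, 1.2)
  mvc <- runif(1, 0, 0.03 * L)
  avo <- runif(1, 0.05, 0.10) * L
  avc <- runif(1, 0.35, 0.45) * L
  mvo <- avc + runif(1, 0.04, 0.08) * L
  dbp <- runif(1, 50, 95)
  sbp <- dbp + runif(1, 30, 90)
  list(events = valve_events(mvc, avo, avc, mvo, L),
       cuff = cuff_pressure(sbp, dbp),
       gradient = runif(1, 0, 70))
}

# ANOVA mean squares via stats::aov, the independent route for ICC oracles
aov_icc <- function(m, model) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  if (model == "oneway_random") {
    tab <- summary(stats::aov(y ~ subject, data = d))[[1]]
    bms <- tab["subject", "Mean Sq"]; wms <- tab["Residuals", "Mean Sq"]
    (bms - wms) / (bms + (k - 1) * wms)
  } else {
    tab <- summary(stats::aov(y ~ subject + rater, data = d))[[1]]
    bms <- tab["subject", "Mean Sq"]; jms <- tab["rater", "Mean Sq"]
    ems <- tab["Residuals", "Mean Sq"]
    if (model == "twoway_mixed_consistency")
      (bms - ems) / (bms + (k - 1) * ems)
    else
      (bms - ems) / (bms + (k - 1) * ems + k * (jms - ems) / n)
  }
}
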