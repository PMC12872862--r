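#' Pressure-strain work of a single myocardial segment
#'
#' Instantaneous myocardial power is `P(t) * (-d strain/dt)` (pressure in mmHg,
#' strain in percent), integrated from mitral valve closure to mitral
#' valve opening. Work is partitioned by phase and direction of
#' deformation: during systole (MVC to AVC) shortening counts as
#' constructive and lengthening as wasted; during isovolumic relaxation
#' (AVC to MVO) lengthening is constructive and shortening wasted. Net
#' segment work is constructive minus wasted.
#'
#' @param p a [pressure_trace()] on the shared grid.
#' @param strain numeric strain vector (%) on the same grid.
#' @param events a [valve_events()].
#' @return list with `constructive`, `wasted`, `net` (mmHg%).
#' @export
segment_work <- function(p, strain, events) {
  stopifnot(inherits(p, "pressure_trace"), inherits(events, "valve_events"))
  tm <- p$time
  if (length(strain) != length(tm))
    stopf("strain (%d samples) is not on the pressure grid (%d samples)",
          length(strain), length(tm), class = "pvloopr_alignment_error")
  dsdt <- centered_gradient(strain, tm)
  power <- p$pressure * (-dsdt)             # > 0 while shortening
  sys <- tm >= events$t_mvc & tm <= events$t_avc
  ivr <- tm > events$t_avc & tm <= events$t_mvo
  constructive <- masked_integral(tm, pmax(power, 0), sys) +
                  masked_integral(tm, pmax(-power, 0), ivr)
  wasted <- masked_integral(tm, pmax(-power, 0), sys) +
            masked_integral(tm, pmax(power, 0), ivr)
  list(constructive = constructive, wasted = wasted,
       net = constructive - wasted)
}

# centered finite differences, one-sided at the ends
centered_gradient <- function(y, x) {
  n <- length(y)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2L)
    g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  g
}

# trapezoid integral of y over the samples where mask is TRUE
masked_integral <- function(x, y, mask) {
  if (sum(mask) < 2L) return(0)
  pracma::trapz(x[mask], y[mask])
}

#' Global myocardial work index from pressure-strain loops
#'
#' Integrates the estimated LV pressure waveform with segmental strain
#' traces: the global work index (GWI) is the mean net segment work, the
#' global constructive (GCW) and wasted (GWW) work are the means of the
#' per-segment components, and global work efficiency is
#' `GWE = 100 * GCW / (GCW + GWW)`.
#'
#' @param p a [pressure_trace()] on the shared grid.
#' @param strains a [strain_traces()] set (>= 1 segment).
#' @param events a [valve_events()].
#' @return Object of class `mwi_metrics`: `GWI`, `GCW`, `GWW` (mmHg%),
#'   `GWE` (%), plus `segments`, a per-segment work table.
#' @export
global_mwi <- function(p, strains, events) {
  stopifnot(inherits(strains, "strain_traces"))
  if (ncol(strains$strain) < 1L) stopf("need at least one strain segment")
  if (length(strains$time) != length(p$time) ||
      max(abs(strains$time - p$time)) > 1e-9)
    stopf("strain set is not on the pressure grid",
          class = "pvloopr_alignment_error")
  per <- lapply(seq_len(ncol(strains$strain)), function(j)
    segment_work(p, strains$strain[, j], events))
  seg <- data.frame(
    segment = strains$segment_ids,
    constructive = vapply(per, `[[`, numeric(1), "constructive"),
    wasted = vapply(per, `[[`, numeric(1), "wasted"),
    net = vapply(per, `[[`, numeric(1), "net"),
    row.names = NULL)
  gcw <- mean(seg$constructive); gww <- mean(seg$wasted)
  structure(list(GWI = mean(seg$net), GCW = gcw, GWW = gww,
                 GWE = mw_efficiency(gcw, gww), segments = seg),
            class = "mwi_metrics")
}

#' Myocardial work efficiency
#'
#' `100 * GCW / (GCW + GWW)` (%), the arithmetic shared by [global_mwi()]
#' and cohort summaries.
#'
#' @param gcw constructive work (mmHg%), >= 0.
#' @param gww wasted work (mmHg%), >= 0.
#' @return efficiency in percent, in `[0, 100]`.
#' @export
mw_efficiency <- function(gcw, gww) {
  if (any(gcw < 0) || any(gww < 0)) stopf("gcw and gww must be non-negative")
  if (any(gcw + gww == 0)) stopf("no myocardial work performed")
  100 * gcw / (gcw + gww)
}

#' @export
print.mwi_metrics <- function(x, ...) {
  cat(sprintf(paste0("Myocardial work index (%d segments)\n",
                     "  GWI %9.4g mmHg%%   GCW %9.4g mmHg%%\n",
                     "  GWW %9.4g mmHg%%   GWE %9.4g %%\n"),
              nrow(x$segments), x$GWI, x$GCW, x$GWW, x$GWE))
  invisible(x)
}
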