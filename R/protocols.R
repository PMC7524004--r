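# Timed protocol events: seizure initiation (intracortical excitability ramp,
# trigeminal drive, low-frequency cortical stimulation), maintenance, and
# termination by high-frequency stimulation.

new_event <- function(kind, t_start, t_end, ...) {
  if (!(t_start >= 0 && t_end > t_start))
    stop("protocol event must have 0 <= t_start < t_end")
  structure(c(list(kind = kind, t_start = t_start, t_end = t_end),
              list(...)),
            class = "swd_event")
}

#' @export
print.swd_event <- function(x, ...) {
  cat(sprintf("<swd_event> %s [%.3f, %.3f) s\n", x$kind, x$t_start, x$t_end))
  invisible(x)
}

#' Seizure initiation by intracortical excitability increase
#'
#' A preictal increase of intracortical excitability: all couplings between
#' focal PY nodes are ramped linearly from their basic value (0.1) up by
#' `factor` (default 1.15, i.e. to 0.115) over `duration_s` (default 0.3 s),
#' after which they return instantly to baseline. Seizures elicited this way
#' start right after the ramp ends.
#'
#' @param t0 ramp start, seconds on the simulation time axis.
#' @param duration_s ramp length in seconds.
#' @param factor multiplicative end value of the ramp.
#' @param region region of the PY nodes involved (default focal).
#' @return an `swd_event` of kind `coupling_scale`.
#' @export
protocol_excitability <- function(t0, duration_s = 0.3, factor = 1.15,
                                  region = "focal") {
  new_event("coupling_scale", t0, t0 + duration_s,
            source_population = "PY", source_region = region,
            target_population = "PY", target_region = region,
            factor = factor, ramp = "linear")
}

#' Seizure initiation by trigeminal drive
#'
#' Steps all couplings from the trigeminal input (NT) onto thalamocortical
#' relay (TC) nodes from 0.1 to `0.1 * factor` (default factor 2, i.e. 0.2)
#' for `duration_s` (default 0.3 s), then restores baseline.
#'
#' @inheritParams protocol_excitability
#' @export
protocol_trigeminal <- function(t0, duration_s = 0.3, factor = 2) {
  new_event("coupling_scale", t0, t0 + duration_s,
            source_population = "NT", source_region = NULL,
            target_population = "TC", target_region = NULL,
            factor = factor, ramp = "step")
}

#' Seizure initiation by low-frequency cortical stimulation
#'
#' Adds a sinusoidal drive (default amplitude 1 model unit at 8 Hz in
#' renormalized time, phase zero at `t0`) to the x-equation of all cortical
#' nodes (PY and IN) for `duration_s` (default 0.3 s). Seizures elicited this
#' way start within the stimulation window.
#'
#' @inheritParams protocol_excitability
#' @param amplitude drive amplitude, model units.
#' @param freq_hz sinusoid frequency in renormalized time, Hz.
#' @param populations stimulated populations (default PY and IN).
#' @param region region restriction (`NULL` = all regions).
#' @export
protocol_lowfreq <- function(t0, duration_s = 0.3, amplitude = 1,
                             freq_hz = 8, populations = c("PY", "IN"),
                             region = NULL) {
  new_event("additive_sinusoid", t0, t0 + duration_s,
            populations = populations, region = region,
            amplitude = amplitude, freq_hz = freq_hz)
}

#' Seizure maintenance process
#'
#' A longer-lasting coupling increase that sustains an ongoing discharge:
#' the magnitude of all couplings from reticular thalamic (RE) nodes onto
#' cortical nodes (PY and IN) is stepped from 0.1 to `0.1 * factor` (default
#' 0.115) for `duration_s` (default 5 s), starting `delay_s` (default 1 s,
#' physiological range 0.5 to 1.5 s) after the detected seizure onset. Signs
#' are preserved: inhibitory weights scale to -0.115.
#'
#' @param t_onset detected seizure onset, seconds.
#' @param delay_s lag between onset and the start of the maintenance process.
#' @param duration_s length of the coupling increase, seconds.
#' @param factor multiplicative increase of the weight magnitude.
#' @param source_population,target_populations edge set to scale; the default
#'   follows the reticular-to-cortex pathway. An alternative cortico-thalamic
#'   variant can be selected with `source_population = "PY"`,
#'   `target_populations = "TC"`.
#' @export
protocol_maintenance <- function(t_onset, delay_s = 1, duration_s = 5,
                                 factor = 1.15,
                                 source_population = "RE",
                                 target_populations = c("PY", "IN")) {
  new_event("coupling_scale", t_onset + delay_s,
            t_onset + delay_s + duration_s,
            source_population = source_population, source_region = NULL,
            target_population = target_populations, target_region = NULL,
            factor = factor, ramp = "step")
}

#' Seizure termination by high-frequency stimulation
#'
#' A rectangular pulse train applied to the x-equation of all focal cortical
#' nodes (PY and IN): amplitude 1 model unit, pulse width 0.6 ms, pulse rate
#' 130 Hz, total length 1 s. A variant with an 8 ms interpulse gap (~116 Hz)
#' is available through `period_s`.
#'
#' @param t_stim stimulation start, seconds (typically seizure onset + 4 s).
#' @param duration_s stimulation length, seconds.
#' @param amplitude pulse amplitude, model units.
#' @param rate_hz pulse rate; the pulse period is `1 / rate_hz` unless
#'   `period_s` is given.
#' @param width_s single pulse width, seconds.
#' @param period_s explicit pulse period in seconds, overriding `rate_hz`
#'   (e.g. `width_s + 8e-3` for the fixed-gap variant).
#' @param populations,region stimulated node set (default focal PY and IN).
#' @export
protocol_hfs <- function(t_stim, duration_s = 1, amplitude = 1,
                         rate_hz = 130, width_s = 0.6e-3, period_s = NULL,
                         populations = c("PY", "IN"), region = "focal") {
  if (is.null(period_s)) period_s <- 1 / rate_hz
  new_event("additive_pulse_train", t_stim, t_stim + duration_s,
            populations = populations, region = region,
            amplitude = amplitude, period_s = period_s, width_s = width_s)
}

# ---- compilation to integrator form ----------------------------------------

# sparse delta matrix holding the base values of the selected edge set
edge_subset <- function(m, target_population, target_region,
                        source_population, source_region) {
  T <- as(m$C, "TsparseMatrix")
  tgt <- layout_indices(m$layout, target_population, target_region)
  src <- layout_indices(m$layout, source_population, source_region)
  keep <- (T@i + 1L) %in% tgt & (T@j + 1L) %in% src
  Matrix::sparseMatrix(i = T@i[keep] + 1L, j = T@j[keep] + 1L,
                       x = T@x[keep], dims = dim(m$C))
}

compile_protocol <- function(protocol, m, f_samp, burn_steps, duration_s) {
  scale <- list()
  drive <- list()
  for (ev in protocol) {
    if (!inherits(ev, "swd_event")) stop("protocol entries must be swd_event")
    if (ev$t_end > duration_s + 1e-9)
      stop(sprintf("protocol event [%g, %g) extends beyond the %g s window",
                   ev$t_start, ev$t_end, duration_s))
    start_step <- burn_steps + round(ev$t_start * f_samp)
    end_step <- burn_steps + round(ev$t_end * f_samp)
    if (ev$kind == "coupling_scale") {
      D <- edge_subset(m, ev$target_population, ev$target_region,
                       ev$source_population, ev$source_region)
      if (length(D@x) == 0L)
        warning(sprintf("coupling_scale event targets no edges (%s -> %s)",
                        paste(ev$source_population, collapse = "/"),
                        paste(ev$target_population, collapse = "/")))
      scale[[length(scale) + 1L]] <- list(
        D = D, start_step = start_step, end_step = end_step,
        g0 = 0, g1 = ev$factor - 1, linear = identical(ev$ramp, "linear"))
    } else if (ev$kind == "additive_sinusoid") {
      nodes <- layout_indices(m$layout, ev$populations, ev$region)
      drive[[length(drive) + 1L]] <- list(
        nodes = nodes - 1L, kind = 0L, amplitude = ev$amplitude,
        omega = 2 * pi * ev$freq_hz / f_samp, period = 1, width = 0,
        start_step = start_step, end_step = end_step)
    } else if (ev$kind == "additive_pulse_train") {
      nodes <- layout_indices(m$layout, ev$populations, ev$region)
      drive[[length(drive) + 1L]] <- list(
        nodes = nodes - 1L, kind = 1L, amplitude = ev$amplitude,
        omega = 0, period = ev$period_s * f_samp,
        width = max(1, round(ev$width_s * f_samp)),
        start_step = start_step, end_step = end_step)
    } else stop("unknown protocol event kind: ", ev$kind)
  }
  list(scale = scale, drive = drive)
}

#' Effective scaled weight of a coupling-scale event at a given time
#'
#' Evaluates what multiple of its baseline value an affected weight takes at
#' time `t`: 1 outside the event, the target factor during a step event, and
#' the linear interpolant during a ramp (so an excitability ramp from 0.1 to
#' 0.115 passes 0.1075 at its midpoint).
#'
#' @param event an `swd_event` of kind `coupling_scale`.
#' @param t time in seconds.
#' @return the scale factor applied to baseline weights at `t`.
#' @export
event_scale_factor <- function(event, t) {
  stopifnot(inherits(event, "swd_event"),
            identical(event$kind, "coupling_scale"))
  vapply(t, function(ti) {
    if (ti < event$t_start || ti >= event$t_end) return(1)
    if (identical(event$ramp, "step")) return(event$factor)
    frac <- (ti - event$t_start) / (event$t_end - event$t_start)
    1 + (event$factor - 1) * frac
  }, numeric(1))
}
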