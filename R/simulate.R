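# Integration front end: configuration, initial conditions, protocol
# compilation, and the SimulationResult container.

#' Sigmoid coupling function
#'
#' The synaptic transfer function applied to the delayed presynaptic state,
#' `h(x) = (1 + tanh(x)) / 2`. Monotone increasing, with values in (0, 1) and
#' `h(0) = 0.5`.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
fhn_coupling <- function(x) (1 + tanh(x)) / 2

#' Renormalized sampling frequency
#'
#' The model is integrated with an Euler step `dt_model` in model time and
#' the time axis is then renormalized by `time_scale`, so one Euler step
#' spans `dt_model * time_scale` seconds. At the defaults (0.5 and 1/1700)
#' this gives 3400 Hz, placing the network's oscillations in the frequency
#' range of rodent spike-and-wave discharges.
#'
#' @param dt_model Euler step in model time units (default 0.5).
#' @param time_scale renormalization ratio (default 1/1700).
#' @return sampling frequency in Hz.
#' @export
#' @examples
#' sampling_frequency()       # 3400
#' 9 / sampling_frequency()   # a 9-step delay ~ 2.6 ms
sampling_frequency <- function(dt_model = 0.5, time_scale = 1 / 1700) {
  stopifnot(dt_model > 0, time_scale > 0)
  1 / (dt_model * time_scale)
}

# indicator weight matrix mapping node states to per-compartment sums
compartment_weights <- function(layout) {
  n <- attr(layout, "n_total")
  k <- nrow(layout)
  W <- matrix(0, n, k)
  for (r in seq_len(k))
    W[seq.int(layout$first[r], layout$last[r]), r] <- 1
  colnames(W) <- paste(layout$population, layout$region, sep = ".")
  W
}

#' Simulate the delay-coupled FitzHugh-Nagumo network
#'
#' Integrates the network defined by a coupling matrix with the explicit
#' Euler method. Every node follows
#' `dx/dt = x(a - x)(x - 1) - y + sum_j C[i,j] h(x_j(t - tau)) + drive`,
#' `dy/dt = b x - gamma y`, with the sigmoid coupling [fhn_coupling()] applied
#' to the presynaptic state delayed by `tau_steps` Euler steps. The
#' integration is fully deterministic given the matrix, the configuration and
#' the seed; identical inputs give bit-identical output.
#'
#' A burn-in period is simulated before time zero and discarded, so that the
#' returned series starts in established activity; protocol event times are
#' relative to the returned time axis.
#'
#' @param m an `swd_matrix`.
#' @param duration_s length of the returned series, seconds.
#' @param protocol list of protocol events (see [protocol_excitability()] and
#'   friends), applied at exact sample indices.
#' @param a,b,gamma FitzHugh-Nagumo node parameters (defaults 0.8, 0.008,
#'   0.0033, identical for all nodes).
#' @param dt_model,time_scale Euler step and time renormalization; see
#'   [sampling_frequency()].
#' @param burn_in_s discarded initial transient, seconds (default 2).
#' @param seed seed for the random initial state.
#' @param init `"random"` (default): x and y drawn uniformly from
#'   `[-init_amplitude, init_amplitude]` around the resting state;
#'   `"rest"`: all nodes exactly at the origin; `"surround"`: random ignition
#'   state in the surrounding region only, all focal and external nodes at
#'   rest (establishes interictal background while the focal subnetwork
#'   stays quiescent).
#' @param init_amplitude half-width of the random initial state (default 1).
#'   The default is an "ignition" initialization: it starts a fraction of the
#'   nodes above firing threshold, which is required to reach the
#'   self-sustained irregular (interictal) regime; small perturbations around
#'   the origin always relax back to the stable resting state.
#' @param init_state optional list with numeric vectors `x` and `y` (length
#'   `n_total`) overriding `init`; used for twin runs continuing from a saved
#'   state.
#' @param record_nodes also return the full per-node x trajectories.
#' @param record_y also return per-node y trajectories (implies full
#'   recording of y).
#' @param record_final also return the exact final state (`final_state`),
#'   suitable as `init_state` of a continuation run.
#' @return an object of class `swd_sim`: `time` (seconds), `channels`
#'   (matrix of per-compartment summed activity, one column per compartment),
#'   optional `x`, `y` (sample-by-node matrices), `f_samp`, `layout`,
#'   `tau_steps`, the applied `protocol`, and the configuration.
#' @export
simulate_network <- function(m, duration_s, protocol = list(),
                             a = 0.8, b = 0.008, gamma = 0.0033,
                             dt_model = 0.5, time_scale = 1 / 1700,
                             burn_in_s = 2, seed = 1L,
                             init = c("random", "rest", "surround"),
                             init_amplitude = 1, init_state = NULL,
                             record_nodes = FALSE, record_y = FALSE,
                             record_final = FALSE) {
  stopifnot(inherits(m, "swd_matrix"))
  init <- match.arg(init)
  if (duration_s <= 0) stop("duration_s must be positive")
  f_samp <- sampling_frequency(dt_model, time_scale)
  n_out <- round(duration_s * f_samp)
  if (n_out < 2L) stop("duration_s too short for the sampling frequency")
  burn_steps <- round(burn_in_s * f_samp)
  n_steps <- burn_steps + n_out - 1L
  n <- attr(m$layout, "n_total")

  state0 <- if (!is.null(init_state)) {
    stopifnot(is.list(init_state), length(init_state$x) == n,
              length(init_state$y) == n)
    list(x = as.numeric(init_state$x), y = as.numeric(init_state$y))
  } else if (init == "rest") {
    list(x = numeric(n), y = numeric(n))
  } else {
    st <- with_seed(seed, list(
      x = stats::runif(n, -init_amplitude, init_amplitude),
      y = stats::runif(n, -init_amplitude, init_amplitude)
    ))
    if (init == "surround") {
      quiet <- layout_indices(m$layout, region = c("focal", "external"))
      st$x[quiet] <- 0
      st$y[quiet] <- 0
    }
    st
  }

  compiled <- compile_protocol(protocol, m, f_samp, burn_steps, duration_s)
  W <- compartment_weights(m$layout)

  raw <- simulate_fhn_cpp(
    C = m$C, tau_steps = m$tau_steps,
    a = a, b = b, gamma_ = gamma, dt = dt_model,
    x0 = state0$x, y0 = state0$y, n_steps = n_steps,
    scale_events = compiled$scale, drive_events = compiled$drive,
    channel_weights = W,
    record_x = record_nodes, record_y = record_y,
    record_from = burn_steps
  )

  channels <- raw[["channels"]]
  colnames(channels) <- colnames(W)
  structure(list(
    time = (seq_len(n_out) - 1L) / f_samp,
    channels = channels,
    x = raw[["x"]], y = raw[["y"]],
    final_state = if (record_final)
      list(x = raw[["x_final"]], y = raw[["y_final"]]),
    f_samp = f_samp, layout = m$layout, tau_steps = m$tau_steps,
    protocol = protocol,
    config = list(a = a, b = b, gamma = gamma, dt_model = dt_model,
                  time_scale = time_scale, burn_in_s = burn_in_s,
                  duration_s = duration_s, seed = seed, init = init,
                  init_amplitude = init_amplitude)
  ), class = "swd_sim")
}

#' @export
print.swd_sim <- function(x, ...) {
  cat(sprintf(
    "<swd_sim> %d nodes, %.2f s at %g Hz, %d protocol event(s)\n",
    attr(x$layout, "n_total"), length(x$time) / x$f_samp, x$f_samp,
    length(x$protocol)))
  invisible(x)
}
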