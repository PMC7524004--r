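# Candidate-matrix screening: surrounding matrices must produce sustained
# chaotic background without a dominant spectral peak; focal matrices must
# produce a seizure in response to the intracortical excitability ramp that
# then terminates spontaneously.

#' Screening criteria
#'
#' Operational thresholds of the matrix-selection procedure. The qualitative
#' selection requirements — surrounding matrices producing chaotic dynamics
#' without a well-established main frequency, and focal matrices able to
#' generate spontaneously terminating SWDs in response to a short increase
#' of intracortical excitability — are operationalized as follows.
#'
#' A surrounding candidate is accepted when its cortical signal is still
#' active (standard deviation above `min_sd`) at the end of a
#' `sim_length_s` run and its spectral prominence ([spectral_prominence()])
#' stays below `prominence_threshold`.
#'
#' A focal candidate is accepted when (i) without any protocol its
#' post-ignition transient dies out (quiescent background), (ii) the
#' excitability ramp applied at `ramp_time_s` elicits a discharge that
#' outlives the protocol-free twin run by at least `min_discharge_s`,
#' (iii) the discharge terminates spontaneously
#' within `max_duration_s`, and (iv) its dominant frequency lies in
#' `swd_band`.
#'
#' @param prominence_threshold maximum allowed spectral prominence of an
#'   accepted surrounding matrix.
#' @param min_sd amplitude floor (standard deviation of the summed cortical
#'   signal over 0.5 s bins, model units) distinguishing activity from the
#'   quiescent fixed point.
#' @param max_duration_s longest discharge still counted as spontaneously
#'   terminating, seconds.
#' @param sim_length_s screening simulation length per candidate (after
#'   burn-in for surrounding candidates), seconds.
#' @param ramp_time_s start of the excitability ramp in the focal test,
#'   seconds from ignition.
#' @param min_discharge_s minimum elicited-discharge length, seconds.
#' @param swd_band acceptable dominant-frequency band of the discharge, Hz.
#' @return a list of class `swd_criteria`.
#' @export
screening_criteria <- function(prominence_threshold = 0.1, min_sd = 0.05,
                               max_duration_s = 60, sim_length_s = 20,
                               ramp_time_s = 0.8, min_discharge_s = 0.5,
                               swd_band = c(4, 12)) {
  stopifnot(prominence_threshold > 0, min_sd > 0, max_duration_s > 0,
            sim_length_s > 0, min_discharge_s > 0)
  structure(list(prominence_threshold = prominence_threshold,
                 min_sd = min_sd, max_duration_s = max_duration_s,
                 sim_length_s = sim_length_s, ramp_time_s = ramp_time_s,
                 min_discharge_s = min_discharge_s, swd_band = swd_band),
            class = "swd_criteria")
}

# summed cortical (PY + IN) signal of a simulation
cortex_sum <- function(sim) {
  ch <- sim$channels
  cols <- grep("^(PY|IN)\\.", colnames(ch))
  rowSums(ch[, cols, drop = FALSE])
}

# standard deviation of consecutive 0.5 s bins
bin_sd <- function(x, f_samp, bin_s = 0.5) {
  nb <- floor(length(x) / (bin_s * f_samp))
  vapply(seq_len(nb) - 1L,
         function(t) stats::sd(x[(t * bin_s * f_samp + 1L):
                                   ((t + 1) * bin_s * f_samp)]),
         numeric(1))
}

#' Classify a surrounding-area candidate matrix
#'
#' Simulates the candidate from the ignition initial state and accepts it if
#' the cortical signal is non-decaying over the whole run and shows no
#' dominant spectral peak (chaotic broadband background).
#'
#' @param m an `swd_matrix` on a surrounding layout.
#' @param criteria an [screening_criteria()] object.
#' @param seed seed of the initial state.
#' @return list with `accept` (logical) and `report` (decision, reason and
#'   the measured statistics).
#' @export
classify_surrounding <- function(m, criteria = screening_criteria(),
                                 seed = 1L) {
  stopifnot(inherits(m, "swd_matrix"), inherits(criteria, "swd_criteria"))
  if (any(m$layout$region != "surrounding"))
    stop("classify_surrounding() expects a surrounding-only matrix")
  sim <- tryCatch(
    simulate_network(m, criteria$sim_length_s, seed = seed),
    error = function(e) e)
  if (inherits(sim, "error")) {
    return(list(accept = FALSE,
                report = list(decision = "reject",
                              reason = paste("blow-up:",
                                             conditionMessage(sim)),
                              sd_last = NA, prominence = NA,
                              dominant_freq = NA)))
  }
  cx <- cortex_sum(sim)
  f <- sim$f_samp
  sd_last <- stats::sd(cx[(length(cx) - f):length(cx)])
  prom <- spectral_prominence(cx, f)
  domf <- dominant_frequency(cx - mean(cx), f)
  reason <- if (sd_last < criteria$min_sd) "decaying"
    else if (is.na(prom)) "flat spectrum"
    else if (prom > criteria$prominence_threshold) "dominant peak"
    else "accept"
  list(accept = reason == "accept",
       report = list(decision = if (reason == "accept") "accept" else
                       "reject",
                     reason = reason, sd_last = sd_last,
                     prominence = prom, dominant_freq = domf))
}

#' Classify a focal-area candidate matrix
#'
#' Tests whether the intracortical excitability ramp elicits a
#' spontaneously terminating discharge. The candidate is simulated from the
#' ignition initial state with the ramp applied at `criteria$ramp_time_s`
#' and, as a twin, without any protocol. Acceptance requires a quiescent
#' twin, an elicited discharge of at least `min_discharge_s` beyond the
#' twin's settling time, spontaneous termination within `max_duration_s`,
#' and a dominant frequency within `swd_band`.
#'
#' @param m an `swd_matrix` on a focal (+NT) layout.
#' @param criteria an [screening_criteria()] object.
#' @param seed seed of the initial state.
#' @return list with `accept` and `report` (onset, offset, duration and
#'   dominant frequency of the elicited discharge, when there is one).
#' @export
classify_focal <- function(m, criteria = screening_criteria(), seed = 1L) {
  stopifnot(inherits(m, "swd_matrix"), inherits(criteria, "swd_criteria"))
  if (any(m$layout$region == "surrounding"))
    stop("classify_focal() expects a focal(+NT) matrix")
  rej <- function(reason, ...) list(
    accept = FALSE, report = c(list(decision = "reject", reason = reason),
                               list(...)))
  ramp <- protocol_excitability(criteria$ramp_time_s)
  onset <- criteria$ramp_time_s + 0.3
  probe_s <- min(12, criteria$max_duration_s)
  s1 <- tryCatch(simulate_network(m, probe_s, protocol = list(ramp),
                                  seed = seed, burn_in_s = 0),
                 error = function(e) e)
  if (inherits(s1, "error")) return(rej(paste("blow-up:",
                                              conditionMessage(s1))))
  f <- s1$f_samp
  off1 <- activity_offset(s1, criteria$min_sd)

  s0 <- tryCatch(simulate_network(m, probe_s, seed = seed, burn_in_s = 0),
                 error = function(e) e)
  if (inherits(s0, "error")) return(rej(paste("blow-up:",
                                              conditionMessage(s0))))
  off0 <- activity_offset(s0, criteria$min_sd)
  if (off0 > 3)
    return(rej("background not quiescent", twin_offset_s = off0))
  if (off1 - max(off0, onset) < criteria$min_discharge_s)
    return(rej("no elicited discharge", offset_s = off1,
               twin_offset_s = off0))

  offset <- off1
  if (off1 > probe_s - 0.5) {
    # discharge outlives the probe: rerun to the termination budget
    sL <- tryCatch(simulate_network(m, criteria$max_duration_s + 5,
                                    protocol = list(ramp), seed = seed,
                                    burn_in_s = 0),
                   error = function(e) e)
    if (inherits(sL, "error")) return(rej(paste("blow-up:",
                                                conditionMessage(sL))))
    offset <- activity_offset(sL, criteria$min_sd)
    if (offset > criteria$max_duration_s)
      return(rej("no spontaneous termination", offset_s = offset))
    s1 <- sL
  }
  duration <- offset - onset
  cx <- cortex_sum(s1)
  seg <- cx[round(onset * f):round(offset * f)]
  domf <- dominant_frequency(seg - mean(seg), f)
  if (is.na(domf) || domf < criteria$swd_band[1] ||
      domf > criteria$swd_band[2])
    return(rej("dominant frequency outside SWD band", dominant_freq = domf))
  list(accept = TRUE,
       report = list(decision = "accept", reason = "accept",
                     onset_s = onset, offset_s = offset,
                     duration_s = duration, dominant_freq = domf))
}

#' Screen a batch of candidate matrices
#'
#' Generates `n_candidates` random matrices with per-candidate seeds and
#' delays derived deterministically from the master seed, classifies each
#' with [classify_focal()] or [classify_surrounding()], and returns the
#' accepted matrices together with a per-candidate report. Reruns with the
#' same master seed reproduce the same accepted set.
#'
#' @param n_candidates number of candidates (>= 1).
#' @param kind `"focal"` or `"surrounding"`.
#' @param criteria an [screening_criteria()] object.
#' @param probs connection probability table.
#' @param seed master seed.
#' @param tau_choices coupling delays sampled per candidate, in steps.
#' @param layout layout used for the candidates.
#' @return list with `accepted` (list of `swd_matrix`), `reports` (data
#'   frame, one row per candidate) and `acceptance_rate`.
#' @export
screen_batch <- function(n_candidates, kind = c("focal", "surrounding"),
                         criteria = screening_criteria(),
                         probs = coupling_probabilities(), seed = 1L,
                         tau_choices = 9:13,
                         layout = network_layout(kind)) {
  kind <- match.arg(kind)
  if (n_candidates < 1) stop("n_candidates must be >= 1")
  draws <- with_seed(seed, list(
    mat_seed = sample.int(.Machine$integer.max - 1L, n_candidates),
    ic_seed = sample.int(.Machine$integer.max - 1L, n_candidates),
    tau = sample(tau_choices, n_candidates, replace = TRUE)
  ))
  classify <- if (kind == "focal") classify_focal else classify_surrounding
  accepted <- list()
  reports <- vector("list", n_candidates)
  for (k in seq_len(n_candidates)) {
    m <- apply_collaterals(sample_matrix(layout, probs,
                                         tau_steps = draws$tau[k],
                                         seed = draws$mat_seed[k]))
    cl <- classify(m, criteria, seed = draws$ic_seed[k])
    reports[[k]] <- data.frame(
      candidate = k, matrix_seed = draws$mat_seed[k],
      ic_seed = draws$ic_seed[k], tau_steps = draws$tau[k],
      decision = cl$report$decision, reason = cl$report$reason,
      stringsAsFactors = FALSE)
    if (cl$accept) accepted[[length(accepted) + 1L]] <- m
  }
  list(accepted = accepted, reports = do.call(rbind, reports),
       acceptance_rate = length(accepted) / n_candidates)
}

#' Pair accepted focal and surrounding matrices
#'
#' Composes every focal matrix with every surrounding matrix that shares the
#' same coupling delay (matrices with different delays are never paired).
#'
#' @param focal,surround lists of accepted `swd_matrix` objects.
#' @param probs probability table for the cross-region couplings.
#' @param seed seed for the cross-block sampling.
#' @return list of composed `swd_matrix` objects (possibly empty).
#' @export
pair_matrices <- function(focal, surround,
                          probs = coupling_probabilities(), seed = 1L) {
  out <- list()
  k <- 0L
  for (mf in focal) for (ms in surround) {
    if (mf$tau_steps != ms$tau_steps) next
    k <- k + 1L
    out[[length(out) + 1L]] <- compose_network(mf, ms, probs,
                                               seed = seed + k)
  }
  out
}
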