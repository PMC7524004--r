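# High-level seizure experiments on screened matrices: elicited discharges,
# duration statistics, maintenance effect, high-frequency stimulation, and
# the onset-aligned peri-ictal coupling analysis.

#' Accepted screening candidates shipped with the package
#'
#' A small table of (kind, matrix seed, delay) triplets found by running the
#' screening pipeline at full budget (7000 focal candidates, 200 surrounding
#' candidates). Matrices are regenerated deterministically from the seeds;
#' no matrix data is stored.
#'
#' @return data frame with columns `kind`, `seed`, `tau_steps`.
#' @export
accepted_candidates <- function() {
  path <- system.file("extdata", "accepted_candidates.tsv",
                      package = "swdnet")
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Rebuild an accepted candidate matrix from its shipped seed
#'
#' @param kind `"focal"` or `"surrounding"`.
#' @param index row among the shipped candidates of that kind.
#' @return an `swd_matrix`.
#' @export
fixture_matrix <- function(kind = c("focal", "surrounding"), index = 1L) {
  kind <- match.arg(kind)
  cand <- accepted_candidates()
  cand <- cand[cand$kind == kind, ]
  if (index < 1L || index > nrow(cand)) stop("no such candidate")
  apply_collaterals(sample_matrix(network_layout(kind),
                                  tau_steps = cand$tau_steps[index],
                                  seed = cand$seed[index]))
}

# last time (s) the summed cortical signal is active, by binned SD
activity_offset <- function(sim, floor = 0.05, bin_s = 0.25) {
  b <- bin_sd(cortex_sum(sim), sim$f_samp, bin_s)
  bin_s * max(c(0, which(b > floor)))
}

# first time (s) at/after `from` that the summed cortical signal is active
activity_onset <- function(sim, from = 0, floor = 0.05, bin_s = 0.25) {
  b <- bin_sd(cortex_sum(sim), sim$f_samp, bin_s)
  k0 <- max(1L, ceiling(from / bin_s))
  act <- which(b > floor)
  act <- act[act >= k0]
  if (length(act) == 0L) return(NA_real_)
  bin_s * (act[1L] - 1L)
}

#' Elicit one seizure on a focal matrix
#'
#' Runs the matrix from the ignition initial state with the excitability ramp
#' at `t_ramp` (while the ignition transient is still alive), optionally with
#' the maintenance process and a high-frequency stimulation train, and
#' measures the discharge span with the amplitude criterion used by the
#' screening (the interictal state of an accepted focal matrix is the exact
#' resting state, so an absolute amplitude floor separates discharge from
#' rest). The protocol-free twin run from the same initial state provides the
#' reference settling time.
#'
#' @param m an accepted focal `swd_matrix`.
#' @param seed initial-state seed; one seed per seizure.
#' @param t_ramp ramp start, seconds.
#' @param maintenance apply the maintenance process.
#' @param maintenance_delay_s lag of the maintenance onset after the seizure
#'   onset, seconds (physiological range 0.5 to 1.5).
#' @param hfs_at if non-`NULL`, start of a high-frequency stimulation train,
#'   in seconds after seizure onset.
#' @param duration_s simulated span, seconds.
#' @param floor amplitude floor of the discharge criterion (SD of the summed
#'   cortical signal in 0.25 s bins, model units).
#' @return list with `onset_s` (end of the ramp), `offset_s`, `duration_s`,
#'   `twin_offset_s`, `elicited` (offset clearly beyond the twin's), and the
#'   two simulations (`run`, `twin`).
#' @export
seizure_run <- function(m, seed = 1L, t_ramp = 0.8, maintenance = TRUE,
                        maintenance_delay_s = 1, hfs_at = NULL,
                        duration_s = 20, floor = 0.05) {
  onset <- t_ramp + 0.3
  protocol <- list(protocol_excitability(t_ramp))
  if (maintenance)
    protocol <- c(protocol, list(protocol_maintenance(
      onset, delay_s = maintenance_delay_s)))
  if (!is.null(hfs_at))
    protocol <- c(protocol, list(protocol_hfs(onset + hfs_at)))
  twin <- simulate_network(m, min(duration_s, 8), seed = seed,
                           burn_in_s = 0)
  run <- simulate_network(m, duration_s, protocol = protocol, seed = seed,
                          burn_in_s = 0)
  off <- activity_offset(run, floor)
  twin_off <- activity_offset(twin, floor)
  list(onset_s = onset, offset_s = off,
       duration_s = off - onset, twin_offset_s = twin_off,
       elicited = off > max(twin_off, onset + 0.25) ,
       run = run, twin = twin)
}

#' Seizure-duration experiment
#'
#' Elicits `n_seizures` discharges per matrix (one initial-state seed per
#' seizure, maintenance delay drawn uniformly from its physiological 0.5 to
#' 1.5 s window) and pools the durations.
#'
#' @param matrices list of accepted focal `swd_matrix` objects.
#' @param n_seizures seizures per matrix.
#' @param seed master seed.
#' @param maintenance apply the maintenance process (default `TRUE`).
#' @param duration_s simulated span per seizure, seconds.
#' @return data frame with one row per elicited seizure: `matrix`, `seed`,
#'   `duration_s`, plus the attribute `stats` from [swd_duration_stats()].
#' @export
swd_duration_experiment <- function(matrices, n_seizures = 10, seed = 1L,
                                    maintenance = TRUE, duration_s = 20) {
  draws <- with_seed(seed, list(
    ic = matrix(sample.int(.Machine$integer.max - 1L,
                           length(matrices) * n_seizures),
                nrow = length(matrices)),
    delay = matrix(stats::runif(length(matrices) * n_seizures, 0.5, 1.5),
                   nrow = length(matrices))
  ))
  rows <- list()
  for (i in seq_along(matrices)) {
    for (j in seq_len(n_seizures)) {
      sz <- seizure_run(matrices[[i]], seed = draws$ic[i, j],
                        maintenance = maintenance,
                        maintenance_delay_s = draws$delay[i, j],
                        duration_s = duration_s)
      if (!sz$elicited) next
      rows[[length(rows) + 1L]] <- data.frame(
        matrix = i, seed = draws$ic[i, j], duration_s = sz$duration_s)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "stats") <- swd_duration_stats(out$duration_s)
  out
}

#' Maintenance-effect experiment
#'
#' For each seizure, runs the deterministic twin pair with and without the
#' maintenance process from the identical initial state and reports the
#' duration ratio.
#'
#' @inheritParams swd_duration_experiment
#' @return data frame with `matrix`, `seed`, `dur_with_s`, `dur_without_s`,
#'   `ratio`.
#' @export
maintenance_effect_experiment <- function(matrices, n_seizures = 5,
                                          seed = 1L) {
  ics <- with_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1L, length(matrices) * n_seizures),
    nrow = length(matrices)))
  rows <- list()
  for (i in seq_along(matrices)) {
    for (j in seq_len(n_seizures)) {
      with_m <- seizure_run(matrices[[i]], seed = ics[i, j],
                            maintenance = TRUE)
      without <- seizure_run(matrices[[i]], seed = ics[i, j],
                             maintenance = FALSE, duration_s = 12)
      if (!without$elicited) next
      rows[[length(rows) + 1L]] <- data.frame(
        matrix = i, seed = ics[i, j],
        dur_with_s = with_m$duration_s,
        dur_without_s = without$duration_s,
        ratio = with_m$duration_s / without$duration_s)
    }
  }
  do.call(rbind, rows)
}

#' High-frequency-stimulation experiment
#'
#' Stimulated seizures (130 Hz cortical pulse train starting `hfs_after_s`
#' after onset) are compared with their unstimulated twins. A seizure counts
#' as terminated when its offset falls before the end of stimulation plus
#' 0.5 s and is earlier than the twin's offset.
#'
#' @inheritParams swd_duration_experiment
#' @param hfs_after_s stimulation start after seizure onset, seconds.
#' @return data frame with per-seizure offsets and the logical `terminated`;
#'   attribute `terminated_fraction`.
#' @export
hfs_experiment <- function(matrices, n_seizures = 10, seed = 1L,
                           hfs_after_s = 4) {
  ics <- with_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1L, length(matrices) * n_seizures),
    nrow = length(matrices)))
  rows <- list()
  for (i in seq_along(matrices)) {
    for (j in seq_len(n_seizures)) {
      base <- seizure_run(matrices[[i]], seed = ics[i, j],
                          maintenance = TRUE)
      if (!base$elicited) next
      stim <- seizure_run(matrices[[i]], seed = ics[i, j],
                          maintenance = TRUE, hfs_at = hfs_after_s)
      stim_end <- base$onset_s + hfs_after_s + 1
      rows[[length(rows) + 1L]] <- data.frame(
        matrix = i, seed = ics[i, j],
        offset_unstim_s = base$offset_s, offset_stim_s = stim$offset_s,
        terminated = stim$offset_s < stim_end + 0.5 &
          stim$offset_s < base$offset_s)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "terminated_fraction") <- mean(out$terminated)
  out
}

#' Initiation-mechanism experiment
#'
#' Applies one of the three initiation mechanisms to an accepted focal matrix
#' and reports when the discharge departs from the protocol-free twin. Two
#' onset notions are returned: `divergence_onset_s`, the first time the
#' binned amplitude of the stimulated run differs from the twin's at all
#' (trajectory-level divergence), and `discharge_onset_s`, the first time
#' the stimulated run's amplitude exceeds the twin's by `onset_margin`
#' (the discharge proper).
#'
#' @param m an accepted focal `swd_matrix`.
#' @param mechanism `"excitability"`, `"trigeminal"` or `"lowfreq"`.
#' @param seed initial-state seed.
#' @param t_stim stimulus start, seconds.
#' @param floor amplitude floor (binned-SD difference, model units).
#' @param onset_margin amplitude margin marking the discharge onset (summed
#'   cortical signal, model units).
#' @return list with `stim_window` (`c(start, end)`), `divergence_onset_s`,
#'   `discharge_onset_s`, `offset_s`, `twin_offset_s`, `elicited`.
#' @export
initiation_experiment <- function(m, mechanism = c("excitability",
                                                   "trigeminal", "lowfreq"),
                                  seed = 1L, t_stim = 0.8, floor = 0.05,
                                  onset_margin = 1) {
  mechanism <- match.arg(mechanism)
  ev <- switch(mechanism,
               excitability = protocol_excitability(t_stim),
               trigeminal = protocol_trigeminal(t_stim),
               lowfreq = protocol_lowfreq(t_stim))
  run <- simulate_network(m, 12, protocol = list(ev), seed = seed,
                          burn_in_s = 0)
  twin <- simulate_network(m, 12, seed = seed, burn_in_s = 0)
  bin_s <- 0.1
  br <- bin_sd(cortex_sum(run), run$f_samp, bin_s)
  bt <- bin_sd(cortex_sum(twin), twin$f_samp, bin_s)
  first_time <- function(idx) if (length(idx)) bin_s * (idx[1L] - 1L)
    else NA_real_
  off <- activity_offset(run, floor)
  twin_off <- activity_offset(twin, floor)
  list(stim_window = c(ev$t_start, ev$t_end),
       divergence_onset_s = first_time(which(abs(br - bt) > floor)),
       discharge_onset_s = first_time(which(br - bt > onset_margin)),
       offset_s = off, twin_offset_s = twin_off,
       elicited = off > max(twin_off, ev$t_end + 0.25))
}

#' Onset-aligned peri-ictal prediction-improvement experiment
#'
#' Elicits `n_trials` seizures on one matrix (identical protocol timing, so
#' trials are aligned at onset), computes the windowed prediction improvement
#' of every directed channel pair per trial, averages curves across trials
#' (`PI_mean`), and flags time points whose `PI_mean` exceeds the one-sided
#' 95th percentile of the pooled pre-onset baseline values. A small amount of
#' seeded measurement noise (fraction `noise_frac` of each channel's standard
#' deviation) is added to the LFP before the analysis; without it the
#' noise-free deterministic signals make the residual-variance ratio
#' degenerate.
#'
#' @param m an accepted focal `swd_matrix`.
#' @param n_trials number of seizures.
#' @param seed master seed.
#' @param t_ramp ramp start, seconds.
#' @param noise_frac measurement-noise level as a fraction of channel SD.
#' @param step_s window step, seconds.
#' @param duration_s simulated span per trial.
#' @return list with `pi_mean` (data frame: `pair`, `time_s`, `pi`,
#'   `flagged`), `onset_s`, `baseline_threshold` (per pair) and `params`.
#' @export
peri_ictal_pi_experiment <- function(m, n_trials = 6, seed = 1L,
                                     t_ramp = 0.8, noise_frac = 0.1,
                                     step_s = 0.25, duration_s = 10) {
  onset <- t_ramp + 0.3
  draws <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      2L * n_trials))
  params <- gc_params(sampling_frequency())
  curves <- list()
  for (tr in seq_len(n_trials)) {
    sz <- simulate_network(
      m, duration_s,
      protocol = list(protocol_excitability(t_ramp),
                      protocol_maintenance(onset)),
      seed = draws[tr], burn_in_s = 0)
    lfp <- compute_lfp(sz)
    lfp$channels <- with_seed(draws[n_trials + tr], {
      ch <- lfp$channels
      for (cn in colnames(ch))
        ch[, cn] <- ch[, cn] +
          stats::rnorm(nrow(ch), 0, noise_frac * stats::sd(ch[, cn]))
      ch
    })
    res <- sliding_pi(lfp, params, baseline = c(0, onset), step_s = step_s)
    curves[[tr]] <- cbind(res$pi, trial = tr)
  }
  df <- do.call(rbind, curves)
  pi_mean <- stats::aggregate(pi ~ pair + time_s, df, mean, na.rm = TRUE)
  bl <- df[df$time_s <= onset, ]
  thr <- tapply(bl$pi, bl$pair, stats::quantile, probs = 0.95,
                na.rm = TRUE, names = FALSE)
  pi_mean$flagged <- !is.na(pi_mean$pi) & pi_mean$pi > thr[pi_mean$pair]
  list(pi_mean = pi_mean[order(pi_mean$pair, pi_mean$time_s), ],
       onset_s = onset, baseline_threshold = thr, params = params,
       per_trial = df)
}
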