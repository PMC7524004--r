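# LFP construction, spectral observables, SWD detection, and duration
# statistics.

#' Build LFP channels from a simulation
#'
#' Model local field potentials are sums of node activities: the Cortex
#' channel is the sum of all PY and IN node series, VPM the sum of all TC
#' series, and RTN the sum of all RE series. The trigeminal input compartment
#' contributes to no channel.
#'
#' @param sim an `swd_sim` from [simulate_network()].
#' @return an object of class `swd_lfp`: a list with `time`, a
#'   three-column matrix `channels` (`Cortex`, `VPM`, `RTN`) and `f_samp`.
#' @export
compute_lfp <- function(sim) {
  stopifnot(inherits(sim, "swd_sim"))
  ch <- sim$channels
  pops <- sub("\\..*$", "", colnames(ch))
  pick <- function(p) {
    cols <- which(pops %in% p)
    if (length(cols) == 0L) rep(0, nrow(ch))
    else rowSums(ch[, cols, drop = FALSE])
  }
  out <- cbind(Cortex = pick(c("PY", "IN")), VPM = pick("TC"),
               RTN = pick("RE"))
  structure(list(time = sim$time, channels = out, f_samp = sim$f_samp),
            class = "swd_lfp")
}

#' @export
print.swd_lfp <- function(x, ...) {
  cat(sprintf("<swd_lfp> %d samples x %d channels at %g Hz\n",
              nrow(x$channels), ncol(x$channels), x$f_samp))
  invisible(x)
}

#' Single-node series from a simulation
#'
#' Extracts the trajectory of one node for single-unit views; requires the
#' simulation to have been run with `record_nodes = TRUE`.
#'
#' @param sim an `swd_sim`.
#' @param node node index (1-based).
#' @return numeric vector of the node's x series.
#' @export
node_series <- function(sim, node) {
  stopifnot(inherits(sim, "swd_sim"))
  if (is.null(sim$x))
    stop("per-node trajectories were not recorded; ",
         "rerun with record_nodes = TRUE")
  sim$x[, node]
}

#' Short-time power spectrogram
#'
#' Splits the signal into windows and computes the two-sided power spectral
#' density of each (mean removed, rectangular taper), folded onto positive
#' frequencies. With the default 1 s window the frequency resolution is 1 Hz.
#' Per Parseval, the summed power of one slice equals the variance of that
#' window.
#'
#' @param x numeric signal, or an `swd_lfp` (in which case `channel` selects
#'   the column).
#' @param f_samp sampling frequency in Hz (taken from the `swd_lfp` if one is
#'   given).
#' @param window_s window length, seconds.
#' @param overlap fractional overlap of consecutive windows in [0, 1).
#' @param channel channel name when `x` is an `swd_lfp`.
#' @return list with `freq` (Hz), `time` (window centers, s) and `power`
#'   (frequency-by-time matrix).
#' @export
lfp_spectrogram <- function(x, f_samp = NULL, window_s = 1, overlap = 0.5,
                            channel = "Cortex") {
  if (inherits(x, "swd_lfp")) {
    f_samp <- x$f_samp
    x <- x$channels[, channel]
  }
  if (is.null(f_samp)) stop("f_samp is required for a plain numeric signal")
  n_win <- round(window_s * f_samp)
  if (n_win > length(x)) stop("window longer than the signal")
  step <- max(1L, round(n_win * (1 - overlap)))
  starts <- seq.int(1L, length(x) - n_win + 1L, by = step)
  segs <- vapply(starts, function(s0) x[s0:(s0 + n_win - 1L)],
                 numeric(n_win))
  segs <- sweep(segs, 2L, colMeans(segs))
  X <- stats::mvfft(segs)
  psd <- Mod(X)^2 / n_win^2            # two-sided, sums to window variance
  n_pos <- floor(n_win / 2)
  power <- psd[2:(n_pos + 1L), , drop = FALSE]
  fold <- psd[n_win:(n_win - n_pos + 1L), , drop = FALSE]
  if (n_win %% 2 == 0) fold[n_pos, ] <- 0  # Nyquist bin has no mirror
  power <- power + fold
  list(freq = (1:n_pos) * f_samp / n_win,
       time = (starts - 1L + n_win / 2) / f_samp,
       power = power)
}

# Welch-style averaged power spectrum (mean-removed, rectangular taper)
welch_psd <- function(x, f_samp, window_s = 2) {
  sg <- lfp_spectrogram(x, f_samp, window_s = window_s, overlap = 0.5)
  list(freq = sg$freq, power = rowMeans(sg$power))
}

#' Spectral peak prominence of a signal
#'
#' The ratio of the largest spectral power ordinate in the 3-15 Hz band to
#' the total power in 1-100 Hz, computed from a Welch-averaged spectrum with
#' 0.5 Hz resolution. Near-periodic signals concentrate power in one bin and
#' score high; irregular broadband activity scores low. Used by the
#' surrounding-matrix screening to reject candidates with a well-established
#' main frequency.
#'
#' @param x numeric signal.
#' @param f_samp sampling frequency, Hz.
#' @param peak_band,total_band frequency bands in Hz.
#' @return scalar ratio in `[0, 1]` (NA for a flat signal).
#' @export
spectral_prominence <- function(x, f_samp, peak_band = c(3, 15),
                                total_band = c(1, 100)) {
  ps <- welch_psd(x, f_samp, window_s = 2)
  tot <- sum(ps$power[ps$freq >= total_band[1] & ps$freq <= total_band[2]])
  if (tot <= 0) return(NA_real_)
  pk <- max(ps$power[ps$freq >= peak_band[1] & ps$freq <= peak_band[2]])
  pk / tot
}

# dominant frequency of a segment (Hz), from the Welch spectrum
dominant_frequency <- function(x, f_samp, band = c(1, 100)) {
  if (length(x) < f_samp) {  # short segment: single mean-removed periodogram
    n <- length(x)
    psd <- Mod(stats::fft(x - mean(x)))^2
    freq <- (seq_len(n) - 1L) * f_samp / n
    keep <- freq >= band[1] & freq <= min(band[2], f_samp / 2)
    if (!any(keep) || sum(psd[keep]) == 0) return(NA_real_)
    return(freq[keep][which.max(psd[keep])])
  }
  ps <- welch_psd(x, f_samp, window_s = 1)
  keep <- ps$freq >= band[1] & ps$freq <= band[2]
  if (sum(ps$power[keep]) == 0) return(NA_real_)
  ps$freq[keep][which.max(ps$power[keep])]
}

# centered moving RMS with half-window edge handling
moving_rms <- function(x, n_win) {
  n_win <- max(3L, as.integer(n_win))
  if (n_win %% 2 == 0L) n_win <- n_win + 1L
  sq <- stats::filter(x^2, rep(1 / n_win, n_win), sides = 2)
  sq <- as.numeric(sq)
  # extend constant at the edges
  first <- which(!is.na(sq))[1L]
  last <- max(which(!is.na(sq)))
  sq[seq_len(first - 1L)] <- sq[first]
  if (last < length(sq)) sq[(last + 1L):length(sq)] <- sq[last]
  sqrt(pmax(sq, 0))
}

#' Detect spike-and-wave discharges in an LFP
#'
#' Amplitude-based detector on the Cortex channel: the moving RMS (0.5 s
#' window) of the mean-removed signal is compared against a baseline interval.
#' A discharge starts where the RMS exceeds `baseline mean + k_on * SD` and
#' ends when it stays below `baseline mean + k_off * SD` for at least
#' `min_gap_s`. Detected spans must have their dominant frequency inside
#' `freq_band` (default 4-12 Hz, the rodent SWD range with margin) and last at
#' least `min_duration_s`. Because all thresholds are relative to baseline
#' statistics, detections are invariant under positive rescaling of the LFP.
#'
#' @param lfp an `swd_lfp`, or a numeric vector (then `f_samp` is required).
#' @param f_samp sampling frequency when `lfp` is a plain vector.
#' @param baseline interval `c(start, end)` in seconds used to calibrate the
#'   thresholds; at least 2 s of interictal signal.
#' @param k_on,k_off onset and offset thresholds in baseline SDs.
#' @param rms_window_s moving-RMS window, seconds.
#' @param min_gap_s time the RMS must stay below the offset threshold to
#'   close an event, seconds.
#' @param freq_band dominant-frequency acceptance band, Hz.
#' @param min_duration_s shortest reportable event, seconds.
#' @return data frame with one row per event: `onset_s`, `offset_s`,
#'   `duration_s`, `dominant_frequency_hz`.
#' @export
detect_swd <- function(lfp, f_samp = NULL, baseline = c(0, 2),
                       k_on = 3, k_off = 2, rms_window_s = 0.5,
                       min_gap_s = 0.5, freq_band = c(4, 12),
                       min_duration_s = 1) {
  if (inherits(lfp, "swd_lfp")) {
    x <- lfp$channels[, "Cortex"]
    f_samp <- lfp$f_samp
  } else {
    x <- as.numeric(lfp)
    if (is.null(f_samp)) stop("f_samp is required for a plain numeric signal")
  }
  if (diff(baseline) < 2 - 1e-9)
    stop("at least 2 s of baseline are required to calibrate the detector")
  b0 <- max(1L, round(baseline[1] * f_samp) + 1L)
  b1 <- min(length(x), round(baseline[2] * f_samp))
  if (b1 <= b0) stop("baseline interval lies outside the recording")

  rms <- moving_rms(x - mean(x[b0:b1]), round(rms_window_s * f_samp))
  mu <- mean(rms[b0:b1])
  sdv <- stats::sd(rms[b0:b1])
  thr_on <- mu + k_on * sdv
  thr_off <- mu + k_off * sdv

  above_on <- rms > thr_on
  below_off <- rms < thr_off
  n <- length(x)
  gap <- round(min_gap_s * f_samp)

  events <- list()
  i <- 1L
  while (i <= n) {
    if (!above_on[i]) { i <- i + 1L; next }
    onset <- i
    # scan forward for a sustained sub-threshold stretch
    j <- onset
    off <- n
    run <- 0L
    while (j <= n) {
      run <- if (below_off[j]) run + 1L else 0L
      if (run >= gap) { off <- j - gap + 1L; break }
      j <- j + 1L
    }
    dur <- (off - onset) / f_samp
    if (dur >= min_duration_s) {
      seg <- x[onset:off]
      fd <- dominant_frequency(seg - mean(seg), f_samp)
      if (!is.na(fd) && fd >= freq_band[1] && fd <= freq_band[2]) {
        events[[length(events) + 1L]] <-
          data.frame(onset_s = (onset - 1L) / f_samp,
                     offset_s = (off - 1L) / f_samp,
                     duration_s = dur,
                     dominant_frequency_hz = fd)
      }
    }
    i <- max(off, onset) + gap
  }
  if (length(events) == 0L)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0),
                      dominant_frequency_hz = numeric(0)))
  do.call(rbind, events)
}

#' Duration statistics of detected discharges
#'
#' Summarizes SWD durations pooled over runs and matrices: a probability
#' density histogram with 1 s bins, the mode bin, the fraction of discharges
#' shorter than 10 s, and the extremes.
#'
#' @param durations numeric vector of SWD durations in seconds (pooled events
#'   from [detect_swd()]).
#' @param bin_s histogram bin width, seconds.
#' @return list with `histogram` (data frame: `bin_lo`, `bin_hi`, `count`,
#'   `density`), `mode_bin` (`c(lo, hi)`), `fraction_below_10s`, `min_s`,
#'   `max_s`, `n`.
#' @export
swd_duration_stats <- function(durations, bin_s = 1) {
  durations <- durations[is.finite(durations)]
  if (length(durations) == 0L) stop("no durations supplied")
  lo <- floor(min(durations) / bin_s) * bin_s
  hi <- ceiling(max(durations) / bin_s + 1e-9) * bin_s
  breaks <- seq(lo, max(hi, lo + bin_s), by = bin_s)
  h <- graphics::hist(durations, breaks = breaks, plot = FALSE,
                      right = FALSE)
  hist_df <- data.frame(bin_lo = head(h$breaks, -1L),
                        bin_hi = tail(h$breaks, -1L),
                        count = h$counts,
                        density = h$density)
  k <- which.max(hist_df$count)
  list(histogram = hist_df,
       mode_bin = c(hist_df$bin_lo[k], hist_df$bin_hi[k]),
       fraction_below_10s = mean(durations < 10),
       min_s = min(durations), max_s = max(durations),
       n = length(durations))
}
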