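# Adapted nonlinear Granger causality: polynomial autoregressive prediction
# models in moving windows, with the prediction-improvement (PI) statistic.

#' Parameters of the nonlinear Granger-causality analysis
#'
#' Converts the characteristic oscillation frequency into the sample-domain
#' parameters of the prediction models. With `T = round(f_samp / f0)` samples
#' per characteristic period, the prediction horizon is `T/12` and the
#' embedding lag `T/24` (both rounded half away from zero); at 3400 Hz and
#' 8 Hz this gives `T = 425`, horizon 35 and lag 18 samples. The univariate
#' model uses `D_s = 4` lagged values in a full polynomial of order `P = 2`;
#' the joint model adds `D_a` lagged values of the putative driver.
#'
#' @param f_samp sampling frequency, Hz.
#' @param f0 characteristic (discharge) frequency, Hz; default 8.
#' @param D_s univariate embedding dimension.
#' @param P polynomial order.
#' @param D_a number of added driver terms in the joint model.
#' @param window_s moving-window length, seconds.
#' @param alpha significance level for the baseline comparison.
#' @return a list of class `swd_gc_params`.
#' @export
#' @examples
#' p <- gc_params(3400)
#' c(p$T, p$tau_pred, p$lag)  # 425 35 18
gc_params <- function(f_samp, f0 = 8, D_s = 4, P = 2, D_a = 1,
                      window_s = 1, alpha = 0.05) {
  stopifnot(f_samp > 0, f0 > 0, D_s >= 1, P >= 1, D_a >= 0)
  Tchar <- round(f_samp / f0)
  structure(list(
    f_samp = f_samp, f0 = f0, T = Tchar,
    tau_pred = round(Tchar / 12), lag = round(Tchar / 24),
    D_s = D_s, P = P, D_a = D_a,
    window_s = window_s, alpha = alpha
  ), class = "swd_gc_params")
}

# all monomials of total degree 1..P over the columns of Z, plus intercept
poly_design <- function(Z, P) {
  d <- ncol(Z)
  n <- nrow(Z)
  combos <- list()
  gen <- function(start, left, cur) {
    if (left == 0L) {
      combos[[length(combos) + 1L]] <<- cur
      return(invisible())
    }
    for (v in start:d) gen(v, left - 1L, c(cur, v))
  }
  for (p in seq_len(P)) gen(1L, p, integer(0))
  X <- matrix(1, n, length(combos) + 1L)
  for (k in seq_along(combos)) {
    v <- Z[, combos[[k]][1L]]
    for (ix in combos[[k]][-1L]) v <- v * Z[, ix]
    X[, k + 1L] <- v
  }
  X
}

# lag-embedding: rows are times t with all lags and the target in range;
# Z[, k] = x[t - (k-1) l], target = x[t + tau_pred]
embed_lags <- function(x, D, l, tau_pred) {
  n <- length(x)
  t0 <- 1L + (D - 1L) * l
  t1 <- n - tau_pred
  if (t1 < t0 + 10L) stop("window too short for the embedding")
  t <- t0:t1
  Z <- vapply(seq_len(D), function(k) x[t - (k - 1L) * l], numeric(length(t)))
  list(Z = Z, target = x[t + tau_pred], t = t)
}

ls_fit_eps2 <- function(X, yv) {
  fit <- stats::lm.fit(X, yv)
  mean(fit$residuals^2)
}

#' Fit the univariate prediction model of one window
#'
#' Least-squares fit of `x(t + tau_pred)` on a polynomial (order `P`) in
#' `D_s` lagged values `x(t), x(t - l), ...` of the signal itself. The
#' returned mean squared prediction error is the reference against which the
#' joint model is compared.
#'
#' @param x numeric window of the predicted signal.
#' @param params an [gc_params()] object.
#' @return list with `eps2` (mean squared in-window prediction error), `n`
#'   (regression rows), `df` (number of coefficients) and `degenerate`
#'   (`TRUE` for a constant window, where `eps2 = 0`).
#' @export
fit_univariate <- function(x, params) {
  stopifnot(inherits(params, "swd_gc_params"))
  if (stats::sd(x) == 0)
    return(list(eps2 = 0, n = length(x), df = NA_integer_, degenerate = TRUE))
  emb <- embed_lags(x, params$D_s, params$lag, params$tau_pred)
  X <- poly_design(emb$Z, params$P)
  if (nrow(X) <= ncol(X) * 10L)
    stop("window too short: fewer than 10 samples per polynomial coefficient")
  list(eps2 = ls_fit_eps2(X, emb$target), n = nrow(X), df = ncol(X),
       degenerate = FALSE)
}

#' Fit the joint (bivariate) prediction model of one window
#'
#' The univariate regression of [fit_univariate()] augmented by `D_a` lagged
#' values of the putative driving signal `y`; the polynomial of order `P` is
#' taken over all `D_s + D_a` variables, so the univariate regressor set is
#' nested in the joint one and the joint residual variance cannot exceed the
#' univariate one.
#'
#' @param x numeric window of the predicted signal.
#' @param y numeric window of the driving signal, time-aligned with `x`.
#' @param params an [gc_params()] object.
#' @return as [fit_univariate()].
#' @export
fit_bivariate <- function(x, y, params) {
  stopifnot(inherits(params, "swd_gc_params"), length(x) == length(y))
  if (stats::sd(x) == 0)
    return(list(eps2 = 0, n = length(x), df = NA_integer_, degenerate = TRUE))
  emb <- embed_lags(x, params$D_s, params$lag, params$tau_pred)
  Za <- vapply(seq_len(params$D_a),
               function(k) y[emb$t - (k - 1L) * params$lag],
               numeric(length(emb$t)))
  X <- poly_design(cbind(emb$Z, Za), params$P)
  if (nrow(X) <= ncol(X) * 10L)
    stop("window too short: fewer than 10 samples per polynomial coefficient")
  list(eps2 = ls_fit_eps2(X, emb$target), n = nrow(X), df = ncol(X),
       degenerate = FALSE)
}

#' Prediction improvement
#'
#' `PI = 1 - eps2_joint / eps2_self`: the relative reduction of the mean
#' squared prediction error when the model is augmented by the driving
#' signal. For nested least-squares fits on the same window, `PI` lies in
#' `[0, 1]`.
#'
#' @param eps2_s univariate (self) mean squared prediction error; must be
#'   positive.
#' @param eps2_j joint mean squared prediction error.
#' @return the prediction improvement.
#' @export
prediction_improvement <- function(eps2_s, eps2_j) {
  if (any(eps2_s <= 0))
    stop("prediction improvement undefined: zero self prediction error")
  1 - eps2_j / eps2_s
}

#' Moving-window prediction improvement for all channel pairs
#'
#' Computes `PI(t)` in moving windows for all 6 directed pairs among the LFP
#' channels (Cortex, VPM, RTN). Each value at time `t` summarizes the window
#' `[t - w, t]`. Significance is assessed against the baseline interval
#' (by default 10 to 3 seconds before the first seizure onset): a point is
#' flagged when its PI exceeds the one-sided `1 - alpha` empirical quantile
#' of the baseline windows of its pair. Windows are standardized (centered
#' and scaled) before embedding, which leaves PI invariant but conditions
#' the polynomial regression.
#'
#' @param lfp an `swd_lfp` from [compute_lfp()], or a numeric matrix with
#'   named columns (then `f_samp` is required).
#' @param params an [gc_params()] object; defaults to `gc_params(f_samp)`.
#' @param events data frame of detected seizures (from [detect_swd()]) used
#'   to place the default baseline interval; optional if `baseline` is given.
#' @param baseline explicit baseline interval `c(start, end)` in seconds.
#' @param step_s window step, seconds.
#' @param f_samp sampling frequency when `lfp` is a plain matrix.
#' @param significance `"percentile"` (empirical baseline quantile, default)
#'   or `"ftest"` (per-window nested-model F test at level `alpha`).
#' @return an object of class `swd_pi`: data frame `pi` with columns
#'   `pair`, `time_s`, `pi`, `flagged`, plus `baseline` (interval),
#'   `threshold` (per-pair flagging thresholds) and `params`.
#' @export
sliding_pi <- function(lfp, params = NULL, events = NULL, baseline = NULL,
                       step_s = 0.25, f_samp = NULL,
                       significance = c("percentile", "ftest")) {
  significance <- match.arg(significance)
  if (inherits(lfp, "swd_lfp")) {
    ch <- lfp$channels
    f_samp <- lfp$f_samp
  } else {
    ch <- as.matrix(lfp)
    if (is.null(f_samp)) stop("f_samp is required for a plain matrix")
  }
  if (is.null(colnames(ch)))
    colnames(ch) <- paste0("ch", seq_len(ncol(ch)))
  if (is.null(params)) params <- gc_params(f_samp)
  stopifnot(inherits(params, "swd_gc_params"))
  n <- nrow(ch)
  w <- round(params$window_s * f_samp)
  if (w > n) stop("window longer than the recording")

  if (is.null(baseline)) {
    if (is.null(events) || nrow(events) == 0L)
      stop("either a baseline interval or detected events are required")
    onset <- min(events$onset_s)
    baseline <- c(onset - 10, onset - 3)
  }
  baseline[1] <- max(baseline[1], 0)
  if (diff(baseline) < params$window_s)
    stop("baseline interval shorter than one window")

  ends <- seq(w, n, by = max(1L, round(step_s * f_samp)))
  chans <- colnames(ch)
  pairs <- expand.grid(from = chans, to = chans, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]

  window_pi <- function(xw, yw) {
    if (stats::sd(xw) == 0 || stats::sd(yw) == 0) return(c(NA_real_, NA_real_))
    xs <- (xw - mean(xw)) / stats::sd(xw)
    ys <- (yw - mean(yw)) / stats::sd(yw)
    fs <- fit_univariate(xs, params)
    fj <- fit_bivariate(xs, ys, params)
    if (fs$degenerate || fs$eps2 <= 0) return(c(NA_real_, NA_real_))
    pi_val <- prediction_improvement(fs$eps2, fj$eps2)
    pf <- NA_real_
    if (significance == "ftest") {
      q <- fj$df - fs$df
      fstat <- ((fs$eps2 - fj$eps2) * fs$n / q) /
        (fj$eps2 * fs$n / (fs$n - fj$df))
      pf <- stats::pf(fstat, q, fs$n - fj$df, lower.tail = FALSE)
    }
    c(pi_val, pf)
  }

  res <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    vals <- matrix(NA_real_, length(ends), 2L)
    for (k in seq_along(ends)) {
      ix <- (ends[k] - w + 1L):ends[k]
      vals[k, ] <- window_pi(ch[ix, pairs$to[p]], ch[ix, pairs$from[p]])
    }
    res[[p]] <- data.frame(
      pair = paste0(pairs$from[p], "->", pairs$to[p]),
      time_s = (ends - 1L) / f_samp,
      pi = vals[, 1L], p_value = vals[, 2L],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, res)

  in_baseline <- df$time_s - params$window_s >= baseline[1] &
    df$time_s <= baseline[2] + 1e-9
  thr <- tapply(df$pi[in_baseline], df$pair[in_baseline],
                stats::quantile, probs = 1 - params$alpha, na.rm = TRUE,
                names = FALSE)
  if (significance == "percentile") {
    df$flagged <- !is.na(df$pi) & df$pi > thr[df$pair]
  } else {
    df$flagged <- !is.na(df$p_value) & df$p_value < params$alpha
  }
  structure(list(pi = df, baseline = baseline,
                 threshold = thr, params = params),
            class = "swd_pi")
}

#' @export
print.swd_pi <- function(x, ...) {
  cat(sprintf("<swd_pi> %d directed pairs, %d window positions, baseline [%g, %g] s\n",
              length(unique(x$pi$pair)),
              length(unique(x$pi$time_s)), x$baseline[1], x$baseline[2]))
  invisible(x)
}
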