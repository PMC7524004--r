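# Shared fixtures: tiny layouts, hand-built matrices, and a brute-force
# reference integrator used as the independent oracle for the compiled one.

# layout with a single population, n nodes
tiny_layout <- function(n, population = "PY", region = "focal") {
  counts <- setNames(rep(0L, length(DEFAULT_COUNTS_NAMES)),
                     DEFAULT_COUNTS_NAMES)
  counts[paste(population, region, sep = ".")] <- as.integer(n)
  network_layout("full", counts = counts)
}
DEFAULT_COUNTS_NAMES <- c("PY.focal", "IN.focal", "TC.focal", "RE.focal",
                          "PY.surrounding", "IN.surrounding",
                          "TC.surrounding", "RE.surrounding", "NT.external")

# swd_matrix from explicit triplets on a given layout (1-based indices)
manual_matrix <- function(layout, i = integer(0), j = integer(0),
                          x = numeric(0), tau_steps = 3L,
                          w_exc = 0.1, w_inh = 0.1) {
  n <- attr(layout, "n_total")
  C <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  swdnet:::new_swd_matrix(C, layout, tau_steps, w_exc, w_inh)
}

# straightforward (non-vectorized) reference integration of the delayed
# FitzHugh-Nagumo network; full-history lookup instead of a ring buffer
oracle_simulate <- function(C, tau_steps, x0, y0, n_steps,
                            a = 0.8, b = 0.008, gamma = 0.0033, dt = 0.5,
                            drive = function(s, n) numeric(n)) {
  C <- as.matrix(C)
  n <- length(x0)
  X <- matrix(0, n_steps + 1L, n)
  Y <- matrix(0, n_steps + 1L, n)
  X[1L, ] <- x0
  Y[1L, ] <- y0
  h <- function(x) (1 + tanh(x)) / 2
  for (s in seq_len(n_steps)) {
    xd <- X[max(s - tau_steps, 1L), ]
    coup <- numeric(n)
    for (i in seq_len(n)) {
      acc <- 0
      for (j in seq_len(n)) if (j != i) acc <- acc + C[i, j] * h(xd[j])
      coup[i] <- acc
    }
    dr <- drive(s - 1L, n)
    for (i in seq_len(n)) {
      xi <- X[s, i]; yi <- Y[s, i]
      X[s + 1L, i] <- xi + dt * (xi * (a - xi) * (xi - 1) - yi + coup[i] +
                                   dr[i])
      Y[s + 1L, i] <- yi + dt * (b * xi - gamma * yi)
    }
  }
  list(x = X, y = Y)
}

# run the compiled integrator directly (no burn-in, explicit state)
raw_simulate <- function(m, x0, y0, n_steps, scale_events = list(),
                         drive_events = list(), a = 0.8, b = 0.008,
                         gamma = 0.0033, dt = 0.5) {
  W <- diag(length(x0))
  swdnet:::simulate_fhn_cpp(m$C, m$tau_steps, a, b, gamma, dt,
                            x0, y0, n_steps, scale_events, drive_events,
                            W, TRUE, TRUE, 0L)
}

# synthetic LFP: baseline noise with an embedded 8 Hz burst
synthetic_burst_lfp <- function(f_samp = 400, pre_s = 5, burst_s = 6,
                                post_s = 4, burst_amp = 10, noise_sd = 0.5,
                                freq = 8, seed = 1) {
  set.seed(seed)
  n_pre <- pre_s * f_samp
  n_b <- burst_s * f_samp
  n_post <- post_s * f_samp
  x <- c(rnorm(n_pre, 0, noise_sd),
         burst_amp * sin(2 * pi * freq * seq_len(n_b) / f_samp) +
           rnorm(n_b, 0, noise_sd),
         rnorm(n_post, 0, noise_sd))
  structure(list(time = (seq_along(x) - 1) / f_samp,
                 channels = cbind(Cortex = x, VPM = 0 * x, RTN = 0 * x),
                 f_samp = f_samp),
            class = "swd_lfp")
}
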