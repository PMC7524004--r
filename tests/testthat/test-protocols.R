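# Protocol events: construction, scaling semantics, drives, baseline
# restoration, and twin-run divergence.

test_that("excitability ramp interpolates linearly and restores baseline", {
  ev <- protocol_excitability(2)
  expect_equal(ev$t_start, 2)
  expect_equal(ev$t_end, 2.3)
  # midpoint of the ramp from 0.1 to 0.115: factor 1.075 -> weight 0.1075
  expect_equal(0.1 * event_scale_factor(ev, 2.15), 0.1075)
  expect_equal(event_scale_factor(ev, 2), 1)       # ramp starts at baseline
  expect_equal(event_scale_factor(ev, 1.99), 1)    # before the event
  expect_equal(event_scale_factor(ev, 2.3), 1)     # instant return
  expect_equal(event_scale_factor(ev, 2.2999), 1.15, tolerance = 1e-3)
})

test_that("trigeminal and maintenance events carry the published factors", {
  tri <- protocol_trigeminal(1)
  expect_equal(0.1 * event_scale_factor(tri, 1.1), 0.2)  # 0.1 -> 0.2 step
  expect_equal(tri$t_end - tri$t_start, 0.3)
  mnt <- protocol_maintenance(3)          # onset + 1 s, for 5 s
  expect_equal(mnt$t_start, 4)
  expect_equal(mnt$t_end, 9)
  expect_equal(0.1 * event_scale_factor(mnt, 5), 0.115)
})

test_that("maintenance preserves signs: no RE-source edge becomes positive", {
  m <- apply_collaterals(sample_matrix(network_layout("focal"),
                                       tau_steps = 9, seed = 11))
  mnt <- protocol_maintenance(0.5, delay_s = 0.5, duration_s = 1)
  compiled <- swdnet:::compile_protocol(list(mnt), m, 3400, 0, 5)
  D <- compiled$scale[[1L]]$D
  g <- compiled$scale[[1L]]$g1
  scaled <- m$C + g * D
  T <- as(scaled, "TsparseMatrix")
  pops <- swdnet:::node_populations(m$layout)
  re_src <- pops[T@j + 1L] == "RE"
  expect_true(all(T@x[re_src] < 0))
  # magnitudes scale from 0.1 to 0.115 on the targeted edges
  expect_equal(sort(unique(abs(T@x[re_src]))),
               sort(unique(c(0.115, 0.1))), tolerance = 1e-12)
})

test_that("low-frequency drive is zero-phase at onset; HFS has 130 pulses/s", {
  low <- protocol_lowfreq(1)
  expect_equal(low$amplitude, 1)
  expect_equal(low$freq_hz, 8)
  m <- manual_matrix(tiny_layout(2), tau_steps = 1L)
  compiled <- swdnet:::compile_protocol(list(low), m, 3400, 0, 5)
  d <- compiled$drive[[1L]]
  # drive at successive steps: amplitude * sin(omega * (s - start))
  expect_equal(d$omega, 2 * pi * 8 / 3400)
  hfs <- protocol_hfs(2)
  ch <- swdnet:::compile_protocol(list(hfs), m, 3400, 0, 5)$drive[[1L]]
  # count pulse onsets over the 1 s train
  steps <- ch$start_step:(ch$end_step - 1L)
  phase <- (steps - ch$start_step) %% ch$period
  on <- phase < ch$width
  pulses <- sum(diff(c(FALSE, on)) == 1)
  expect_equal(pulses, 130)
  # fixed-gap variant: 0.6 ms + 8 ms period ~ 116 pulses
  hfs2 <- protocol_hfs(2, period_s = 0.6e-3 + 8e-3)
  ch2 <- swdnet:::compile_protocol(list(hfs2), m, 3400, 0, 5)$drive[[1L]]
  phase2 <- (steps - ch2$start_step) %% ch2$period
  pulses2 <- sum(diff(c(FALSE, phase2 < ch2$width)) == 1)
  expect_equal(pulses2, 117, tolerance = 2)
})

test_that("null stimuli leave the trajectory unchanged; real events diverge at onset", {
  m <- apply_collaterals(sample_matrix(network_layout("focal"),
                                       tau_steps = 9, seed = 11))
  base <- simulate_network(m, 2, seed = 3, burn_in_s = 0)
  zero_amp <- protocol_hfs(1, amplitude = 0)
  s_zero <- simulate_network(m, 2, protocol = list(zero_amp), seed = 3,
                             burn_in_s = 0)
  expect_identical(base$channels, s_zero$channels)
  # a ramp applied to a zero matrix has no edges to scale and no effect
  m0 <- manual_matrix(network_layout("focal"), tau_steps = 9L)
  expect_warning(
    s0 <- simulate_network(m0, 1, protocol = list(protocol_excitability(0.2)),
                           seed = 3, burn_in_s = 0),
    "no edges")
  s0_twin <- simulate_network(m0, 1, seed = 3, burn_in_s = 0)
  expect_identical(s0$channels, s0_twin$channels)
  # twin runs diverge no earlier than the first affected sample
  ev <- protocol_lowfreq(1, amplitude = 0.5)
  s_ev <- simulate_network(m, 2, protocol = list(ev), seed = 3,
                           burn_in_s = 0)
  first_diff <- which(rowSums(abs(s_ev$channels - base$channels)) > 0)[1L]
  onset_sample <- round(1 * 3400) + 1L
  expect_gte(first_diff, onset_sample)
  expect_lte(first_diff, onset_sample + 2L)
})

test_that("events outside the simulation window are rejected", {
  m <- apply_collaterals(sample_matrix(network_layout("focal"),
                                       tau_steps = 9, seed = 11))
  expect_error(simulate_network(m, 2, protocol = list(protocol_trigeminal(1.9)),
                                seed = 1),
               "beyond")
  expect_error(swdnet:::new_event("coupling_scale", -1, 2), "t_start")
  # trigeminal protocol on a network without NT -> TC edges warns
  ms <- sample_matrix(network_layout("surrounding"), tau_steps = 9, seed = 1)
  expect_warning(simulate_network(ms, 1.5, seed = 1, burn_in_s = 0,
                                  protocol = list(protocol_trigeminal(1))),
                 "no edges")
})

test_that("coupling scaling leaves the stored matrix untouched", {
  m <- apply_collaterals(sample_matrix(network_layout("focal"),
                                       tau_steps = 9, seed = 11))
  before <- as.matrix(m$C)
  invisible(simulate_network(m, 1.5, protocol = list(protocol_excitability(0.5)),
                             seed = 3, burn_in_s = 0))
  expect_identical(as.matrix(m$C), before)
})
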