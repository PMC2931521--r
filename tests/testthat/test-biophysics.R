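# Single-neuron dynamics, synaptic waveforms, spike thresholds.

test_that("neuron_params converts densities and validates reversals", {
  p <- fx_params()
  expect_equal(p$area_cm2, 4 * pi * (10e-4)^2)
  expect_equal(p$c_pf / p$gl_ns, 10) # membrane time constant 10 ms
  expect_error(neuron_params(e_k = -50), "reversal")
  # m steady-state half-activation near -40 mV
  m40 <- steady_state_gates(-40)$m
  expect_gt(m40, 0.4)
  expect_lt(m40, 0.7)
})

test_that("conductance waveform is peak-normalized with the closed-form peak time", {
  k <- ampa_kinetics()
  # closed form: t* = tau1 tau2 / (tau2 - tau1) * log(tau2/tau1)
  t_star <- (4 / 3) * log(4)
  expect_equal(k$t_peak, t_star)
  expect_equal(conductance_waveform(0, k, 5), 0)
  expect_equal(conductance_waveform(-1, k, 5), 0)
  expect_equal(conductance_waveform(t_star, k, 5), 5)
  # numerical maximization agrees with the closed form
  opt <- optimize(function(t) conductance_waveform(t, k, 1),
                  c(0, 20), maximum = TRUE)
  expect_equal(opt$maximum, t_star, tolerance = 1e-4)
  expect_lt(max(conductance_waveform(seq(0, 30, 0.01), k, 1)), 1 + 1e-9)
  expect_error(conductance_waveform(1, k, -2), "non-negative")
  g <- gaba_kinetics()
  expect_equal(c(g$tau1, g$tau2, g$e_rev), c(2, 8, -80))
})

test_that("resting neuron stays at rest and diverging states are reported", {
  p <- fx_params()
  r <- simulate_neuron(p, NULL, duration = 100, dt = 0.025, record = TRUE)
  expect_lt(max(abs(r$trace$v - p$v_rest)), 0.5)
  st <- neuron_state(p)
  st$v <- NaN
  expect_error(step_neuron(st, p, 0.025), "non-finite state variable 'v'")
  expect_error(step_neuron(neuron_state(p), p, 0.2), "dt")
})

test_that("suprathreshold AMPA events elicit prompt spikes, dt-convergent", {
  p <- fx_params()
  thr <- find_spike_threshold(p, g_i = 0)
  # far-suprathreshold event: spiking starts within 10 ms of onset
  ev <- data.frame(onset = 1, amplitude = 20 * thr, type = "ampa")
  sp <- simulate_neuron(p, ev, duration = 15)$spikes
  expect_gte(length(sp), 1)
  expect_lt(sp[1] - 1, 10)
  # just-suprathreshold event: exactly one (late) spike within the probe
  # window the threshold was defined with
  ev1 <- data.frame(onset = 1, amplitude = 1.01 * thr, type = "ampa")
  expect_length(simulate_neuron(p, ev1, duration = 30)$spikes, 1)
  # halving dt moves the spike time by < 0.1 ms
  s1 <- simulate_neuron(p, ev, duration = 15, dt = 0.025)$spikes[1]
  s2 <- simulate_neuron(p, ev, duration = 15, dt = 0.0125)$spikes[1]
  expect_lt(abs(s1 - s2), 0.1)
})

test_that("gating variables stay in [0,1] and V within reversals under bombardment", {
  p <- fx_params()
  set.seed(7)
  ev <- data.frame(onset = sort(runif(60, 0, 950)),
                   amplitude = runif(60, 0, 30),
                   type = sample(c("ampa", "gaba"), 60, replace = TRUE))
  st <- neuron_state(p)
  kin <- list(ampa = ampa_kinetics(), gaba = gaba_kinetics())
  for (i in seq_len(nrow(ev))) {
    st <- add_synaptic_event(st, ev$onset[i], kin[[ev$type[i]]],
                             ev$amplitude[i])
  }
  lo <- c(1, 1, 1)
  hi <- c(0, 0, 0)
  vrange <- c(st$v, st$v)
  for (k in seq_len(40000)) { # 1 s at dt = 0.025
    st <- step_neuron(st, p, 0.025)
    g <- c(st$m, st$h, st$n)
    lo <- pmin(lo, g)
    hi <- pmax(hi, g)
    vrange <- c(min(vrange[1], st$v), max(vrange[2], st$v))
  }
  expect_true(all(lo >= 0) && all(hi <= 1))
  expect_gte(vrange[1], p$e_k)
  expect_lte(vrange[2], p$e_na)
})

test_that("two near-threshold events 1 ms apart produce at most two spikes", {
  p <- fx_params()
  thr <- find_spike_threshold(p, g_i = 0)
  ev <- data.frame(onset = c(1, 2), amplitude = 1.01 * thr,
                   type = "ampa")
  expect_lte(length(simulate_neuron(p, ev, duration = 20)$spikes), 2)
})

test_that("spike threshold equals the isolated threshold at gI = 0 and is monotone in gI", {
  p <- fx_params()
  tab <- fx_table()
  expect_equal(tab$threshold_gE[tab$gI == 0],
               find_spike_threshold(p, g_i = 0), tolerance = 1e-3)
  expect_false(is.unsorted(tab$threshold_gE))
  # monotonicity holds for freshly computed thresholds too (no cummax help)
  gi <- c(0, 30, 120, 700, 5000)
  fresh <- vapply(gi, function(g) find_spike_threshold(p, g_i = g),
                  numeric(1))
  expect_false(is.unsorted(fresh + 1e-9 * seq_along(fresh)))
  # unreachable sentinel: with a tiny search bound the threshold is Inf
  expect_identical(find_spike_threshold(p, g_i = 500, upper = 0.2), Inf)
})

test_that("threshold tables round-trip through CSV including Inf sentinels", {
  tab <- build_threshold_table(fx_params(), g_i_values = c(0, 50, 200),
                               upper = 1.0) # force an unreachable row
  expect_true(any(!is.finite(tab$threshold_gE)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_threshold_table(tab, path)
  back <- read_threshold_table(path)
  expect_equal(back$threshold_gE, tab$threshold_gE)
  expect_equal(back$gI, tab$gI)
})

test_that("threshold lookup interpolates, propagates Inf, and rejects out-of-range gI", {
  tab <- fx_table()
  expect_true(threshold_lookup(tab, g_e = 100, g_i = 0))
  expect_false(threshold_lookup(tab, g_e = 1e-4, g_i = 0))
  expect_error(threshold_lookup(tab, 1, max(tab$gI) * 2), "extrapolation")
  small <- build_threshold_table(fx_params(), g_i_values = c(0, 50, 200),
                                 upper = 1.0)
  expect_false(threshold_lookup(small, g_e = 1e6, g_i = 150))
})
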