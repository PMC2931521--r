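# Conductance-based isopotential point neuron and synaptic kinetics.
#
# Working units throughout: mV, ms, nS, pF, pA (so G*V is pA and pA/pF is
# mV/ms). Membrane densities are specified per cm^2 and converted to
# whole-cell values via the sphere surface area.

#' Biophysical constants of the model neuron
#'
#' The neuron is an isopotential sphere (radius 10 um) carrying a leak
#' conductance, a fast Na+ conductance (m^3 h gating) and a delayed-rectifier
#' K+ conductance (n^4 gating). Densities follow the classical reduced
#' Traub-Miles pyramidal-cell model: note that they are interpreted in
#' mS/cm^2 (giving a membrane time constant C_m/G_leak = 10 ms and regular
#' spiking); a uS/cm^2 reading would make the cell unspikable.
#'
#' @param radius_um Sphere radius in micrometres.
#' @param c_m Membrane capacitance density, uF/cm^2.
#' @param g_leak,g_na,g_k Conductance densities, mS/cm^2.
#' @param e_leak,e_na,e_k Reversal potentials, mV. Must satisfy
#'   `e_k < e_leak < 0 < e_na`.
#' @return An object of class `neuron_params`: the inputs plus the derived
#'   whole-cell values `area_cm2`, `c_pf` (pF), `gl_ns`, `gna_ns`, `gk_ns`
#'   (nS).
#' @examples
#' p <- neuron_params()
#' p$c_pf / p$gl_ns # membrane time constant, ms
#' @export
neuron_params <- function(radius_um = 10, c_m = 1.0,
                          g_leak = 0.1, g_na = 100, g_k = 80,
                          e_leak = -67, e_na = 90, e_k = -100) {
  stopifnot(radius_um > 0, c_m > 0, g_leak > 0, g_na >= 0, g_k >= 0)
  if (!(e_k < e_leak && e_leak < 0 && 0 < e_na)) {
    stop("reversal potentials must satisfy e_k < e_leak < 0 < e_na")
  }
  area_cm2 <- 4 * pi * (radius_um * 1e-4)^2
  p <- list(
    radius_um = radius_um, c_m = c_m,
    g_leak = g_leak, g_na = g_na, g_k = g_k,
    e_leak = e_leak, e_na = e_na, e_k = e_k,
    area_cm2 = area_cm2,
    c_pf = c_m * area_cm2 * 1e6,      # uF -> pF
    gl_ns = g_leak * area_cm2 * 1e6,  # mS -> nS
    gna_ns = g_na * area_cm2 * 1e6,
    gk_ns = g_k * area_cm2 * 1e6
  )
  p$v_rest <- .resting_potential(p)
  class(p) <- "neuron_params"
  p
}

# Total steady-state membrane current (pA, outward positive) at voltage v.
.steady_current <- function(p, v) {
  g <- steady_state_gates(v)
  p$gl_ns * (v - p$e_leak) +
    p$gna_ns * g$m^3 * g$h * (v - p$e_na) +
    p$gk_ns * g$n^4 * (v - p$e_k)
}

# Stable resting potential: the zero of the steady-state I-V curve just
# above e_leak (the Na+ window current pulls rest slightly depolarised).
.resting_potential <- function(p) {
  # scan for the first sign change of the I-V curve above e_leak - 1 (the
  # second zero, a few mV higher, is the unstable spike threshold)
  vs <- seq(p$e_leak - 1, p$e_leak + 8, by = 0.25)
  iv <- vapply(vs, function(v) .steady_current(p, v), numeric(1))
  k <- which(iv[-length(iv)] < 0 & iv[-1] >= 0)
  if (length(k) == 0) return(p$e_leak) # fall back for exotic parameter sets
  stats::uniroot(function(v) .steady_current(p, v),
                 c(vs[k[1]], vs[k[1] + 1]), tol = 1e-8)$root
}

#' Double-exponential synaptic kinetics
#'
#' @param tau1 Rise time constant, ms. @param tau2 Decay time constant, ms
#'   (`tau2 > tau1 > 0`). @param e_rev Reversal potential, mV.
#' @param delay Synaptic delay, ms.
#' @return Object of class `synapse_kinetics` with the peak time and the
#'   peak value of the unit difference-of-exponentials precomputed.
#' @export
synapse_kinetics <- function(tau1, tau2, e_rev, delay = 1) {
  stopifnot(tau1 > 0, tau2 > tau1, delay >= 0)
  t_peak <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  peak <- exp(-t_peak / tau2) - exp(-t_peak / tau1)
  structure(list(tau1 = tau1, tau2 = tau2, e_rev = e_rev, delay = delay,
                 t_peak = t_peak, peak = peak),
            class = "synapse_kinetics")
}

#' @rdname synapse_kinetics
#' @export
ampa_kinetics <- function() synapse_kinetics(tau1 = 1, tau2 = 4, e_rev = 0)

#' @rdname synapse_kinetics
#' @export
gaba_kinetics <- function() synapse_kinetics(tau1 = 2, tau2 = 8, e_rev = -80)

#' Synaptic conductance waveform
#'
#' Difference-of-exponentials `exp(-t/tau2) - exp(-t/tau1)`, rescaled so its
#' peak equals `amplitude`; the event amplitude is therefore the peak
#' conductance in nS. Zero for `t < 0`.
#'
#' @param t_since_onset Time since event onset, ms (vectorised).
#' @param kinetics A [synapse_kinetics()] object.
#' @param amplitude Peak conductance, nS (must be >= 0).
#' @return Conductance values, same length as `t_since_onset`.
#' @export
conductance_waveform <- function(t_since_onset, kinetics, amplitude = 1) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  g <- ifelse(t_since_onset < 0, 0,
              exp(-t_since_onset / kinetics$tau2) -
                exp(-t_since_onset / kinetics$tau1))
  amplitude * g / kinetics$peak
}

# x / (1 - exp(-x/a)), with the removable singularity at x = 0 filled in.
vtrap <- function(x, a) {
  y <- x / a
  small <- abs(y) < 1e-7
  out <- numeric(length(x))
  out[small] <- a * (1 + y[small] / 2)
  out[!small] <- x[!small] / (1 - exp(-y[!small]))
  out
}

# Reduced Traub-Miles rate functions (1/ms), vectorised over V (mV).
gate_rates <- function(v) {
  list(
    am = 0.32 * vtrap(v + 54, 4),
    bm = 0.28 * vtrap(-(v + 27), 5),
    ah = 0.128 * exp(-(v + 50) / 18),
    bh = 4 / (1 + exp(-(v + 27) / 5)),
    an = 0.032 * vtrap(v + 52, 5),
    bn = 0.5 * exp(-(v + 57) / 40)
  )
}

#' Steady-state gating variables at a fixed voltage
#'
#' @param v Membrane potential, mV (vectorised).
#' @return List with components `m`, `h`, `n` in `[0, 1]`.
#' @export
steady_state_gates <- function(v) {
  r <- gate_rates(v)
  list(m = r$am / (r$am + r$bm),
       h = r$ah / (r$ah + r$bh),
       n = r$an / (r$an + r$bn))
}

#' Initial neuron state
#'
#' Voltage at the resting potential (the stable zero of the steady-state
#' I-V curve, about 0.7 mV above the leak reversal because of the Na+ window
#' current) with gating variables at their steady state.
#'
#' @param params A [neuron_params()] object.
#' @param v Starting voltage, mV.
#' @return Object of class `neuron_state` with fields `v`, `m`, `h`, `n`,
#'   `t` (ms), `events` (pending synaptic events) and `spikes` (times of 0 mV
#'   upward crossings).
#' @export
neuron_state <- function(params = neuron_params(), v = params$v_rest) {
  g <- steady_state_gates(v)
  structure(list(v = v, m = g$m, h = g$h, n = g$n, t = 0,
                 events = data.frame(onset = numeric(), tau1 = numeric(),
                                     tau2 = numeric(), e_rev = numeric(),
                                     peak = numeric(), amplitude = numeric()),
                 spikes = numeric()),
            class = "neuron_state")
}

#' Schedule a synaptic event on a neuron state
#'
#' @param state A [neuron_state()].
#' @param onset Event onset time, ms (absolute simulation time).
#' @param kinetics A [synapse_kinetics()] object.
#' @param amplitude Peak conductance, nS.
#' @return The updated state.
#' @export
add_synaptic_event <- function(state, onset, kinetics, amplitude) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  state$events <- rbind(state$events,
                        data.frame(onset = onset, tau1 = kinetics$tau1,
                                   tau2 = kinetics$tau2, e_rev = kinetics$e_rev,
                                   peak = kinetics$peak, amplitude = amplitude))
  state
}

# Summed synaptic conductance and conductance-weighted reversal drive of all
# pending events at time t. Returns c(g_total, g_times_erev_total).
.event_drive <- function(events, t) {
  if (nrow(events) == 0) return(c(0, 0))
  dt <- t - events$onset
  g <- ifelse(dt < 0, 0,
              (exp(-dt / events$tau2) - exp(-dt / events$tau1)) / events$peak) *
    events$amplitude
  c(sum(g), sum(g * events$e_rev))
}

#' Advance a neuron one time step
#'
#' Exponential-Euler update of V and of the m, h, n gating variables under
#' leak, Na+, K+ and the summed synaptic currents of the state's pending
#' events. A spike is registered on an upward crossing of 0 mV.
#'
#' @param state A [neuron_state()].
#' @param params A [neuron_params()].
#' @param dt Time step, ms; must be in (0, 0.1].
#' @param i_stim Injected current, pA.
#' @return The updated state.
#' @export
step_neuron <- function(state, params, dt, i_stim = 0) {
  stopifnot(dt > 0, dt <= 0.1)
  vals <- c(state$v, state$m, state$h, state$n)
  if (any(!is.finite(vals))) {
    bad <- c("v", "m", "h", "n")[!is.finite(vals)][1]
    stop("numerical divergence: non-finite state variable '", bad, "'")
  }
  v0 <- state$v
  r <- gate_rates(v0)
  state$m <- .gate_step(state$m, r$am, r$bm, dt)
  state$h <- .gate_step(state$h, r$ah, r$bh, dt)
  state$n <- .gate_step(state$n, r$an, r$bn, dt)

  # synaptic conductance sampled at the end of the step, matching the
  # accumulator recursion of the vectorised engine exactly
  syn <- .event_drive(state$events, state$t + dt)
  gna <- params$gna_ns * state$m^3 * state$h
  gk <- params$gk_ns * state$n^4
  gtot <- params$gl_ns + gna + gk + syn[1]
  vinf <- (params$gl_ns * params$e_leak + gna * params$e_na +
             gk * params$e_k + syn[2] + i_stim) / gtot
  state$v <- vinf + (v0 - vinf) * exp(-dt * gtot / params$c_pf)
  state$t <- state$t + dt
  if (v0 < 0 && state$v >= 0) state$spikes <- c(state$spikes, state$t)
  state
}

.gate_step <- function(x, a, b, dt) {
  tau <- 1 / (a + b)
  xinf <- a * tau
  xinf + (x - xinf) * exp(-dt / tau)
}

#' Simulate a single neuron with scheduled synaptic events
#'
#' Convenience driver around [step_neuron()].
#'
#' @param params A [neuron_params()].
#' @param events Data frame with columns `onset` (ms), `amplitude` (nS) and
#'   `type` (`"ampa"` or `"gaba"`), or `NULL`.
#' @param duration Total simulated time, ms.
#' @param dt Time step, ms.
#' @param i_stim Constant injected current, pA, or a data frame with columns
#'   `start`, `end`, `amplitude` for a pulse.
#' @param record If `TRUE`, also return the voltage trace.
#' @return List with `spikes` (times, ms), final `state`, and optionally
#'   `trace` (data.frame `t`, `v`).
#' @export
simulate_neuron <- function(params = neuron_params(), events = NULL,
                            duration = 25, dt = 0.025, i_stim = 0,
                            record = FALSE) {
  st <- neuron_state(params)
  if (!is.null(events) && nrow(events) > 0) {
    kin <- list(ampa = ampa_kinetics(), gaba = gaba_kinetics())
    for (i in seq_len(nrow(events))) {
      st <- add_synaptic_event(st, events$onset[i], kin[[events$type[i]]],
                               events$amplitude[i])
    }
  }
  n_steps <- ceiling(duration / dt)
  pulse <- is.data.frame(i_stim)
  trace <- if (record) numeric(n_steps) else NULL
  for (k in seq_len(n_steps)) {
    cur <- if (pulse) {
      t0 <- (k - 1) * dt
      sum(i_stim$amplitude[i_stim$start <= t0 & t0 < i_stim$end])
    } else i_stim
    st <- step_neuron(st, params, dt, i_stim = cur)
    if (record) trace[k] <- st$v
  }
  out <- list(spikes = st$spikes, state = st)
  if (record) out$trace <- data.frame(t = seq_len(n_steps) * dt, v = trace)
  out
}

# ---- fast internal cell engine -------------------------------------------
#
# Vectorised over neurons; synaptic conductances are tracked with rise/decay
# accumulators (exact exponential recursion of the difference-of-exponentials
# waveform) instead of per-event sums. Amplitudes added to the accumulators
# must be pre-divided by the kinetics' unit peak so that the event amplitude
# is the peak conductance, matching conductance_waveform().

.cell_consts <- function(params, dt, ampa = ampa_kinetics(),
                         gaba = gaba_kinetics()) {
  list(dt = dt, c = params$c_pf,
       gl = params$gl_ns, gna = params$gna_ns, gk = params$gk_ns,
       el = params$e_leak, ena = params$e_na, ek = params$e_k,
       ea = ampa$e_rev, eg = gaba$e_rev,
       fra = exp(-dt / ampa$tau1), fda = exp(-dt / ampa$tau2),
       pka = ampa$peak,
       frg = exp(-dt / gaba$tau1), fdg = exp(-dt / gaba$tau2),
       pkg = gaba$peak)
}

.cell_state <- function(params, n) {
  g <- steady_state_gates(params$v_rest)
  z <- numeric(n)
  list(v = rep(params$v_rest, n), m = rep(g$m, n), h = rep(g$h, n),
       n = rep(g$n, n), ra = z, da = z, rg = z, dg = z,
       spiked = logical(n))
}

.cell_step <- function(S, C, i_stim = 0) {
  v0 <- S$v
  r <- gate_rates(v0)
  S$m <- .gate_step(S$m, r$am, r$bm, C$dt)
  S$h <- .gate_step(S$h, r$ah, r$bh, C$dt)
  S$n <- .gate_step(S$n, r$an, r$bn, C$dt)
  S$ra <- S$ra * C$fra; S$da <- S$da * C$fda
  S$rg <- S$rg * C$frg; S$dg <- S$dg * C$fdg
  ga <- S$da - S$ra
  gg <- S$dg - S$rg
  gna <- C$gna * S$m * S$m * S$m * S$h
  gk <- C$gk * S$n^4
  gtot <- C$gl + gna + gk + ga + gg
  vinf <- (C$gl * C$el + gna * C$ena + gk * C$ek + ga * C$ea + gg * C$eg +
             i_stim) / gtot
  S$v <- vinf + (v0 - vinf) * exp(-C$dt * gtot / C$c)
  S$spiked <- v0 < 0 & S$v >= 0
  S
}

# Single neuron, one AMPA event at t = 0 (amplitude g_e) and one GABA event
# at t = offset (amplitude g_i). TRUE iff it spikes within `duration`.
.probe_spike <- function(params, g_e, g_i, offset, duration, dt) {
  C <- .cell_consts(params, dt)
  S <- .cell_state(params, 1)
  S$ra <- S$ra + g_e / C$pka
  S$da <- S$da + g_e / C$pka
  gaba_step <- if (g_i > 0) max(1, round(offset / dt)) else -1
  n_steps <- ceiling(duration / dt)
  for (k in seq_len(n_steps)) {
    if (k == gaba_step) {
      S$rg <- S$rg + g_i / C$pkg
      S$dg <- S$dg + g_i / C$pkg
    }
    S <- .cell_step(S, C)
    if (S$spiked) return(TRUE)
  }
  FALSE
}

#' Minimal AMPA amplitude that makes the neuron spike
#'
#' Bisection search for the smallest AMPA-event peak conductance that
#' elicits a spike when a GABA event of amplitude `g_i` arrives
#' `timing_offset` ms after the AMPA onset. The default 1.35 ms is the
#' disynaptic feedback latency measured in the explicit network: recurrent
#' AMPA and E-to-I AMPA arrive together (1 ms synaptic delay), and the
#' strongly driven interneuron converts its input to a spike in ~0.35 ms,
#' whose GABA then needs a further 1 ms delay.
#'
#' @param params A [neuron_params()].
#' @param g_i GABA event peak conductance, nS (>= 0).
#' @param timing_offset GABA onset lag relative to AMPA onset, ms.
#' @param upper Search upper bound, nS; if even this does not elicit a spike
#'   the threshold is reported as `Inf` ("unreachable").
#' @param rel_tol Relative bisection tolerance.
#' @param duration Simulated window per probe, ms; the default matches the
#'   25 ms gamma cycle used by the recall assays.
#' @param dt Integration step, ms.
#' @param lower Known subthreshold amplitude to start the bracket from
#'   (e.g. the threshold at a smaller `g_i`); speeds up table construction.
#' @return Threshold peak conductance in nS, or `Inf`.
#' @export
find_spike_threshold <- function(params = neuron_params(), g_i = 0,
                                 timing_offset = 1.35, upper = 2e4,
                                 rel_tol = 1e-3, duration = 25, dt = 0.025,
                                 lower = 0) {
  stopifnot(g_i >= 0, upper > 0, lower >= 0, lower < upper)
  probe <- function(g_e) {
    .probe_spike(params, g_e, g_i, timing_offset, duration, dt)
  }
  # bracket [lo, hi] with lo subthreshold, hi suprathreshold
  lo <- lower
  hi <- max(2 * lower, 0.25)
  while (hi < upper && !probe(hi)) {
    lo <- hi
    hi <- hi * 4
  }
  if (hi >= upper) {
    if (!probe(upper)) return(Inf)
    hi <- upper
  }
  while ((hi - lo) > rel_tol * hi) {
    mid <- (hi + lo) / 2
    if (probe(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Build a spike-threshold table
#'
#' Tabulates the minimal excitatory (AMPA) peak conductance needed to spike
#' as a function of the concurrent inhibitory (GABA) peak conductance. The
#' table substitutes for explicit integration during large parameter sweeps:
#' a neuron is predicted to fire iff its summed excitatory drive reaches the
#' interpolated threshold at its inhibitory conductance.
#'
#' @param params A [neuron_params()].
#' @param g_i_values Grid of GABA amplitudes, nS. Default: 0 plus
#'   `n_gi - 1` geometrically spaced values up to `g_i_max`.
#' @param g_i_max Largest inhibitory conductance the table must cover, nS.
#' @param n_gi Number of grid points.
#' @param timing_offset,upper,rel_tol,dt Passed to [find_spike_threshold()].
#' @return Data frame of class `threshold_table` with columns `gI`, `offset`,
#'   `threshold_gE` (nS; `Inf` where unreachable), and the neuron parameters
#'   stored as attribute `params`.
#' @export
build_threshold_table <- function(params = neuron_params(), g_i_values = NULL,
                                  g_i_max = 1e6, n_gi = 30, timing_offset = 1.35,
                                  upper = 2e4, rel_tol = 1e-3, dt = 0.025) {
  if (is.null(g_i_values)) {
    g_i_values <- c(0, exp(seq(log(g_i_max * 1e-4), log(g_i_max),
                               length.out = n_gi - 1)))
  }
  g_i_values <- sort(unique(g_i_values))
  thr <- numeric(length(g_i_values))
  prev <- 0 # threshold is monotone in gI: warm-start each bracket
  for (i in seq_along(g_i_values)) {
    prev <- find_spike_threshold(params, g_i = g_i_values[i],
                                 timing_offset = timing_offset, upper = upper,
                                 rel_tol = rel_tol, dt = dt,
                                 lower = if (is.finite(prev)) prev * 0.999 else 0)
    thr[i] <- prev
  }
  # the true threshold is monotone in gI; remove sub-tolerance bisection
  # jitter in the saturated (spike-escapes-before-GABA) regime
  thr <- cummax(thr)
  tab <- data.frame(gI = g_i_values, offset = timing_offset,
                    threshold_gE = thr)
  attr(tab, "params") <- params
  class(tab) <- c("threshold_table", "data.frame")
  tab
}

# Interpolated threshold at arbitrary gI (vectorised). Linear interpolation
# between grid points; Inf as soon as either bracketing threshold is
# unreachable (the threshold is monotone increasing in gI).
.threshold_at <- function(table, g_i) {
  if (any(g_i < 0)) stop("g_i must be non-negative")
  if (any(g_i > max(table$gI) * (1 + 1e-9))) {
    stop("extrapolation error: gI = ", format(max(g_i)),
         " exceeds table range [0, ", format(max(table$gI)),
         "]; rebuild the table with larger g_i_max")
  }
  x <- table$gI
  y <- table$threshold_gE
  idx <- findInterval(g_i, x, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  idx[idx >= length(x)] <- length(x) - 1
  x0 <- x[idx]; x1 <- x[idx + 1]
  y0 <- y[idx]; y1 <- y[idx + 1]
  w <- ifelse(x1 > x0, (g_i - x0) / (x1 - x0), 0)
  out <- y0 + w * (y1 - y0) # Inf propagates to Inf/NaN
  out[!is.finite(y0) | (!is.finite(y1) & w > 0)] <- Inf
  out
}

#' Predict spiking from a threshold table
#'
#' @param table A [build_threshold_table()] result.
#' @param g_e Summed excitatory peak conductance, nS (vectorised).
#' @param g_i Inhibitory peak conductance, nS (vectorised or scalar).
#' @return Logical vector: `TRUE` where the neuron is predicted to fire.
#' @export
threshold_lookup <- function(table, g_e, g_i = 0) {
  thr <- .threshold_at(table, rep_len(g_i, length(g_e)))
  g_e >= thr
}

#' Read/write threshold tables as CSV
#'
#' @param table A threshold table. @param path File path.
#' @return `write_threshold_table` returns `path` invisibly;
#'   `read_threshold_table` returns the table (without neuron-parameter
#'   metadata).
#' @export
write_threshold_table <- function(table, path) {
  df <- as.data.frame(table)
  df$threshold_gE[!is.finite(df$threshold_gE)] <- NA # sentinel: unreachable
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_threshold_table
#' @export
read_threshold_table <- function(path) {
  df <- utils::read.csv(path)
  df$threshold_gE[is.na(df$threshold_gE)] <- Inf
  class(df) <- c("threshold_table", "data.frame")
  df
}
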