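---
title: "Methods: model, calibrations, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, calibrations, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how the model is put together, which parameters
matter, where the design was genuinely open and what we chose, and what the
test suite does and does not establish. It states no empirical result that
the tests or the acceptance script do not themselves compute.

## The model

A recurrent network of `n_exc = 100` excitatory point neurons plus a single
interneuron that represents the pooled feedback inhibition of the circuit.
Memories are binary patterns of `pattern_size = 10` neurons. Storage is
interleaved and non-dynamical: the whole pattern set is converted at once
into per-pair coactivation counts and then into synaptic weights

$$W_{ij} = g^{\max}_{AMPA}\,\frac{n^{11}_{ij}}{n^{11}_{ij} +
(n^{10}_{ij}+n^{01}_{ij})\,\gamma_{LTD}},$$

with $W_{ij}=0$ where $n^{11}_{ij}=0$ (silent synapse) or where no
anatomical synapse exists. Recall is assayed one gamma cycle at a time:
separation (stimulate all 10 members; any other excitatory spike in the
window is a failure) and completion (stimulate 9; the holdout must fire).

### Neuron biophysics and the unit decision

The membrane uses leak, fast Na$^+$ ($m^3h$) and delayed-rectifier K$^+$
($n^4$) conductances on an isopotential 10 um sphere. The conductance
densities (0.1 / 100 / 80 per cm²) are interpreted in **mS/cm²**, not the
uS/cm² a literal reading would suggest: in uS/cm² the membrane time
constant would be $\sim 10^4$ s and the cell could never spike, whereas in
mS/cm² the values are exactly the classical reduced Traub–Miles
pyramidal-cell densities and give $\tau_m = C_m/G_{leak} = 10$ ms. The
rate functions are the standard reduced Traub–Miles set (the source model's
kinetics are published only as curves); the suite checks the qualitative
signatures (e.g. $m_\infty$ half-activation near $-40$ mV, stable rest
$\approx -66.3$ mV). This cell is deliberately very excitable: an isolated
neuron fires from a $\sim$0.1 nS peak AMPA event, so network function is
dominated by the inhibition/plasticity balance rather than by a high
intrinsic threshold.

### Synapses

Conductance waveforms are difference-of-exponentials
$e^{-t/\tau_2}-e^{-t/\tau_1}$ (AMPA 1/4 ms at 0 mV; GABA$_A$ 2/8 ms at
$-80$ mV; 1 ms synaptic delay), **normalized so the event amplitude is the
peak conductance**. The raw difference peaks at $\approx 0.472$, so without
normalization `g_max_ampa` and `gGABA` would be abstract scale factors;
with it they are peak conductances in nS, the convention most simulators
use. Feedback inhibition is calibrated to the maximal excitation a cell can
receive during a pattern:
`gGABA = g_max_ampa * pattern_size * connectivity * relative_inhibition`
(the literal constant 10 is implemented as `pattern_size`). Each excitatory
neuron also drives the interneuron at `0.9 * g_max_ampa`, and the
interneuron carries a gGABA autapse.

### Integration

Fixed-step exponential Euler at `dt = 0.025` ms for voltage and gates, with
synaptic conductances carried by exact rise/decay accumulators; spikes are
0 mV upward crossings. Two independent code paths exist — a per-event
waveform-sum integrator behind `step_neuron()`/`simulate_neuron()` and a
vectorised accumulator engine behind the network and threshold-table code —
and they agree to machine precision on voltage traces, which the dual-route
tests exploit. Halving `dt` moves spike times by well under 0.1 ms.

## The threshold table

For the 160,000-combination sweep, explicit integration is replaced by a
lookup: the minimal AMPA amplitude that fires a cell as a function of the
GABA amplitude arriving `timing_offset` ms later. Choices that matter:

* **Probe window 25 ms**, equal to the gamma cycle used by the assays, so
  "spikes" means the same thing in both paths (near-threshold spikes here
  have latencies of 10–20 ms).
* **Timing offset 1.35 ms** (configurable). A stylized argument gives 2 ms
  (1 ms E→I plus 1 ms I→E delay), but in the explicit network the recurrent
  AMPA and the E→I AMPA arrive simultaneously 1 ms after the presynaptic
  spikes, and the interneuron — driven by $10 \times 0.9\,g^{\max}$ — takes
  only $\approx 0.35$ ms to fire. The measured disynaptic lag is therefore
  $\approx 1.35$ ms; building the table at 2 ms under-weights inhibition
  and measurably degrades fast-versus-explicit agreement.
* **Bisection to 1e-3 relative tolerance**, warm-started row to row (the
  threshold is monotone in gI); sub-tolerance jitter is removed by a
  monotone (cumulative-maximum) pass. Unreachable thresholds (no spike even
  at the search bound) are stored as `Inf` and serialized as `NA` in CSV.
* **Linear interpolation in gI** over a log-spaced grid (default 30 points
  to $10^6$ nS); the threshold saturates once the E event can outrun the
  delayed GABA ($\approx 1.6$ nS for the default cell), so coarse coverage
  of large gI is cheap and accurate.

The fast assay then uses one synchronous recruitment round per cycle:
stimulated members fire; the interneuron's decision is made at gI = 0 (its
autaptic GABA arrives only after its own spike); every other neuron
compares its summed weight drive against the table threshold at
gI = gGABA or 0. Because the weight matrix has a zero diagonal, the
completion drive onto a holdout equals the full-pattern drive onto it,
which the implementation exploits.

### Fidelity, and what a green test establishes

Per-neuron agreement between the fast path and full network integration is
high in the operating regime (median per-combination agreement
$\approx 98\%$ over the optimal ensemble; the suite requires a pooled 95%
there). It degrades — to roughly 73–80% per combination — in the
near-zero-inhibition corner of the grid, where nothing stops reverberation:
neurons fire repeatedly within the 25 ms cycle and recruit second- and
higher-order spurious activity that the single-round fast path ignores by
construction. The sweep database should therefore be read as the
first-round recruitment structure of the network, exact for the balanced
networks all downstream analyses use, and only approximate deep inside the
runaway regime (where both error rates are saturated anyway). Single-neuron
fidelity of the table itself (the acceptance-grade check) is essentially
exact at the bisection tolerance.

## Parameter grids

Defaults reproduce the study grid: connectivity 20 linear values 5–100%;
`g_max_ampa` 20 values 2.78–55.56 nS — **linear**, because
$55.56/20 = 2.778$ means a linear grid with step 2.78 hits both printed
endpoints exactly, while the other two grids are the ones described as
logarithmic; `relative_inhibition` 20 log values 0.01–100;
`gamma_ltd` 20 log values 0.1–10 (consecutive ratio $10^{2/19} = 1.274$,
matching the printed "1.27-fold"). The printed "1.83-fold" increment for
the inhibition grid is inconsistent with 20 log-spaced values over 0.01–100
(which gives 1.62-fold); the 20-value/endpoint specification wins. Pattern
loads default to {5, 10, 15, 20, 25, 30}: the set of six sizes is not
enumerated in the source, and 5 and 30 are the two loads it illustrates.

`select_optimal()` minimizes the max of the two mean error rates at 50%
connectivity and 30 stored patterns; ties break by smaller
`|sep − comp|` (the better-balanced network), then lexicographically by
(`g_max_ampa`, `gamma_ltd`, `relative_inhibition`) for reproducibility —
the original tie handling is unstated.

Desk-scale runs use 5 values per free axis. One consequence, documented in
the acceptance suite: the 5-per-axis optimum at 30 patterns is poor (mean
max error near 0.9 across its top 10), so pathology analyses that need
*headroom* (the ≥20% rescue demonstration) run on a 10-per-axis sweep,
whose optimum (mean max error ≈ 0.56) can genuinely be damaged and
repaired. The trade-off directions themselves are robust at either density.

## Synthetic data: what the generator emulates

Patterns are independent uniform draws of 10 of 100 neurons — the study's
stated world. This reproduces the load-dependent accumulation of overlap
(expected pairwise overlap 1 neuron) but none of the correlation structure
of real CA3 inputs: no place-field topology, no theta-nested sequences, no
storage-order effects (interleaved learning is assumed). Error rates are
aggregated exactly as in the study design — mean over 10 random memory sets
within each of 3 connectivity profiles, then mean ± SEM over profiles — so
SEMs describe between-profile variability only.

The pathological cohort draws independent uniform *decreases* of all four
properties per individual: LTP and connectivity factors on U[0.85, 1],
LTD and inhibition factors on U[0.4, 1]. These ranges are a calibration,
not a source value: decreases of LTD/inhibition promote spurious activity
(pushing toward completion bias) while decreases of LTP/connectivity do the
opposite, and the chosen asymmetry makes the *population mean*
completion-biased — the construction the therapeutics demonstration
requires — while leaving enough heterogeneity that a minority of
individuals are separation-biased. With equal ranges on all four
properties the population bias is not reliably reproduced at desk scale.

Tolerable limits default to the optimal-ensemble mean error per type at the
same load (a mean + 1 SD option exists); "limits defined by optimal network
performance" admits either. When both errors exceed their limits,
classification follows the larger relative exceedance (unstated in the
source). Treatment line-searches a log-spaced factor grid
($2^{0.5}$–$2^{3.5}$), applied in the prescribed direction and always
including the identity, so personalized treatment can never worsen an
individual; uniform treatment applies the single factor (same grid,
population-prescribed direction) that minimizes the cohort mean max error.

## Known limitations

* Single-cycle recall only: no multi-cycle attractor dynamics, no
  theta-nested gamma, no noise currents.
* One interneuron, one inhibition amplitude: no interneuron diversity,
  no distance dependence, no synaptic stochasticity.
* No NMDA or GABA$_B$ components; plasticity is a deterministic function of
  counts with hard bounds [0, g_max].
* The completion assay averages all 10 leave-one-out holdouts per pattern
  (variance reduction); a single-random-holdout mode exists for fidelity
  comparisons since the original protocol is ambiguous.
* The full 20⁴ grid is a documented long-running mode (`--scale paper`);
  all shipped tests and examples run the desk-scale grids described above,
  so quantitative statements in the test suite are about those grids.
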