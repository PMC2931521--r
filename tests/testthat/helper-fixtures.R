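# Shared fixtures, memoised so expensive objects (threshold table, reduced
# sweep, optimal ensemble) are built once per test run. Everything is
# generated in code from fixed seeds; no files are read.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = .fx, inherits = FALSE)) {
    assign(name, build(), envir = .fx)
  }
  get(name, envir = .fx, inherits = FALSE)
}

fx_params <- function() fx("params", neuron_params)

# Default spike-threshold table (2 ms E/I offset), covering the full grid.
fx_table <- function() {
  fx("table", function() build_threshold_table(fx_params()))
}

# Reduced desk-scale sweep: 5 values per free axis, connectivity constrained
# to the wild-type 50%, loads 5 and 30.
fx_grid <- function() {
  fx("grid", function() {
    grid_spec(n_g = 5, n_inhibition = 5, n_gamma = 5,
              connectivity = 0.5, sizes = c(5, 30))
  })
}

fx_sweep <- function() {
  fx("sweep", function() run_sweep(fx_grid(), fx_table(), seed = 1))
}

# Top-10 optimal wild-type ensemble at 50% connectivity, 30 patterns.
fx_optimal <- function() {
  fx("optimal", function() select_optimal(fx_sweep(), 0.5, 30, top_k = 10))
}

fx_baseline <- function() {
  fx("baseline", function() evaluate_ensemble(fx_optimal(), fx_table(),
                                              n_patterns = 30, seed = 1))
}

fx_limits <- function() {
  fx("limits", function() tolerable_limits(fx_baseline()))
}

# Denser 10-values-per-axis sweep (still 50% connectivity, load 30): its
# tighter optimum leaves room for pathologies to degrade performance and for
# rescues to recover it, which the 5-per-axis optimum is too poor to show.
fx_sweep10 <- function() {
  fx("sweep10", function() {
    run_sweep(grid_spec(n_g = 10, n_inhibition = 10, n_gamma = 10,
                        connectivity = 0.5, sizes = 30),
              fx_table(), seed = 1)
  })
}

fx_optimal10 <- function() {
  fx("optimal10", function() select_optimal(fx_sweep10(), 0.5, 30,
                                            top_k = 10))
}

fx_limits10 <- function() {
  fx("limits10", function() {
    tolerable_limits(evaluate_ensemble(fx_optimal10(), fx_table(),
                                       n_patterns = 30, seed = 1))
  })
}

# Small standalone network used across assay tests.
fx_small_net <- function(n_patterns = 10, g_max_ampa = 5, gamma_ltd = 2,
                         relative_inhibition = 0.1) {
  cfg <- network_config(connectivity_level = 0.5, g_max_ampa = g_max_ampa,
                        gamma_ltd = gamma_ltd,
                        relative_inhibition = relative_inhibition)
  build_network(cfg, generate_pattern_set(n_patterns, cfg))
}

# Per-neuron fast-path spike predictions built from exported primitives
# only; used as the comparison route against explicit simulation.
fast_predictions <- function(net, pattern, table, holdout = NULL) {
  cfg <- net$config
  stim <- if (is.null(holdout)) pattern else setdiff(pattern, holdout)
  x <- rep(0, cfg$n_exc)
  x[stim] <- 1
  drive <- as.vector(crossprod(net$weights, x))
  i_drive <- length(stim) * cfg$e_to_i_scale * cfg$g_max_ampa
  i_fires <- threshold_lookup(table, i_drive, 0)
  g_i <- if (i_fires) feedback_inhibition_strength(cfg) else 0
  list(exc = threshold_lookup(table, drive, g_i), interneuron = i_fires)
}
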