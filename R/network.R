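# Network architecture: 100 recurrently connected excitatory neurons plus a
# single feedback interneuron that pools network activity.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Network configuration
#'
#' Bundles the four synaptic properties under study (LTP strength
#' `g_max_ampa`, LTD strength `gamma_ltd`, `relative_inhibition`, and
#' `connectivity_level`) with the structural constants of the circuit.
#'
#' @param n_exc Number of excitatory neurons.
#' @param pattern_size Neurons per stimulus pattern.
#' @param connectivity_level Fraction of possible E-to-E connections
#'   realised, in (0, 1].
#' @param g_max_ampa Peak AMPA conductance of a fully potentiated synapse,
#'   nS (LTP strength).
#' @param gamma_ltd Dimensionless LTD strength (> 0).
#' @param relative_inhibition Feedback GABA conductance relative to the
#'   maximal excitation a neuron can receive during a pattern (>= 0).
#' @param e_to_i_scale Strength of each excitatory synapse onto the
#'   interneuron, as a fraction of `g_max_ampa`.
#' @param conn_seed,pattern_seed Default RNG seeds for connectivity and
#'   pattern generation.
#' @return Object of class `ca3_config`.
#' @export
network_config <- function(n_exc = 100, pattern_size = 10,
                           connectivity_level = 0.5, g_max_ampa = 10,
                           gamma_ltd = 1, relative_inhibition = 0.1,
                           e_to_i_scale = 0.9,
                           conn_seed = 1L, pattern_seed = 1L) {
  stopifnot(n_exc >= 2, pattern_size >= 1, pattern_size <= n_exc,
            g_max_ampa >= 0, relative_inhibition >= 0,
            e_to_i_scale >= 0)
  if (gamma_ltd <= 0) stop("gamma_ltd must be > 0")
  if (connectivity_level <= 0 || connectivity_level > 1) {
    stop("connectivity_level must be in (0, 1]")
  }
  structure(list(n_exc = as.integer(n_exc),
                 pattern_size = as.integer(pattern_size),
                 connectivity_level = connectivity_level,
                 g_max_ampa = g_max_ampa, gamma_ltd = gamma_ltd,
                 relative_inhibition = relative_inhibition,
                 e_to_i_scale = e_to_i_scale,
                 conn_seed = as.integer(conn_seed),
                 pattern_seed = as.integer(pattern_seed)),
            class = "ca3_config")
}

#' @export
print.ca3_config <- function(x, ...) {
  cat(sprintf(paste0("ca3_config: %d excitatory neurons, patterns of %d\n",
                     "  connectivity %.3f | gMaxAMPA %.3g nS | gammaLTD %.3g",
                     " | rel. inhibition %.3g\n  gGABA %.3g nS\n"),
              x$n_exc, x$pattern_size, x$connectivity_level, x$g_max_ampa,
              x$gamma_ltd, x$relative_inhibition,
              feedback_inhibition_strength(x)))
  invisible(x)
}

#' Random recurrent connectivity with fixed out-degree
#'
#' Every presynaptic neuron projects to exactly
#' `round(connectivity_level * (n_exc - 1))` randomly chosen postsynaptic
#' targets (half-up rounding), with no autapses among excitatory cells.
#'
#' @param config A [network_config()].
#' @param seed RNG seed; defaults to `config$conn_seed`.
#' @return Logical `n_exc x n_exc` matrix, `[i, j]` meaning a synapse from
#'   presynaptic `i` onto postsynaptic `j`; diagonal all `FALSE`.
#' @export
build_connectivity <- function(config, seed = config$conn_seed) {
  n <- config$n_exc
  k <- floor(config$connectivity_level * (n - 1) + 0.5)
  if (k < 1) stop("connectivity_level too low: no connections")
  adj <- matrix(FALSE, n, n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      targets <- sample((seq_len(n))[-i], k)
      adj[i, targets] <- TRUE
    }
  })
  adj
}

#' Feedback inhibition strength
#'
#' Peak GABA conductance each excitatory neuron (and the interneuron's
#' autapse) receives when the interneuron fires, scaled to the maximal total
#' excitation a pyramidal cell can receive during a stimulus pattern:
#' `gGABA = g_max_ampa * pattern_size * connectivity_level *
#' relative_inhibition`.
#'
#' @param config A [network_config()].
#' @return Conductance in nS.
#' @export
feedback_inhibition_strength <- function(config) {
  config$g_max_ampa * config$pattern_size * config$connectivity_level *
    config$relative_inhibition
}
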