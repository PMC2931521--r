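# Hebbian LTP/LTD rule converting coactivation counts into peak AMPA
# conductances. All synapses start silent; co-firing within a pattern
# potentiates towards g_max_ampa, asynchronous firing across patterns
# depresses with strength gamma_ltd.

#' Synaptic weight from coactivation counts
#'
#' `W = g_max_ampa * n11 / (n11 + (n10 + n01) * gamma_ltd)`, with `W = 0`
#' when `n11 = 0` (silent synapse). The synchronous-coactivation coefficient
#' is fixed at 1, so a synapse whose pre/post pair only ever fires together
#' is fully potentiated at `g_max_ampa`.
#'
#' @param n11,n10,n01 Non-negative pattern counts (vectorised).
#' @param g_max_ampa Maximal (fully potentiated) conductance, nS.
#' @param gamma_ltd LTD strength, > 0.
#' @return Weights in nS, in `[0, g_max_ampa]`.
#' @export
compute_weight <- function(n11, n10, n01, g_max_ampa, gamma_ltd) {
  if (any(gamma_ltd <= 0)) stop("gamma_ltd must be > 0")
  if (any(n11 < 0) || any(n10 < 0) || any(n01 < 0)) {
    stop("counts must be non-negative")
  }
  w <- g_max_ampa * n11 / (n11 + (n10 + n01) * gamma_ltd)
  w[n11 == 0] <- 0
  w
}

#' Build the full weight matrix
#'
#' Applies [compute_weight()] elementwise over anatomical synapses.
#'
#' @param counts A [count_pair_activity()] result.
#' @param config A [network_config()].
#' @return `n_exc x n_exc` matrix of peak AMPA conductances (nS), zero off
#'   the anatomical adjacency.
#' @export
build_weight_matrix <- function(counts, config) {
  w <- compute_weight(counts$n11, counts$n10, counts$n01,
                      config$g_max_ampa, config$gamma_ltd)
  w * (counts$adjacency * 1)
}
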