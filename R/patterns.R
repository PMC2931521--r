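# Stimulus patterns (the model's only "data") and the coactivation counts
# that drive synaptic plasticity.

#' Generate a random stimulus-pattern set
#'
#' Each pattern is a uniformly random draw of `pattern_size` distinct
#' excitatory-neuron indices; patterns are sampled independently of one
#' another, so larger sets accumulate more chance overlap (the expected
#' overlap of two patterns is `pattern_size^2 / n_exc` neurons).
#'
#' @param n_patterns Number of patterns (>= 1).
#' @param config A [network_config()].
#' @param seed RNG seed; defaults to `config$pattern_seed`.
#' @return Object of class `pattern_set`: a list of sorted integer vectors
#'   with attributes `seed` and `n_exc`.
#' @export
generate_pattern_set <- function(n_patterns, config,
                                 seed = config$pattern_seed) {
  stopifnot(n_patterns >= 1)
  if (config$pattern_size > config$n_exc) {
    stop("pattern_size exceeds n_exc")
  }
  pats <- with_seed(seed, {
    lapply(seq_len(n_patterns), function(i) {
      sort(sample.int(config$n_exc, config$pattern_size))
    })
  })
  structure(pats, seed = seed, n_exc = config$n_exc, class = "pattern_set")
}

# n_exc x n_patterns 0/1 membership matrix.
pattern_matrix <- function(patterns, n_exc = attr(patterns, "n_exc")) {
  x <- matrix(0L, n_exc, length(patterns))
  for (j in seq_along(patterns)) x[patterns[[j]], j] <- 1L
  x
}

#' Per-pair coactivation counts
#'
#' For every ordered, anatomically connected pair (presynaptic i,
#' postsynaptic j), counts over the stored set: `n11` patterns where both
#' fire, `n10` where only the presynaptic fires, `n01` where only the
#' postsynaptic fires. Entries without an anatomical synapse are zero.
#'
#' @param patterns A [generate_pattern_set()] result.
#' @param adjacency Logical connectivity matrix from [build_connectivity()].
#' @return List of class `pair_counts` with integer matrices `n11`, `n10`,
#'   `n01` and the `adjacency` mask.
#' @export
count_pair_activity <- function(patterns, adjacency) {
  x <- pattern_matrix(patterns, nrow(adjacency))
  joint <- x %*% t(x)               # co-membership counts, all pairs
  per <- rowSums(x)                 # patterns containing each neuron
  n11 <- joint
  n10 <- matrix(per, nrow(x), nrow(x)) - joint        # row i: pre-only
  n01 <- matrix(per, nrow(x), nrow(x), byrow = TRUE) - joint
  mask <- adjacency * 1L
  structure(list(n11 = n11 * mask, n10 = n10 * mask, n01 = n01 * mask,
                 adjacency = adjacency),
            class = "pair_counts")
}
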