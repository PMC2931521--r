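# Pattern-separation and pattern-completion assays over one gamma cycle,
# either by explicit conductance-based simulation of the whole circuit or
# by the spike-threshold-table fast path used for large sweeps.

#' Assemble a network realization
#'
#' Draws the connectivity, stores a pattern set through the plasticity rule
#' and attaches the feedback-inhibition strength, yielding everything needed
#' to run the recall assays.
#'
#' @param config A [network_config()].
#' @param patterns A [generate_pattern_set()] result (weights are built from
#'   this set).
#' @param conn_seed Connectivity seed; defaults to `config$conn_seed`.
#' @return Object of class `ca3_network`: `config`, `adjacency`, `counts`,
#'   `weights`, `g_gaba`, `patterns`.
#' @export
build_network <- function(config, patterns, conn_seed = config$conn_seed) {
  adjacency <- build_connectivity(config, seed = conn_seed)
  counts <- count_pair_activity(patterns, adjacency)
  structure(list(config = config, adjacency = adjacency, counts = counts,
                 weights = build_weight_matrix(counts, config),
                 g_gaba = feedback_inhibition_strength(config),
                 patterns = patterns),
            class = "ca3_network")
}

#' Explicitly simulate one gamma cycle of the full network
#'
#' All `n_exc` excitatory neurons plus the interneuron are integrated with
#' the exponential-Euler scheme. Stimulated neurons are forced to fire by a
#' brief suprathreshold current pulse at cycle onset. Every excitatory spike
#' delivers (after the 1 ms synaptic delay) AMPA events onto its anatomical
#' targets with the learned weights and onto the interneuron at
#' `e_to_i_scale * g_max_ampa`; an interneuron spike delivers GABA of
#' amplitude `g_gaba` onto every excitatory cell and onto itself (autapse).
#'
#' @param network A [build_network()] result.
#' @param stimulated Integer indices of directly activated neurons.
#' @param window Cycle duration, ms.
#' @param dt Integration step, ms.
#' @param params A [neuron_params()].
#' @param stim_current,stim_duration Amplitude (pA) and duration (ms) of the
#'   activating pulse.
#' @return Data frame with columns `neuron` (interneuron is `n_exc + 1`) and
#'   `time` (ms) of every spike in the window.
#' @export
simulate_network_cycle <- function(network, stimulated, window = 25,
                                   dt = 0.025, params = neuron_params(),
                                   stim_current = 200, stim_duration = 2) {
  if (window <= 0) stop("window must be positive")
  cfg <- network$config
  n <- cfg$n_exc
  ntot <- n + 1L
  w <- network$weights
  g_e2i <- cfg$e_to_i_scale * cfg$g_max_ampa
  delay_steps <- max(1L, as.integer(round(1 / dt))) # 1 ms synaptic delay
  n_steps <- as.integer(ceiling(window / dt))
  stim_steps <- as.integer(ceiling(stim_duration / dt))

  C <- .cell_consts(params, dt)
  S <- .cell_state(params, ntot)
  pend_a <- matrix(0, n_steps + delay_steps + 1L, ntot)
  pend_g <- matrix(0, n_steps + delay_steps + 1L, ntot)
  stim_vec <- numeric(ntot)
  stim_vec[stimulated] <- stim_current

  sp_neuron <- integer(0)
  sp_time <- numeric(0)
  for (k in seq_len(n_steps)) {
    add_a <- pend_a[k, ]
    add_g <- pend_g[k, ]
    if (any(add_a > 0)) {
      S$ra <- S$ra + add_a / C$pka
      S$da <- S$da + add_a / C$pka
    }
    if (any(add_g > 0)) {
      S$rg <- S$rg + add_g / C$pkg
      S$dg <- S$dg + add_g / C$pkg
    }
    S <- .cell_step(S, C, i_stim = if (k <= stim_steps) stim_vec else 0)
    if (any(S$spiked)) {
      ids <- which(S$spiked)
      sp_neuron <- c(sp_neuron, ids)
      sp_time <- c(sp_time, rep(k * dt, length(ids)))
      kk <- k + delay_steps
      e_ids <- ids[ids <= n]
      if (length(e_ids) > 0) {
        pend_a[kk, seq_len(n)] <- pend_a[kk, seq_len(n)] +
          colSums(w[e_ids, , drop = FALSE])
        pend_a[kk, ntot] <- pend_a[kk, ntot] + length(e_ids) * g_e2i
      }
      if (any(ids == ntot)) {
        pend_g[kk, ] <- pend_g[kk, ] + network$g_gaba
      }
    }
  }
  data.frame(neuron = sp_neuron, time = sp_time)
}

# ---- fast (threshold table) spike predictions -----------------------------
#
# One synchronous recruitment round per cycle: the stimulated neurons fire;
# the interneuron's decision is made first from its summed drive at gI = 0
# (its autaptic inhibition arrives only after its own spike); every other
# decision compares summed excitatory drive against the table threshold at
# gI = g_gaba (interneuron fired) or 0.
.fast_outcomes <- function(network, patterns, table,
                           completion_holdouts = "all", holdout_seed = 1) {
  cfg <- network$config
  x <- pattern_matrix(patterns, cfg$n_exc)
  member <- x > 0
  drive <- crossprod(network$weights, x)  # [neuron, pattern], full-pattern stim
  g_e2i <- cfg$e_to_i_scale * cfg$g_max_ampa
  psz <- colSums(x)
  thr0 <- .threshold_at(table, 0)

  # separation: all pattern members stimulated
  i_fires_sep <- (psz * g_e2i) >= thr0
  thr_sep <- .threshold_at(table, ifelse(i_fires_sep, network$g_gaba, 0))
  spurious <- sweep(drive, 2, thr_sep, ">=") & !member
  sep_fail <- colSums(spurious) > 0

  # completion: pattern_size - 1 members stimulated; with a zero diagonal the
  # drive onto holdout k from the other members equals drive[k, p]
  i_fires_comp <- ((psz - 1) * g_e2i) >= thr0
  thr_comp <- .threshold_at(table, ifelse(i_fires_comp, network$g_gaba, 0))
  completed <- sweep(drive, 2, thr_comp, ">=")
  comp_fail <- vapply(seq_along(patterns), function(p) {
    ks <- patterns[[p]]
    if (completion_holdouts == "single") {
      ks <- with_seed(holdout_seed + p, sample(ks, 1))
    }
    mean(!completed[ks, p])
  }, numeric(1))
  list(sep_fail = sep_fail, comp_fail = comp_fail)
}

#' Pattern-separation assay
#'
#' Each stored pattern's neurons are activated at cycle onset; the pattern
#' fails separation if one or more non-member excitatory neurons fire within
#' the gamma window.
#'
#' @param network A [build_network()] result (weights built from
#'   `patterns`).
#' @param patterns Pattern set; defaults to the set stored in the network.
#' @param window Gamma-cycle window, ms (explicit method only).
#' @param method `"fast"` (threshold table, default) or `"explicit"`
#'   (full simulation).
#' @param table Threshold table, required for the fast method.
#' @param ... Passed to [simulate_network_cycle()].
#' @return Logical vector, `TRUE` where the pattern failed separation.
#' @export
assay_separation <- function(network, patterns = network$patterns,
                             window = 25, method = c("fast", "explicit"),
                             table = NULL, ...) {
  if (window <= 0) stop("window must be positive")
  method <- match.arg(method)
  if (method == "fast") {
    if (is.null(table)) stop("the fast method requires a threshold table")
    return(.fast_outcomes(network, patterns, table)$sep_fail)
  }
  n <- network$config$n_exc
  vapply(patterns, function(pat) {
    sp <- simulate_network_cycle(network, pat, window = window, ...)
    any(sp$neuron <= n & !(sp$neuron %in% pat))
  }, logical(1))
}

#' Pattern-completion assay
#'
#' For each stored pattern, all but one member are activated and the pattern
#' is completed if the held-out member fires within the gamma window. By
#' default every leave-one-out holdout is tested and the per-pattern error
#' is the fraction of failed holdouts; `holdouts = "single"` tests one
#' randomly chosen holdout per pattern.
#'
#' @inheritParams assay_separation
#' @param holdouts `"all"` or `"single"`.
#' @param holdout_seed Seed for the single-holdout choice.
#' @return Numeric vector in `[0, 1]`: per-pattern completion error.
#' @export
assay_completion <- function(network, patterns = network$patterns,
                             window = 25, method = c("fast", "explicit"),
                             table = NULL, holdouts = c("all", "single"),
                             holdout_seed = 1, ...) {
  if (window <= 0) stop("window must be positive")
  method <- match.arg(method)
  holdouts <- match.arg(holdouts)
  if (method == "fast") {
    if (is.null(table)) stop("the fast method requires a threshold table")
    return(.fast_outcomes(network, patterns, table,
                          completion_holdouts = holdouts,
                          holdout_seed = holdout_seed)$comp_fail)
  }
  vapply(seq_along(patterns), function(p) {
    pat <- patterns[[p]]
    ks <- if (holdouts == "single") {
      with_seed(holdout_seed + p, sample(pat, 1))
    } else pat
    fails <- vapply(ks, function(k) {
      sp <- simulate_network_cycle(network, setdiff(pat, k),
                                   window = window, ...)
      !(k %in% sp$neuron)
    }, logical(1))
    mean(fails)
  }, numeric(1))
}

#' Run both assays via the threshold-table fast path
#'
#' @param network A [build_network()] result.
#' @param patterns Pattern set; defaults to the network's stored set.
#' @param table Threshold table from [build_threshold_table()].
#' @return Object of class `assay_result`: per-pattern `separation` (logical
#'   fail) and `completion` (error fraction), the two error rates, and
#'   `max_error = max(separation_error_rate, completion_error_rate)`.
#' @export
fast_assay <- function(network, patterns = network$patterns, table) {
  out <- .fast_outcomes(network, patterns, table)
  sep <- mean(out$sep_fail)
  comp <- mean(out$comp_fail)
  structure(list(separation = out$sep_fail, completion = out$comp_fail,
                 separation_error_rate = sep, completion_error_rate = comp,
                 max_error = max(sep, comp),
                 n_patterns = length(patterns)),
            class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  cat(sprintf("assay_result: %d patterns | separation %.3f | completion %.3f | max %.3f\n",
              x$n_patterns, x$separation_error_rate,
              x$completion_error_rate, x$max_error))
  invisible(x)
}

#' Aggregate per-run error rates across seeds and connectivity profiles
#'
#' Averages the per-run rates over pattern-set seeds within each
#' connectivity profile, then reports mean and SEM across profiles.
#'
#' @param runs Data frame with columns `profile`, `set`, `sep_err`,
#'   `comp_err`; the (profile, set) grid must be complete.
#' @return List with `sep_err`, `comp_err`, `max_err` (max of the two
#'   means), `sep_sem`, `comp_sem`, `n_profiles`.
#' @export
aggregate_errors <- function(runs) {
  stopifnot(all(c("profile", "set", "sep_err", "comp_err") %in% names(runs)))
  profiles <- sort(unique(runs$profile))
  sets <- sort(unique(runs$set))
  want <- expand.grid(profile = profiles, set = sets)
  have <- paste(runs$profile, runs$set)
  missing <- want[!(paste(want$profile, want$set) %in% have), ]
  if (nrow(missing) > 0) {
    stop("incomplete run grid; missing (profile, set): ",
         paste(sprintf("(%s, %s)", missing$profile, missing$set),
               collapse = ", "))
  }
  by_prof_sep <- tapply(runs$sep_err, runs$profile, mean)
  by_prof_comp <- tapply(runs$comp_err, runs$profile, mean)
  np <- length(profiles)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  list(sep_err = mean(by_prof_sep), comp_err = mean(by_prof_comp),
       max_err = max(mean(by_prof_sep), mean(by_prof_comp)),
       sep_sem = sem(by_prof_sep), comp_sem = sem(by_prof_comp),
       n_profiles = np)
}

#' Evaluate one parameter combination over the full run grid
#'
#' Runs the fast assays for `n_profiles` connectivity profiles x `n_sets`
#' random memory sets (the study design: 3 profiles x 10 sets) and
#' aggregates with [aggregate_errors()]. Seeds are derived deterministically
#' from `seed` so that evaluations of different parameter combinations are
#' paired.
#'
#' @param config A [network_config()].
#' @param table Threshold table covering the configuration's conductances.
#' @param n_patterns Number of stored patterns.
#' @param n_profiles,n_sets Run-grid dimensions.
#' @param seed Base seed.
#' @return The [aggregate_errors()] list, plus `n_patterns`.
#' @export
evaluate_config <- function(config, table, n_patterns, n_profiles = 3,
                            n_sets = 10, seed = 1) {
  rows <- vector("list", n_profiles * n_sets)
  r <- 0L
  for (p in seq_len(n_profiles)) {
    adjacency <- build_connectivity(config, seed = seed + 7919L * p)
    for (s in seq_len(n_sets)) {
      pats <- generate_pattern_set(n_patterns, config,
                                   seed = seed + 104729L * p + s)
      counts <- count_pair_activity(pats, adjacency)
      net <- structure(list(config = config, adjacency = adjacency,
                            counts = counts,
                            weights = build_weight_matrix(counts, config),
                            g_gaba = feedback_inhibition_strength(config),
                            patterns = pats),
                       class = "ca3_network")
      out <- .fast_outcomes(net, pats, table)
      r <- r + 1L
      rows[[r]] <- data.frame(profile = p, set = s,
                              sep_err = mean(out$sep_fail),
                              comp_err = mean(out$comp_fail))
    }
  }
  agg <- aggregate_errors(do.call(rbind, rows))
  agg$n_patterns <- n_patterns
  agg
}
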