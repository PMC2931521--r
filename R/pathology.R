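# Simulated synaptic pathologies and the personalized-therapeutics
# analysis: perturb optimal networks, map the completion/separation
# trade-off, classify network bias, and prescribe/apply rebalancing
# manipulations.

.properties <- c("ltp", "ltd", "inhibition", "connectivity")

#' Pathology specification
#'
#' Multiplicative perturbation factors for LTP (`g_max_ampa`), LTD
#' (`gamma_ltd`) and relative inhibition, plus an absolute
#' percentage-point shift (as a fraction, e.g. `0.2` for +20 points) and/or
#' a multiplicative factor for the connectivity level.
#'
#' @param ltp_factor,ltd_factor,inhibition_factor Positive factors.
#' @param connectivity_delta Additive change of the connectivity fraction.
#' @param connectivity_factor Multiplicative change of the connectivity
#'   fraction (applied before the delta).
#' @return Object of class `pathology_spec`.
#' @export
pathology_spec <- function(ltp_factor = 1, ltd_factor = 1,
                           inhibition_factor = 1, connectivity_delta = 0,
                           connectivity_factor = 1) {
  stopifnot(ltp_factor > 0, ltd_factor > 0, inhibition_factor > 0,
            connectivity_factor > 0)
  structure(list(ltp_factor = ltp_factor, ltd_factor = ltd_factor,
                 inhibition_factor = inhibition_factor,
                 connectivity_delta = connectivity_delta,
                 connectivity_factor = connectivity_factor),
            class = "pathology_spec")
}

#' Apply a pathology to a network configuration
#'
#' Scales the four synaptic properties; the feedback inhibition conductance
#' gGABA is not stored but recomputed from the perturbed g_max_ampa,
#' connectivity and relative inhibition wherever it is used, so it follows
#' the perturbation automatically. Perturbed connectivity is clipped to at
#' most 100%; a non-positive result is an error.
#'
#' @param config A [network_config()].
#' @param spec A [pathology_spec()].
#' @return A new `ca3_config`.
#' @export
apply_pathology <- function(config, spec) {
  conn <- config$connectivity_level * spec$connectivity_factor +
    spec$connectivity_delta
  if (conn <= 0) stop("perturbed connectivity is non-positive")
  network_config(n_exc = config$n_exc, pattern_size = config$pattern_size,
                 connectivity_level = min(conn, 1),
                 g_max_ampa = config$g_max_ampa * spec$ltp_factor,
                 gamma_ltd = config$gamma_ltd * spec$ltd_factor,
                 relative_inhibition = config$relative_inhibition *
                   spec$inhibition_factor,
                 e_to_i_scale = config$e_to_i_scale,
                 conn_seed = config$conn_seed,
                 pattern_seed = config$pattern_seed)
}

# pathology_spec perturbing one named property by `value` (a factor, or an
# additive delta for connectivity).
.single_spec <- function(property, value, connectivity_as_delta = TRUE) {
  switch(property,
         ltp = pathology_spec(ltp_factor = value),
         ltd = pathology_spec(ltd_factor = value),
         inhibition = pathology_spec(inhibition_factor = value),
         connectivity = if (connectivity_as_delta) {
           pathology_spec(connectivity_delta = value)
         } else {
           pathology_spec(connectivity_factor = value)
         },
         stop("unknown property '", property, "'"))
}

#' Evaluate an ensemble of network configurations
#'
#' @param networks Data frame with columns `connectivity`, `g_max_ampa`,
#'   `gamma_ltd`, `relative_inhibition` (e.g. a [select_optimal()] result),
#'   or a list of `ca3_config` objects.
#' @param table Threshold table.
#' @param n_patterns Memory load.
#' @param spec Optional [pathology_spec()] applied to every network first.
#' @param n_profiles,n_sets,seed Run grid passed to [evaluate_config()].
#' @return Data frame with one row per network: `sep_err`, `comp_err`,
#'   `max_err`.
#' @export
evaluate_ensemble <- function(networks, table, n_patterns = 30, spec = NULL,
                              n_profiles = 3, n_sets = 10, seed = 1) {
  configs <- if (is.data.frame(networks)) {
    lapply(seq_len(nrow(networks)), function(i) {
      config_from_row(networks[i, ])
    })
  } else networks
  rows <- lapply(configs, function(cfg) {
    if (!is.null(spec)) cfg <- apply_pathology(cfg, spec)
    ev <- evaluate_config(cfg, table, n_patterns, n_profiles = n_profiles,
                          n_sets = n_sets, seed = seed)
    data.frame(sep_err = ev$sep_err, comp_err = ev$comp_err,
               max_err = ev$max_err)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Error rates as one synaptic property is perturbed
#'
#' Re-assesses the mean completion and separation error of the optimal
#' ensemble while one property is scaled through a grid of factors
#' (connectivity: additive percentage-point deltas expressed as fractions).
#' The identity value (1, or 0 for connectivity) reproduces the baseline.
#'
#' @param networks Optimal ensemble (see [evaluate_ensemble()]).
#' @param table Threshold table.
#' @param property One of `"ltp"`, `"ltd"`, `"inhibition"`,
#'   `"connectivity"`.
#' @param values Perturbation grid; defaults to symmetric log factors
#'   `{1/4, 1/2, 1/sqrt 2, 1, sqrt 2, 2, 4}` (connectivity:
#'   `{-0.3 ... +0.3}` in 0.1 steps).
#' @param n_patterns,n_profiles,n_sets,seed Passed through.
#' @return Data frame: `property`, `value`, `sep_err`, `comp_err`,
#'   `max_err` (ensemble means).
#' @export
single_pathology_curves <- function(networks, table, property,
                                    values = NULL, n_patterns = 30,
                                    n_profiles = 3, n_sets = 10, seed = 1) {
  property <- match.arg(property, .properties)
  if (is.null(values)) {
    values <- if (property == "connectivity") {
      seq(-0.3, 0.3, by = 0.1)
    } else {
      c(0.25, 0.5, 1 / sqrt(2), 1, sqrt(2), 2, 4)
    }
  }
  rows <- lapply(values, function(v) {
    ev <- evaluate_ensemble(networks, table, n_patterns,
                            spec = .single_spec(property, v),
                            n_profiles = n_profiles, n_sets = n_sets,
                            seed = seed)
    data.frame(property = property, value = v,
               sep_err = mean(ev$sep_err), comp_err = mean(ev$comp_err),
               max_err = mean(ev$max_err))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean max-error surface for simultaneous perturbation of two properties
#'
#' @param networks Optimal ensemble.
#' @param table Threshold table.
#' @param properties Character vector of two distinct property names.
#' @param values1,values2 Perturbation grids (defaults as in
#'   [single_pathology_curves()]).
#' @param n_patterns,n_profiles,n_sets,seed Passed through.
#' @return Data frame: `value1`, `value2`, `sep_err`, `comp_err`,
#'   `max_err` (ensemble means); the identity cell is the unperturbed
#'   baseline.
#' @export
interaction_surface <- function(networks, table, properties,
                                values1 = NULL, values2 = NULL,
                                n_patterns = 30, n_profiles = 3,
                                n_sets = 10, seed = 1) {
  stopifnot(length(properties) == 2)
  p1 <- match.arg(properties[1], .properties)
  p2 <- match.arg(properties[2], .properties)
  if (p1 == p2) stop("properties must be distinct")
  default_grid <- function(p) {
    if (p == "connectivity") seq(-0.3, 0.3, by = 0.1)
    else c(0.25, 0.5, 1 / sqrt(2), 1, sqrt(2), 2, 4)
  }
  if (is.null(values1)) values1 <- default_grid(p1)
  if (is.null(values2)) values2 <- default_grid(p2)
  grid <- expand.grid(value1 = values1, value2 = values2,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s1 <- .single_spec(p1, grid$value1[i])
    s2 <- .single_spec(p2, grid$value2[i])
    spec <- pathology_spec(
      ltp_factor = s1$ltp_factor * s2$ltp_factor,
      ltd_factor = s1$ltd_factor * s2$ltd_factor,
      inhibition_factor = s1$inhibition_factor * s2$inhibition_factor,
      connectivity_delta = s1$connectivity_delta + s2$connectivity_delta,
      connectivity_factor = s1$connectivity_factor * s2$connectivity_factor)
    ev <- evaluate_ensemble(networks, table, n_patterns, spec = spec,
                            n_profiles = n_profiles, n_sets = n_sets,
                            seed = seed)
    data.frame(value1 = grid$value1[i], value2 = grid$value2[i],
               sep_err = mean(ev$sep_err), comp_err = mean(ev$comp_err),
               max_err = mean(ev$max_err))
  })
  out <- do.call(rbind, rows)
  attr(out, "properties") <- c(p1, p2)
  rownames(out) <- NULL
  out
}

#' Tolerable error limits from the optimal ensemble
#'
#' @param baseline [evaluate_ensemble()] result for the unperturbed optimal
#'   networks at the load of interest.
#' @param type `"mean"` (default): ensemble mean error per type;
#'   `"mean_sd"`: mean + 1 SD.
#' @return List with `sep_limit` and `comp_limit`.
#' @export
tolerable_limits <- function(baseline, type = c("mean", "mean_sd")) {
  type <- match.arg(type)
  bump <- if (type == "mean_sd") 1 else 0
  list(sep_limit = mean(baseline$sep_err) + bump * stats::sd(baseline$sep_err),
       comp_limit = mean(baseline$comp_err) + bump * stats::sd(baseline$comp_err))
}

#' Classify a network's performance bias
#'
#' A *separation bias* is a network whose completion error exceeds its
#' tolerable limit while separation error does not (separation performance
#' is preserved at the cost of completion), and symmetrically for
#' *completion bias*. If both exceed their limits the label follows the
#' larger relative exceedance; if neither does, the network is `balanced`.
#'
#' @param result List or one-row data frame with `sep_err` and `comp_err`.
#' @param limits A [tolerable_limits()] list.
#' @return Object of class `bias_classification`: `label` (one of
#'   `"separation_bias"`, `"completion_bias"`, `"balanced"`), the `limits`
#'   used, and the relative `exceedance` per error type.
#' @export
classify_bias <- function(result, limits) {
  eps <- 1e-9
  exc_sep <- (result$sep_err - limits$sep_limit) / max(limits$sep_limit, eps)
  exc_comp <- (result$comp_err - limits$comp_limit) /
    max(limits$comp_limit, eps)
  label <- if (exc_comp > 0 && exc_sep <= 0) "separation_bias"
  else if (exc_sep > 0 && exc_comp <= 0) "completion_bias"
  else if (exc_sep > 0 && exc_comp > 0) {
    if (exc_comp > exc_sep) "separation_bias" else "completion_bias"
  } else "balanced"
  structure(list(label = label, limits = limits,
                 exceedance = c(sep = exc_sep, comp = exc_comp)),
            class = "bias_classification")
}

#' Therapeutic directions for a network bias
#'
#' A separation-biased network (intolerable completion error) calls for
#' manipulations that favour completion: increase LTP, decrease LTD,
#' decrease inhibition, increase connectivity. A completion-biased network
#' calls for the four opposite directions. A balanced network gets no
#' prescription.
#'
#' @param bias A [classify_bias()] result, or a label string.
#' @return Named character vector over `ltp`, `ltd`, `inhibition`,
#'   `connectivity` with values `"increase"`/`"decrease"`; empty for
#'   balanced.
#' @export
prescribe <- function(bias) {
  label <- if (inherits(bias, "bias_classification")) bias$label else bias
  up <- c(ltp = "increase", ltd = "decrease", inhibition = "decrease",
          connectivity = "increase")
  down <- c(ltp = "decrease", ltd = "increase", inhibition = "increase",
            connectivity = "decrease")
  switch(label,
         separation_bias = up,
         completion_bias = down,
         balanced = stats::setNames(character(0), character(0)),
         stop("unknown bias label '", label, "'"))
}

#' Generate a heterogeneous pathological cohort
#'
#' Each optimal network becomes one "individual", perturbed with
#' independent uniform random decreases of all four synaptic properties
#' (connectivity multiplicatively, then clipped to (0, 1]). The default
#' ranges emulate a schizophrenia-like population in which decreased
#' inhibition/LTD outweigh decreased LTP/connectivity, so that the cohort
#' mean shows a completion bias while individual heterogeneity still
#' produces some separation-biased members.
#'
#' @param networks Optimal ensemble (data frame, see
#'   [evaluate_ensemble()]).
#' @param ranges Named list of `c(min, max)` factor ranges per property.
#' @param seed RNG seed.
#' @return Data frame of class `cohort`: one row per individual with its
#'   perturbed parameters and the drawn factors.
#' @export
generate_cohort <- function(networks,
                            ranges = list(ltp = c(0.85, 1),
                                          ltd = c(0.4, 1),
                                          inhibition = c(0.4, 1),
                                          connectivity = c(0.85, 1)),
                            seed = 1) {
  stopifnot(is.data.frame(networks))
  n <- nrow(networks)
  fac <- with_seed(seed, {
    vapply(.properties, function(p) {
      stats::runif(n, ranges[[p]][1], ranges[[p]][2])
    }, numeric(n))
  })
  fac <- matrix(fac, nrow = n,
                dimnames = list(NULL, paste0(.properties, "_factor")))
  out <- data.frame(
    individual = seq_len(n),
    connectivity = pmin(1, networks$connectivity * fac[, "connectivity_factor"]),
    g_max_ampa = networks$g_max_ampa * fac[, "ltp_factor"],
    gamma_ltd = networks$gamma_ltd * fac[, "ltd_factor"],
    relative_inhibition = networks$relative_inhibition *
      fac[, "inhibition_factor"],
    fac)
  class(out) <- c("cohort", "data.frame")
  out
}

#' Personalized versus uniform treatment of a cohort
#'
#' Each individual is assayed, classified against the wild-type tolerable
#' limits, and treated along the prescribed direction of `target_property`:
#' the treatment factor is chosen from a log-spaced grid (always including
#' the identity) to minimize that individual's max error. For comparison, a
#' uniform therapy applies one shared factor, in the direction prescribed
#' by the cohort mean bias, chosen to minimize the cohort mean max error.
#'
#' @param cohort A [generate_cohort()] data frame.
#' @param table Threshold table.
#' @param limits [tolerable_limits()] of the wild-type ensemble at the same
#'   load.
#' @param target_property Property targeted by the drug (default
#'   `"inhibition"`).
#' @param factors Candidate magnitudes (> 1) applied as `f` or `1/f`
#'   according to the prescribed direction; identity is always included.
#' @param n_patterns,n_profiles,n_sets,seed Assay settings.
#' @return List of class `treatment_result`: `individuals` (per-individual
#'   untreated/treated errors, label, chosen factor), `uniform` (shared
#'   factor and resulting per-individual errors), and the mean max errors
#'   under no, personalized, and uniform treatment.
#' @export
treat_cohort <- function(cohort, table, limits,
                         target_property = "inhibition",
                         factors = 2^seq(0.5, 3.5, by = 0.5),
                         n_patterns = 30, n_profiles = 3, n_sets = 10,
                         seed = 1) {
  target_property <- match.arg(target_property, .properties)
  stopifnot(all(factors > 1))
  eval_row <- function(row, value) {
    cfg <- config_from_row(row)
    if (!is.null(value)) {
      cfg <- apply_pathology(cfg, .single_spec(target_property, value,
                                               connectivity_as_delta = FALSE))
    }
    evaluate_config(cfg, table, n_patterns, n_profiles = n_profiles,
                    n_sets = n_sets, seed = seed)
  }
  n <- nrow(cohort)
  untreated <- lapply(seq_len(n), function(i) eval_row(cohort[i, ], NULL))
  labels <- vapply(untreated, function(ev) classify_bias(ev, limits)$label,
                   character(1))

  candidates_for <- function(direction) {
    if (direction == "increase") factors else 1 / factors
  }
  # personalized: per-individual direction and factor (identity included)
  personalized <- lapply(seq_len(n), function(i) {
    if (labels[i] == "balanced") {
      return(list(factor = 1, ev = untreated[[i]]))
    }
    dirs <- prescribe(labels[i])
    cand <- c(1, candidates_for(dirs[[target_property]]))
    evs <- lapply(cand, function(f) {
      if (f == 1) untreated[[i]] else eval_row(cohort[i, ], f)
    })
    best <- which.min(vapply(evs, `[[`, numeric(1), "max_err"))
    list(factor = cand[best], ev = evs[[best]])
  })
  # uniform: one shared factor in the population-prescribed direction
  pop_ev <- list(sep_err = mean(vapply(untreated, `[[`, numeric(1), "sep_err")),
                 comp_err = mean(vapply(untreated, `[[`, numeric(1), "comp_err")))
  pop_label <- classify_bias(pop_ev, limits)$label
  pop_dir <- if (pop_label == "balanced") "increase"
  else prescribe(pop_label)[[target_property]]
  u_cand <- c(1, candidates_for(pop_dir))
  u_results <- lapply(u_cand, function(f) {
    lapply(seq_len(n), function(i) {
      if (f == 1) untreated[[i]] else eval_row(cohort[i, ], f)
    })
  })
  u_means <- vapply(u_results, function(res) {
    mean(vapply(res, `[[`, numeric(1), "max_err"))
  }, numeric(1))
  u_best <- which.min(u_means)

  g <- function(lst, field) vapply(lst, function(z) z$ev[[field]], numeric(1))
  ind <- data.frame(
    individual = cohort$individual,
    label = labels,
    untreated_sep = vapply(untreated, `[[`, numeric(1), "sep_err"),
    untreated_comp = vapply(untreated, `[[`, numeric(1), "comp_err"),
    untreated_max = vapply(untreated, `[[`, numeric(1), "max_err"),
    treatment_factor = vapply(personalized, `[[`, numeric(1), "factor"),
    treated_sep = g(personalized, "sep_err"),
    treated_comp = g(personalized, "comp_err"),
    treated_max = g(personalized, "max_err"),
    uniform_max = vapply(u_results[[u_best]], `[[`, numeric(1), "max_err"))
  structure(list(
    individuals = ind,
    uniform = list(factor = u_cand[u_best], direction = pop_dir,
                   mean_max_err = u_means[u_best]),
    population_label = pop_label,
    mean_untreated_max = mean(ind$untreated_max),
    mean_personalized_max = mean(ind$treated_max),
    mean_uniform_max = u_means[u_best]),
    class = "treatment_result")
}

#' @export
print.treatment_result <- function(x, ...) {
  cat(sprintf(paste0("treatment_result: %d individuals (population %s)\n",
                     "  mean max error: untreated %.3f | uniform %.3f",
                     " (factor %.2f) | personalized %.3f\n"),
              nrow(x$individuals), x$population_label, x$mean_untreated_max,
              x$mean_uniform_max, x$uniform$factor,
              x$mean_personalized_max))
  invisible(x)
}
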