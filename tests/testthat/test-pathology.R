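# Pathology perturbations, bias classification, prescriptions, cohort
# generation and treatment plumbing (the headline directional results live
# in test-acceptance.R).

test_that("apply_pathology scales properties and recomputes gGABA", {
  cfg <- network_config(connectivity_level = 0.5, g_max_ampa = 10,
                        gamma_ltd = 0.5, relative_inhibition = 2)
  same <- apply_pathology(cfg, pathology_spec())
  expect_equal(same[c("connectivity_level", "g_max_ampa", "gamma_ltd",
                      "relative_inhibition")],
               cfg[c("connectivity_level", "g_max_ampa", "gamma_ltd",
                     "relative_inhibition")])
  pert <- apply_pathology(cfg, pathology_spec(ltd_factor = 2))
  expect_equal(pert$gamma_ltd, 1.0)
  half_inh <- apply_pathology(cfg, pathology_spec(inhibition_factor = 0.5))
  expect_equal(feedback_inhibition_strength(half_inh),
               feedback_inhibition_strength(cfg) / 2)
  up <- apply_pathology(cfg, pathology_spec(connectivity_delta = 0.7))
  expect_equal(up$connectivity_level, 1) # clipped at 100%
  expect_error(apply_pathology(cfg, pathology_spec(connectivity_delta = -0.6)),
               "non-positive")
})

test_that("bias classification follows the limit-exceedance definition", {
  lim <- list(sep_limit = 0.3, comp_limit = 0.2)
  expect_equal(classify_bias(list(sep_err = 0.1, comp_err = 0.1), lim)$label,
               "balanced")
  expect_equal(classify_bias(list(sep_err = 0.0, comp_err = 0.9), lim)$label,
               "separation_bias")
  expect_equal(classify_bias(list(sep_err = 0.9, comp_err = 0.0), lim)$label,
               "completion_bias")
  # both exceed: the larger relative exceedance wins
  expect_equal(classify_bias(list(sep_err = 0.35, comp_err = 0.9), lim)$label,
               "separation_bias")
  expect_equal(classify_bias(list(sep_err = 0.9, comp_err = 0.21), lim)$label,
               "completion_bias")
})

test_that("tolerable limits come from the ensemble and ignore duplicated rows", {
  base <- data.frame(sep_err = c(0.2, 0.4), comp_err = c(0.1, 0.3))
  lim <- tolerable_limits(base)
  expect_equal(lim$sep_limit, 0.3)
  expect_equal(lim$comp_limit, 0.2)
  lim_sd <- tolerable_limits(base, type = "mean_sd")
  expect_gt(lim_sd$sep_limit, lim$sep_limit)
  # classification is invariant to adding identical-error networks
  res <- list(sep_err = 0.5, comp_err = 0.05)
  expect_equal(classify_bias(res, tolerable_limits(base))$label,
               classify_bias(res, tolerable_limits(rbind(base, base)))$label)
})

test_that("prescriptions are opposite for opposite biases and empty when balanced", {
  sep_rx <- prescribe("separation_bias")
  comp_rx <- prescribe("completion_bias")
  expect_equal(sep_rx[["inhibition"]], "decrease")
  expect_equal(comp_rx[["inhibition"]], "increase")
  expect_equal(sep_rx[["ltp"]], "increase")
  expect_equal(sep_rx[["connectivity"]], "increase")
  flip <- c(increase = "decrease", decrease = "increase")
  expect_equal(unname(flip[sep_rx]), unname(comp_rx))
  expect_length(prescribe("balanced"), 0)
})

test_that("identity perturbation grids reproduce the baseline", {
  opt <- fx_optimal()[1:3, ]
  tab <- fx_table()
  base <- evaluate_ensemble(opt, tab, n_patterns = 30, seed = 1)
  curve <- single_pathology_curves(opt, tab, "ltd", values = 1,
                                   n_patterns = 30, seed = 1)
  expect_equal(curve$sep_err, mean(base$sep_err))
  expect_equal(curve$comp_err, mean(base$comp_err))
  surf <- interaction_surface(opt, tab, c("ltp", "inhibition"),
                              values1 = 1, values2 = 1, n_patterns = 30,
                              seed = 1)
  expect_equal(surf$max_err, mean(base$max_err))
  expect_error(interaction_surface(opt, tab, c("ltp", "ltp")), "distinct")
})

test_that("unit-range cohort is the optimal set; default cohort is reproducible", {
  opt <- fx_optimal()
  unit <- generate_cohort(opt, ranges = list(ltp = c(1, 1), ltd = c(1, 1),
                                             inhibition = c(1, 1),
                                             connectivity = c(1, 1)),
                          seed = 3)
  expect_equal(unit$g_max_ampa, opt$g_max_ampa)
  expect_equal(unit$connectivity, opt$connectivity)
  c1 <- generate_cohort(opt, seed = 11)
  expect_identical(c1, generate_cohort(opt, seed = 11))
  expect_false(identical(c1$g_max_ampa, generate_cohort(opt, seed = 12)$g_max_ampa))
  # factors are decreases within the stated ranges
  expect_true(all(c1$ltd_factor >= 0.4 & c1$ltd_factor <= 1))
  expect_true(all(c1$ltp_factor >= 0.85 & c1$ltp_factor <= 1))
})

test_that("balanced individuals are left untreated", {
  coh <- generate_cohort(fx_optimal()[1:2, ], seed = 4)
  generous <- list(sep_limit = 1, comp_limit = 1) # nothing exceeds
  tr <- treat_cohort(coh, fx_table(), generous, factors = c(2, 4),
                     n_profiles = 2, n_sets = 2, seed = 1)
  expect_true(all(tr$individuals$label == "balanced"))
  expect_true(all(tr$individuals$treatment_factor == 1))
  expect_equal(tr$individuals$treated_max, tr$individuals$untreated_max)
})
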