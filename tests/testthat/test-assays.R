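# Separation/completion assays: degenerate cases, aggregation, and
# agreement between the threshold-table fast path and explicit simulation.

zero_weight_net <- function() {
  cfg <- network_config(connectivity_level = 0.5, g_max_ampa = 10,
                        gamma_ltd = 1, relative_inhibition = 1)
  pats <- generate_pattern_set(3, cfg, seed = 2)
  net <- build_network(cfg, pats)
  net$weights[] <- 0
  net
}

test_that("all-silent weights give zero separation error and total completion failure", {
  net <- zero_weight_net()
  tab <- fx_table()
  expect_false(any(assay_separation(net, method = "fast", table = tab)))
  expect_equal(assay_completion(net, method = "fast", table = tab),
               rep(1, 3))
  # the explicit route agrees on both counts
  expect_false(any(assay_separation(net, method = "explicit")))
  expect_equal(assay_completion(net, method = "explicit",
                                holdouts = "single"), rep(1, 3))
  res <- fast_assay(net, table = tab)
  expect_equal(res$separation_error_rate, 0)
  expect_equal(res$completion_error_rate, 1)
  expect_equal(res$max_error, 1)
  expect_error(assay_separation(net, window = 0, method = "fast",
                                table = tab), "window")
})

test_that("one stored pattern at full connectivity, max LTP, no inhibition completes perfectly", {
  cfg <- network_config(connectivity_level = 1, g_max_ampa = 55.56,
                        gamma_ltd = 1, relative_inhibition = 0)
  pats <- generate_pattern_set(1, cfg, seed = 3)
  net <- build_network(cfg, pats)
  tab <- fx_table()
  expect_equal(assay_completion(net, method = "fast", table = tab), 0)
  expect_equal(assay_completion(net, method = "explicit"), 0)
})

test_that("fast assays are deterministic and max_error is order-invariant", {
  net <- fx_small_net()
  tab <- fx_table()
  r1 <- fast_assay(net, table = tab)
  r2 <- fast_assay(net, table = tab)
  expect_identical(r1, r2)
  expect_equal(r1$max_error,
               max(r1$completion_error_rate, r1$separation_error_rate))
})

test_that("fast path and explicit simulation agree on per-neuron decisions", {
  # compared over the optimal-ensemble operating regime (the fast path by
  # design ignores higher-order recruitment, which dominates only in the
  # near-zero-inhibition corner of the grid)
  tab <- fx_table()
  combos <- select_optimal(fx_sweep(), 0.5, 30, top_k = 20)
  agree <- 0
  total <- 0
  for (i in seq_len(nrow(combos))) {
    cfg <- network_config(connectivity_level = combos$connectivity[i],
                          g_max_ampa = combos$g_max_ampa[i],
                          gamma_ltd = combos$gamma_ltd[i],
                          relative_inhibition = combos$relative_inhibition[i])
    pats <- generate_pattern_set(15, cfg, seed = 100 + i)
    net <- build_network(cfg, pats, conn_seed = 200 + i)
    pat <- pats[[1]]
    # separation trial: compare fired/not for each non-member neuron
    pred <- fast_predictions(net, pat, tab)
    sp <- simulate_network_cycle(net, pat)
    fired <- tabulate(sp$neuron, nbins = 101) > 0
    nonmem <- setdiff(1:100, pat)
    agree <- agree + sum(pred$exc[nonmem] == fired[nonmem]) +
      (pred$interneuron == fired[101])
    total <- total + length(nonmem) + 1
    # completion trials: holdout neuron decision
    for (k in pat[1:3]) {
      predc <- fast_predictions(net, pat, tab, holdout = k)
      spc <- simulate_network_cycle(net, setdiff(pat, k))
      agree <- agree + (predc$exc[k] == (k %in% spc$neuron))
      total <- total + 1
    }
  }
  expect_gte(total, 900)
  expect_gte(agree / total, 0.95)
})

test_that("aggregation reproduces closed-form means/SEMs and a brute-force oracle", {
  runs <- expand.grid(profile = 1:3, set = 1:4)
  runs$sep_err <- 0.25
  runs$comp_err <- 0.5
  agg <- aggregate_errors(runs)
  expect_equal(agg$sep_err, 0.25)
  expect_equal(agg$sep_sem, 0)
  expect_equal(agg$max_err, 0.5)
  # profile means {0, 0.5, 1}: mean 0.5, SEM = sd/sqrt(3)
  runs$sep_err <- (runs$profile - 1) / 2
  agg <- aggregate_errors(runs)
  expect_equal(agg$sep_err, 0.5)
  expect_equal(agg$sep_sem, sd(c(0, 0.5, 1)) / sqrt(3))
  # randomized oracle
  set.seed(5)
  runs$sep_err <- runif(nrow(runs))
  runs$comp_err <- runif(nrow(runs))
  agg <- aggregate_errors(runs)
  pm_sep <- vapply(1:3, function(p) mean(runs$sep_err[runs$profile == p]),
                   numeric(1))
  pm_comp <- vapply(1:3, function(p) mean(runs$comp_err[runs$profile == p]),
                    numeric(1))
  expect_equal(agg$sep_err, mean(pm_sep))
  expect_equal(agg$comp_err, mean(pm_comp))
  expect_equal(agg$max_err, max(mean(pm_sep), mean(pm_comp)))
  expect_equal(agg$comp_sem, sd(pm_comp) / sqrt(3))
  # missing runs are reported by (profile, set)
  expect_error(aggregate_errors(runs[-1, ]), "\\(1, 1\\)")
})

test_that("evaluate_config is deterministic and bounded", {
  cfg <- network_config(connectivity_level = 0.5, g_max_ampa = 5,
                        gamma_ltd = 2, relative_inhibition = 0.1)
  tab <- fx_table()
  e1 <- evaluate_config(cfg, tab, 10, n_profiles = 2, n_sets = 3, seed = 9)
  e2 <- evaluate_config(cfg, tab, 10, n_profiles = 2, n_sets = 3, seed = 9)
  expect_identical(e1, e2)
  expect_true(e1$sep_err >= 0 && e1$sep_err <= 1)
  expect_true(e1$comp_err >= 0 && e1$comp_err <= 1)
})
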