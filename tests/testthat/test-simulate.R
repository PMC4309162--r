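test_that("identical seeds give bit-identical simulations", {
  cfg <- simulation_config(n_genes = 200, seed = 13)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$expression$signal, b$expression$signal)
  expect_identical(a$expression$call, b$expression$call)
  expect_identical(a$truth, b$truth)
  expect_identical(a$n_fc, b$n_fc)
  c2 <- simulate_experiment(simulation_config(n_genes = 200, seed = 14))
  expect_false(identical(a$expression$signal, c2$expression$signal))
})

test_that("configuration validation rejects infeasible settings", {
  expect_error(simulation_config(n_genes = 10), "seed")
  expect_error(simulation_config(seed = 1, noise_sd = -1), "noise_sd")
  expect_error(simulation_config(seed = 1,
                                 class_fractions = c(UP.DDD = 1.5)),
               "more than 1")
  expect_error(simulation_config(seed = 1,
                                 class_fractions = c(UP.UDU = 0.1)),
               "infeasible pattern")
  expect_error(simulation_config(seed = 1, call_flip_rate = 2), "flip")
  expect_error(metabolite_config(seed = 1, cv = 0), "cv")
})

test_that("the realised absent-call fraction sits in the configured band", {
  sim <- simulate_experiment(simulation_config(n_genes = 10000, seed = 8))
  frac <- mean(sim$expression$call == "A")
  expect_gte(frac, 0.25)
  expect_lte(frac, 0.36)
  # per experiment too
  for (e in experiments()) {
    cols <- sim$design$sample_id[sim$design$experiment == e]
    fe <- mean(sim$expression$call[, cols] == "A")
    expect_gte(fe, 0.25)
    expect_lte(fe, 0.36)
  }
})

test_that("a noiseless run is recovered perfectly end-to-end", {
  cfg <- simulation_config(n_genes = 1500, seed = 2, noise_sd = 0,
                           call_flip_rate = 0)
  sim <- simulate_experiment(cfg)
  res <- sulfate_screen(sim$expression, sim$design,
                        n_fc = sim$n_fc, p_fc = sim$p_fc)
  rec <- evaluate_recovery(res, sim$truth)
  expect_true(all(rec$per_category$responder_rate == 1))
  expect_true(all(rec$per_category$class_rate == 1))
  expect_true(all(rec$per_category$specificity_rate == 1))
  expect_identical(unname(rec$false_positive_rate), 0)
})

test_that("shuffled class labels drop recovery to about chance", {
  cfg <- simulation_config(n_genes = 1500, seed = 2, noise_sd = 0,
                           call_flip_rate = 0)
  sim <- simulate_experiment(cfg)
  res <- sulfate_screen(sim$expression, sim$design)
  set.seed(99)
  for (d in c("UP", "DOWN")) {
    labs <- res$classes[[d]]$class_label
    res$classes[[d]]$class_label <- sample(labs)
  }
  rec <- evaluate_recovery(res, sim$truth)
  # 6-way labels on a balanced planted design: chance is ~1/6
  expect_lt(unname(rec$overall["class"]), 0.25)
})

test_that("truth without planted responders reports false positives only", {
  cfg <- simulation_config(n_genes = 300, seed = 6,
                           class_fractions = c(UP.DDD = 0))
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$truth$category == "NULL"))
  res <- sulfate_screen(sim$expression, sim$design)
  rec <- evaluate_recovery(res, sim$truth)
  expect_identical(nrow(rec$per_category), 0L)
  expect_false(is.na(rec$false_positive_rate))
  # mismatched gene universes are an error
  expect_error(evaluate_recovery(res, sim$truth[-1, ]), "do not match")
})

test_that("recovery degrades monotonically with noise on average", {
  rates <- sapply(c(0, 0.5, 1.2), function(ns) {
    mean(sapply(1:3, function(s) {
      cfg <- simulation_config(n_genes = 400, seed = 100 + s, noise_sd = ns,
                               call_flip_rate = if (ns == 0) 0 else 0.01)
      sim <- simulate_experiment(cfg)
      res <- sulfate_screen(sim$expression, sim$design)
      rec <- evaluate_recovery(res, sim$truth)
      unname(rec$overall["class"])
    }))
  })
  expect_true(all(diff(rates) <= 0))
  expect_equal(rates[1], 1)
})

test_that("metabolite simulation is seeded, powered and calibrated", {
  mc <- metabolite_config(seed = 5)
  g1 <- generate_metabolites(mc)
  g2 <- generate_metabolites(mc)
  expect_identical(g1$table, g2$table)
  # power: a planted 2-fold effect at CV 0.05, n = 3 is nearly always caught
  hits <- sapply(1:200, function(s) {
    g <- generate_metabolites(metabolite_config(
      effects = c(M = 1), cv = 0.05, seed = s
    ))
    tt <- g$table
    a <- tt$value[tt$condition == "S_MINUS" & tt$experiment == "EXP1"]
    b <- tt$value[tt$condition == "FN" & tt$experiment == "EXP1"]
    welch_t_test(a, b)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
  # null effects: type-I error near alpha
  set.seed(77)
  nullp <- replicate(2000, {
    welch_t_test(stats::rnorm(3), stats::rnorm(3))$p_value
  })
  expect_gt(mean(nullp < 0.05), 0.02)
  expect_lt(mean(nullp < 0.05), 0.08)
})
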