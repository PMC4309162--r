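test_that("sign patterns follow the strict >1 rule with configurable dead zone", {
  expect_identical(sign_pattern(0.5, 0.25, 0.5), "DDD")
  expect_identical(sign_pattern(2, 1.5, 0.75), "UUD")
  expect_identical(sign_pattern(1, 1, 1), "DDD")     # ratio exactly 1 -> D
  expect_identical(sign_pattern(1.05, 1.05 * 1.05, 1.05, epsilon = 0.2),
                   "DDD")                             # inside the dead zone
  expect_true(is.na(sign_pattern(NA, 2, 2)))
  expect_error(sign_pattern(-1, 2, 2), "ratios must be > 0")
  expect_warning(sign_pattern(2, 0.5, 2), "violate")  # not from shared means
})

test_that("exactly six sign patterns are algebraically feasible", {
  grid <- expand.grid(a = c(0.25, 0.5, 2, 4), d = c(0.25, 0.5, 2, 4))
  pats <- suppressWarnings(
    sign_pattern(grid$a, grid$a * grid$d, grid$d)
  )
  expect_setequal(unique(pats), feasible_patterns())
  expect_length(feasible_patterns(), 6L)
  expect_false(any(c("UDU", "DUD") %in% feasible_patterns()))
})

test_that("patterns derived from condition means are always feasible", {
  sim <- simulate_experiment(simulation_config(n_genes = 300, seed = 3,
                                               noise_sd = 0.5))
  fc <- fold_change_table(sim$expression, sim$design)
  for (e in c("EXP1", "EXP2")) {
    g <- function(ct) {
      sl <- fc[fc$experiment == e & fc$contrast == ct, ]
      sl$ratio[order(sl$gene_id)]
    }
    pats <- sign_pattern(g("R30_vs_S"), g("R3H_vs_S"), g("R3H_vs_R30"))
    expect_true(all(pats[!is.na(pats)] %in% feasible_patterns()))
  }
})

test_that("the default class map anchors class I and is total and injective", {
  up <- default_class_map("UP")
  dn <- default_class_map("DOWN")
  expect_identical(unname(up["DDD"]), "I")
  expect_identical(unname(dn["UUU"]), "I")
  for (m in list(up, dn)) {
    expect_setequal(names(m), feasible_patterns())
    expect_false(anyDuplicated(m) > 0)
  }
})

test_that("class assignment requires cross-experiment agreement", {
  a <- assign_class("g1", "DDD", "DDD", "UP")
  expect_identical(a$class_label, "I")
  b <- assign_class("g1", "DDD", "UUU", "UP")
  expect_identical(b$class_label, "OTHERS")
  expect_identical(b$reason, "inconsistent between experiments")
  c1 <- assign_class("g1", NA, "DDD", "UP")
  expect_identical(c1$class_label, "OTHERS")
  expect_identical(c1$reason, "missing contrast")
})

test_that("all 36 pattern pairs yield 6 consistent labels and 30 OTHERS", {
  pairs <- expand.grid(p1 = feasible_patterns(), p2 = feasible_patterns(),
                       stringsAsFactors = FALSE)
  res <- assign_class(sprintf("g%02d", seq_len(nrow(pairs))),
                      pairs$p1, pairs$p2, "UP")
  expect_identical(sum(res$class_label != "OTHERS"), 6L)
  expect_identical(sum(res$class_label == "OTHERS"), 30L)
  expect_setequal(res$class_label[res$class_label != "OTHERS"],
                  c("I", "II", "III", "IV", "V", "VI"))
})

test_that("class I equals the all-ratios-below-one oracle on synthetic data", {
  sim <- simulate_experiment(simulation_config(n_genes = 600, seed = 17,
                                               noise_sd = 0.3))
  fc <- fold_change_table(sim$expression, sim$design)
  up <- screen_responders(fc, "UP", 5)
  cls <- classify_responders(fc, up)
  # oracle: class I (UP) iff all six resupply ratios across both
  # experiments are < 1
  for (i in seq_len(nrow(cls))) {
    g <- cls$gene_id[i]
    ratios <- fc$ratio[fc$gene_id == g &
                         fc$contrast %in% c("R30_vs_S", "R3H_vs_S",
                                            "R3H_vs_R30")]
    oracle_is_I <- all(!is.na(ratios)) && all(ratios < 1)
    expect_identical(cls$class_label[i] == "I", oracle_is_I)
  }
  # partition: every intersected responder receives exactly one label
  expect_setequal(cls$gene_id, up$intersection)
  expect_false(anyDuplicated(cls$gene_id) > 0)
})

test_that("classification is deterministic and honours a map override", {
  fcr <- rbind(
    fc_from_ratios("g1", data.frame(
      experiment = rep(c("EXP1", "EXP2"), each = 3),
      contrast = rep(c("R30_vs_S", "R3H_vs_S", "R3H_vs_R30"), 2),
      ratio = rep(c(0.5, 0.25, 0.5), 2)
    ))
  )
  a <- classify_responders(fcr, "g1", direction = "UP")
  b <- classify_responders(fcr, "g1", direction = "UP")
  expect_identical(a, b)
  expect_identical(a$class_label, "I")
  override <- c(DDD = "FAST", DDU = "II", UDD = "III", UUD = "IV",
                DUU = "V", UUU = "VI")
  o <- classify_responders(fcr, "g1", direction = "UP", class_map = override)
  expect_identical(o$class_label, "FAST")
  # empty responder set: empty frame, not an error
  e <- classify_responders(fcr, character(), direction = "UP")
  expect_identical(nrow(e), 0L)
})
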