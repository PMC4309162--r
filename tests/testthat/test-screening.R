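test_that("condition means are geometric with any-P/M detection", {
  sig <- matrix(c(100, 400, 7, NA, 30, 60), 3, 2, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  cl <- matrix(c("P", "P", "M", "A", "A", "A"), 3, 2, byrow = TRUE,
               dimnames = dimnames(sig))
  em <- expression_matrix(sig, cl)
  d <- suppressWarnings(sample_design(data.frame(
    sample_id = c("s1", "s2"), experiment = "EXP1",
    condition = "S_MINUS", replicate = 1:2
  )))
  cm <- condition_mean(em, d, "EXP1", "S_MINUS")
  expect_equal(cm$mean_signal[1], 200)            # geometric mean of 100, 400
  expect_equal(cm$mean_signal[2], 7)              # single non-NA value
  expect_true(cm$detected[2])                     # M counts as detected
  expect_false(cm$detected[3])                    # A and A
  # arithmetic option
  cma <- condition_mean(em, d, "EXP1", "S_MINUS", aggregate = "arithmetic")
  expect_equal(cma$mean_signal[1], 250)
  expect_error(condition_mean(em, d, "EXP1", "FN"), "no samples match")
})

test_that("fold changes are ratios of condition means with NA denominators flagged", {
  sig <- matrix(c(100, 800, 50, 50, 0, 10), 3, 2, byrow = TRUE,
                dimnames = list(paste0("g", 1:3), c("fn", "s")))
  cl <- matrix("P", 3, 2, dimnames = dimnames(sig))
  em <- expression_matrix(sig, cl)
  d <- suppressWarnings(sample_design(data.frame(
    sample_id = c("fn", "s"), experiment = "EXP1",
    condition = c("FN", "S_MINUS"), replicate = 1L
  )))
  expect_message(fc <- fold_change(em, d, "EXP1", "S_vs_FN"),
                 "zero/NA denominator")
  expect_equal(fc$ratio[1], 8)
  expect_equal(fc$ratio[2], 1)
  expect_true(is.na(fc$ratio[3]))
  expect_error(fold_change(em, d, "EXP1", "bogus"), "unknown contrast")
})

test_that("responder screens apply strict thresholds and call filters", {
  fc <- data.frame(
    gene_id = paste0("g", 1:4), experiment = "EXP1", contrast = "S_vs_FN",
    ratio = c(6, 6, 5, NA), log2_ratio = log2(c(6, 6, 5, NA)),
    detected_num = c(TRUE, FALSE, TRUE, TRUE),
    detected_den = TRUE, stringsAsFactors = FALSE
  )
  expect_identical(responder_screen(fc, "UP", 5), "g1")   # g2 absent, g3 at boundary
  expect_identical(responder_screen(fc, "UP", 5, call_filter = FALSE),
                   c("g1", "g2"))
  expect_error(responder_screen(fc, "UP", 0.5), "threshold > 1")
  expect_error(responder_screen(fc, "DOWN", 2), "threshold < 1")

  dn <- fc
  dn$ratio <- c(0.1, 0.1, 0.2, 0.6)
  dn$detected_den <- c(TRUE, FALSE, TRUE, TRUE)
  expect_identical(responder_screen(dn, "DOWN", 0.2), "g1")
})

test_that("replicate intersection reports Venn counts", {
  rs <- intersect_replicates(list(EXP1 = c("a", "b", "c"),
                                  EXP2 = c("b", "c", "d")), "UP", 5)
  expect_setequal(rs$intersection, c("b", "c"))
  expect_identical(unname(rs$counts), c(3L, 3L, 2L))
  rs2 <- intersect_replicates(list(EXP1 = "a", EXP2 = "b"))
  expect_length(rs2$intersection, 0L)
  expect_error(intersect_replicates(list(EXP1 = "a")), "at least two")
})

test_that("vectorised screen agrees with the per-gene brute-force oracle", {
  sim <- simulate_experiment(simulation_config(
    n_genes = 50, seed = 11, noise_sd = 0.4, call_flip_rate = 0.05
  ))
  fc <- fold_change_table(sim$expression, sim$design)
  for (e in c("EXP1", "EXP2")) {
    sl <- fc[fc$contrast == "S_vs_FN" & fc$experiment == e, ]
    for (cf in c(TRUE, FALSE)) {
      expect_setequal(
        responder_screen(sl, "UP", 2, call_filter = cf),
        oracle_screen(sim$expression, sim$design, e, "UP", 2, cf)
      )
      expect_setequal(
        responder_screen(sl, "DOWN", 0.5, call_filter = cf),
        oracle_screen(sim$expression, sim$design, e, "DOWN", 0.5, cf)
      )
    }
  }
})

test_that("resupply ratios are multiplicative and screens are monotone", {
  sim <- simulate_experiment(simulation_config(n_genes = 400, seed = 5,
                                               noise_sd = 0.3))
  fc <- fold_change_table(sim$expression, sim$design)
  for (e in c("EXP1", "EXP2")) {
    g <- function(ct) {
      sl <- fc[fc$experiment == e & fc$contrast == ct, ]
      sl$ratio[order(sl$gene_id)]
    }
    r30 <- g("R30_vs_S"); r3h <- g("R3H_vs_S"); rr <- g("R3H_vs_R30")
    ok <- !is.na(r30) & !is.na(r3h) & !is.na(rr)
    expect_true(all(abs(r3h[ok] - r30[ok] * rr[ok]) <=
                      1e-9 * pmax(r3h[ok], r30[ok] * rr[ok])))
  }
  up5 <- screen_responders(fc, "UP", 5)
  up2 <- screen_responders(fc, "UP", 2)
  dn02 <- screen_responders(fc, "DOWN", 0.2)
  dn05 <- screen_responders(fc, "DOWN", 0.5)
  expect_true(all(up5$intersection %in% up2$intersection))
  expect_true(all(dn02$intersection %in% dn05$intersection))
  for (e in c("EXP1", "EXP2")) {
    expect_true(all(up5$per_experiment[[e]] %in% up2$per_experiment[[e]]))
    expect_true(all(dn02$per_experiment[[e]] %in% dn05$per_experiment[[e]]))
  }
  # removing the call filter never shrinks a set
  up2_nf <- screen_responders(fc, "UP", 2, call_filter = FALSE)
  dn05_nf <- screen_responders(fc, "DOWN", 0.5, call_filter = FALSE)
  expect_true(all(up2$intersection %in% up2_nf$intersection))
  expect_true(all(dn05$intersection %in% dn05_nf$intersection))
})
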