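make_panel_fc <- function(genes, ratio_matrix, detected = TRUE) {
  # ratio_matrix: genes x 6 (EXP1 then EXP2, contrasts S_vs_FN, R30_vs_S,
  # R3H_vs_S)
  panel <- default_contrast_panel()
  do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    data.frame(
      gene_id = genes, experiment = panel$experiment[i],
      contrast = panel$contrast[i], ratio = ratio_matrix[, i],
      log2_ratio = log2(ratio_matrix[, i]),
      detected_num = detected, detected_den = detected,
      stringsAsFactors = FALSE
    )
  }))
}

test_that("profiles are log2 ratios in panel order, with absent handling", {
  rm <- matrix(c(8, 0.5, 0.25, 4, 0.5, 0.5), 1)
  fc <- make_panel_fc("g1", rm)
  prof <- build_profile("g1", fc)
  expect_equal(unname(prof), c(3, -1, -2, 2, -1, -1))
  expect_identical(names(prof)[1], "EXP1.S_vs_FN")
  # NA ratio at one position leaves the others intact
  fc2 <- fc
  fc2$ratio[fc2$experiment == "EXP1" & fc2$contrast == "R30_vs_S"] <- NA
  prof2 <- build_profile("g1", fc2)
  expect_true(is.na(prof2[2]) && !anyNA(prof2[-2]))
  # include_absent = FALSE masks undetected positions
  fc3 <- fc
  fc3$detected_num[fc3$experiment == "EXP1"] <- FALSE
  prof3 <- build_profile("g1", fc3, include_absent = FALSE)
  expect_true(all(is.na(prof3[1:3])) && !anyNA(prof3[4:6]))
  expect_error(build_profile("nope", fc), "not present")
})

test_that("cobehaviour scores are Pearson over paired finite points", {
  expect_equal(cobehavior_score(1:6, c(2, 4, 6, 8, 10, 12))$r, 1)
  expect_equal(cobehavior_score(1:6, -(1:6))$r, -1)
  sc <- cobehavior_score(1:6, c(2, 1, 4, 3, 6, 5))
  expect_equal(sc$r, 0.8285714, tolerance = 1e-6)   # frozen from the
  expect_identical(sc$n_points, 6L)                 # definitional oracle
  expect_equal(sc$r, oracle_pearson(1:6, c(2, 1, 4, 3, 6, 5)),
               tolerance = 1e-12)
  # too few paired points / zero variance are flagged, not errors
  ins <- cobehavior_score(c(1, 2, NA, NA, NA, NA), c(1, 2, 3, NA, NA, NA))
  expect_identical(ins$flag, "insufficient_data")
  expect_true(is.na(ins$r))
  zv <- cobehavior_score(rep(1, 6), 1:6)
  expect_identical(zv$flag, "zero_variance")
  # scale invariance and symmetry
  x <- c(0.3, -1, 2, 0.5, -0.2, 1.4)
  y <- c(1, 0.5, 2.5, 1.2, 0.1, 2)
  expect_equal(cobehavior_score(x, y)$r,
               cobehavior_score(3 * x + 7, 0.2 * y - 1)$r)
  expect_equal(cobehavior_score(x, y)$r, cobehavior_score(y, x)$r)
})

test_that("TF ranking equals brute-force recomputation with stable ties", {
  set.seed(9)
  genes <- c(paste0("tf", 1:3), paste0("tg", 1:4))
  profs <- matrix(stats::rnorm(7 * 6), 7, 6, dimnames = list(genes, NULL))
  rk <- rank_tf_targets(paste0("tf", 1:3), paste0("tg", 1:4), profs)
  brute <- sapply(paste0("tf", 1:3), function(tf)
    mean(sapply(paste0("tg", 1:4), function(tg)
      oracle_pearson(profs[tf, ], profs[tg, ]))))
  expect_equal(stats::setNames(rk$ranking$mean_r, rk$ranking$tf),
               brute[order(-brute)], tolerance = 1e-12)
  expect_false(is.unsorted(rev(rk$ranking$mean_r)))
  # a TF identical to every target ranks first with mean r = 1
  profs2 <- profs
  for (tg in paste0("tg", 1:4)) profs2[tg, ] <- profs2["tf2", ]
  rk2 <- rank_tf_targets(paste0("tf", 1:3), paste0("tg", 1:4), profs2)
  expect_identical(rk2$ranking$tf[1], "tf2")
  expect_equal(rk2$ranking$mean_r[1], 1)
  # a TF with only unscorable pairs is excluded with a reason
  profs3 <- profs
  profs3["tf1", ] <- c(1, 2, NA, NA, NA, NA)
  rk3 <- rank_tf_targets(paste0("tf", 1:3), paste0("tg", 1:4), profs3)
  expect_true(rk3$ranking$excluded[rk3$ranking$tf == "tf1"])
  expect_error(rank_tf_targets(character(), "tg1", profs), "non-empty")
})

test_that("a TF tracks the target set sharing its planted kinetics", {
  # two target sets with different planted kinetics; the TF shares set A's
  base <- c(3, -0.7, -1.7, 3, -0.7, -1.7)   # strong induction, relaxing
  alt <- c(-2, 0.6, 1.3, -2, 0.6, 1.3)      # repression, recovering
  set.seed(21)
  noise <- function() stats::rnorm(6, 0, 0.1)
  profs <- rbind(
    TF = base + noise(),
    A1 = base + noise(), A2 = base + noise(),
    B1 = alt + noise(), B2 = alt + noise()
  )
  scoreA <- mean(c(cobehavior_score(profs["TF", ], profs["A1", ])$r,
                   cobehavior_score(profs["TF", ], profs["A2", ])$r))
  scoreB <- mean(c(cobehavior_score(profs["TF", ], profs["B1", ])$r,
                   cobehavior_score(profs["TF", ], profs["B2", ])$r))
  expect_gt(scoreA, scoreB)
})
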