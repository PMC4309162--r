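# independent reference implementations and small fixture builders,
# deliberately written straight from textbook definitions so they stay
# independent of the package code paths they check

# textbook Welch test: statistic, Welch-Satterthwaite df, two-sided p
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# definitional Pearson correlation
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# per-gene brute-force responder screen (loops, no vectorised shortcuts)
oracle_screen <- function(expr, design, experiment, direction, threshold,
                          call_filter = TRUE) {
  ct <- contrasts_table()
  hits <- character()
  for (g in rownames(expr$signal)) {
    gm <- function(cond) {
      sids <- design$sample_id[design$experiment == experiment &
                                 design$condition == cond]
      v <- expr$signal[g, sids]
      v <- v[!is.na(v)]
      if (!length(v)) return(list(m = NA_real_, det = FALSE))
      cl <- expr$call[g, sids][!is.na(expr$signal[g, sids])]
      list(m = exp(mean(log(v))), det = any(cl %in% c("P", "M")))
    }
    s <- gm("S_MINUS"); fn <- gm("FN")
    if (is.na(fn$m) || fn$m == 0 || is.na(s$m)) next
    ratio <- s$m / fn$m
    pass <- if (direction == "UP") {
      ratio > threshold && (!call_filter || s$det)
    } else {
      ratio < threshold && (!call_filter || fn$det)
    }
    if (pass) hits <- c(hits, g)
  }
  hits
}

# literal 5-gene x 8-sample fixture (one experiment's worth per 4 samples)
tiny_fixture <- function() {
  genes <- paste0("g", 1:5)
  sids <- c(paste0("E1_", c("FN", "S", "R30", "R3H")),
            paste0("E2_", c("FN", "S", "R30", "R3H")))
  sig <- matrix(c(
    100, 800, 480, 240, 110, 770, 462, 231,   # strong up, relaxing
    500, 90, 120, 300, 480, 100, 130, 310,    # down, recovering
    50, 50, 50, 50, 55, 52, 51, 53,           # flat
    10, 90, 85, 80, 12, 88, 84, 79,           # up but absent-called under -S
    200, NA, 100, 100, 210, 400, 120, 110     # missing value case
  ), nrow = 5, byrow = TRUE, dimnames = list(genes, sids))
  cl <- matrix("P", 5, 8, dimnames = dimnames(sig))
  cl[4, c("E1_S", "E2_S")] <- "A"
  cl[3, "E1_FN"] <- "M"
  expression_matrix(sig, cl)
}

tiny_design <- function() {
  sample_design(data.frame(
    sample_id = c(paste0("E1_", c("FN", "S", "R30", "R3H")),
                  paste0("E2_", c("FN", "S", "R30", "R3H"))),
    experiment = rep(c("EXP1", "EXP2"), each = 4),
    condition = rep(c("FN", "S_MINUS", "RESUPPLY_30M", "RESUPPLY_3H"), 2),
    replicate = 1L, stringsAsFactors = FALSE
  ))
}

# fold-change table built directly from stated ratios, for profile tests:
# one gene, ratios per (experiment, contrast)
fc_from_ratios <- function(gene, ratios) {
  # ratios: data.frame(experiment, contrast, ratio, detected_num, detected_den)
  data.frame(
    gene_id = gene, experiment = ratios$experiment,
    contrast = ratios$contrast, ratio = ratios$ratio,
    log2_ratio = log2(ratios$ratio),
    detected_num = ratios$detected_num %||% TRUE,
    detected_den = ratios$detected_den %||% TRUE,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
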