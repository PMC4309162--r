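#' Configuration for the synthetic starvation/resupply simulator
#'
#' Describes a synthetic study with the structure the screen assumes: two
#' biological replicate experiments, four conditions (full nutrition,
#' 48 h starvation, 30 min and 3 h resupply), a configurable number of
#' technical replicate arrays per cell, log-normal signal noise, and
#' planted responder genes with known direction, resupply kinetics and
#' cross-nutrient behaviour.
#'
#' Planted categories are named `<DIRECTION>.<PATTERN>` over the six
#' feasible resupply sign patterns (e.g. `UP.DDD` is a classic class-I
#' induced gene that relaxes monotonically). Per-category fractions must
#' sum to at most 1; the remainder are null genes with no planted effect.
#' Starvation effect sizes are drawn log2-uniform from `effect_range`
#' (bits); resupply kinetics are linear multipliers applied to the starved
#' level at 30 min and 3 h, one pair per pattern, chosen so every feasible
#' pattern is exercised. Detection calls are threshold-driven: within each
#' experiment the absent threshold is the `target_absent_fraction` quantile
#' of realised log2 signals (default 0.30, inside the 25–36% range typical
#' of whole-genome arrays on this platform), with a thin marginal band
#' above it and an optional random call-flip rate modelling call noise.
#'
#' @param n_genes Number of simulated genes.
#' @param class_fractions Named fractions per planted category; default
#'   0.005 for each of the 12 direction-by-pattern categories.
#' @param nutrient_fractions Mix of cross-nutrient behaviours among planted
#'   responders (`S_ONLY`, `S_N`, `S_P`, `S_N_P`); default 5:9:2:5, the
#'   proportions observed for sulfate-responsive transcription factors.
#' @param effect_range Log2 starvation effect range in bits (default
#'   c(2.5, 5): 5.7- to 32-fold, safely past a 5-fold screen).
#' @param kinetics Named list of `c(m30, m3h)` multipliers per pattern.
#' @param noise_sd Per-sample log2-scale Gaussian SD (>= 0).
#' @param baseline_mean,baseline_sd Log2 baseline distribution (default
#'   N(8, 2)).
#' @param responder_min_baseline Planted responders draw baselines
#'   truncated to at least this log2 level so they are detectable in the
#'   condition their screen requires (null genes carry the absent mass).
#' @param target_absent_fraction Expected fraction of absent calls.
#' @param marginal_band Quantile width of the marginal (`M`) call band.
#' @param call_flip_rate Probability a call is flipped between detected
#'   and absent (call noise; set 0 for a fully noiseless run).
#' @param n_technical_replicates Arrays per (experiment, condition).
#' @param nutrient_effect_range,nutrient_null_range Log2 ranges (bits) for
#'   responding / non-responding nutrient fold changes (magnitudes).
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return List of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 10000,
                              class_fractions = NULL,
                              nutrient_fractions = c(S_ONLY = 5, S_N = 9,
                                                     S_P = 2, S_N_P = 5) / 21,
                              effect_range = c(2.5, 5),
                              kinetics = default_kinetics(),
                              noise_sd = 0.2,
                              baseline_mean = 8, baseline_sd = 2,
                              responder_min_baseline = 8,
                              target_absent_fraction = 0.30,
                              marginal_band = 0.02,
                              call_flip_rate = 0.01,
                              n_technical_replicates = 2,
                              nutrient_effect_range = c(1.2, 3),
                              nutrient_null_range = c(-0.8, 0.8),
                              seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for reproducibility")
  if (is.null(class_fractions)) {
    cats <- as.vector(outer(c("UP", "DOWN"), feasible_patterns(), paste,
                            sep = "."))
    class_fractions <- stats::setNames(rep(0.005, length(cats)), cats)
  }
  if (sum(class_fractions) > 1)
    stop("class fractions sum to more than 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (call_flip_rate < 0 || call_flip_rate > 1)
    stop("call_flip_rate must be in [0, 1]")
  if (target_absent_fraction <= 0 || target_absent_fraction >= 1)
    stop("target_absent_fraction must be in (0, 1)")
  bad <- setdiff(sub("^(UP|DOWN)\\.", "", names(class_fractions)),
                 feasible_patterns())
  if (length(bad))
    stop("class fractions name infeasible pattern(s): ",
         paste(bad, collapse = ", "))
  structure(list(
    n_genes = n_genes, class_fractions = class_fractions,
    nutrient_fractions = nutrient_fractions / sum(nutrient_fractions),
    effect_range = effect_range, kinetics = kinetics, noise_sd = noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    responder_min_baseline = responder_min_baseline,
    target_absent_fraction = target_absent_fraction,
    marginal_band = marginal_band, call_flip_rate = call_flip_rate,
    n_technical_replicates = n_technical_replicates,
    nutrient_effect_range = nutrient_effect_range,
    nutrient_null_range = nutrient_null_range,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Default resupply kinetics per sign pattern
#'
#' Linear multipliers `c(m30, m3h)` applied to the starved expression
#' level at 30 min and 3 h of resupply; each pair realises one of the six
#' feasible sign patterns (e.g. `DDD`: 0.6 then 0.3 — monotone relaxation).
#'
#' @return Named list of length-2 numeric vectors.
#' @export
default_kinetics <- function() {
  list(
    DDD = c(0.6, 0.3), DDU = c(0.4, 0.7), UDD = c(1.5, 0.5),
    UUD = c(1.8, 1.3), UUU = c(1.3, 1.8), DUU = c(0.7, 1.4)
  )
}

#' Simulate a starvation/resupply expression study with planted truth
#'
#' Generates the full synthetic study described by a
#' [simulation_config()]: a combined [expression_matrix()] over both
#' experiments, the matching [sample_design()], nitrogen/phosphorus
#' nutrient fold-change tables, and a per-gene ground-truth table for
#' recovery testing. Baseline log2 expression is N(baseline_mean,
#' baseline_sd); condition means add the planted starvation effect and
#' resupply kinetics; each array adds N(0, noise_sd) on the log2 scale
#' (log-normal signal noise). Identical seeds give bit-identical output.
#'
#' @param config A [simulation_config()].
#' @return List of class `"sim_data"`: `expression`, `design`, `n_fc`,
#'   `p_fc`, `truth` (data.frame: gene_id, category, direction, pattern,
#'   s_fold, nutrient_category, n_fc, p_fc), `call_thresholds`, `config`.
#' @examples
#' sim <- simulate_experiment(simulation_config(n_genes = 200, seed = 42))
#' sim$expression
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("GENE%05d", seq_len(n))

  # planted categories: contiguous blocks, remainder null
  counts <- round(config$class_fractions * n)
  category <- rep("NULL", n)
  at <- 1L
  for (nm in names(counts)) {
    k <- counts[[nm]]
    if (k > 0) {
      category[at:(at + k - 1L)] <- nm
      at <- at + k
    }
  }
  is_resp <- category != "NULL"
  direction <- ifelse(is_resp, sub("\\..*$", "", category), NA_character_)
  pattern <- ifelse(is_resp, sub("^[A-Z]+\\.", "", category), NA_character_)

  # starvation effects (bits), signed by direction
  mag <- stats::runif(n, config$effect_range[1], config$effect_range[2])
  s_effect <- ifelse(is_resp, ifelse(direction == "UP", mag, -mag), 0)

  # baselines: responders truncated so their screen-relevant condition is
  # expressed; null genes carry the absent-call mass
  u <- stats::runif(n)
  lo <- stats::pnorm((config$responder_min_baseline - config$baseline_mean) /
                       config$baseline_sd)
  u2 <- ifelse(is_resp, lo + u * (1 - lo), u)
  baseline <- config$baseline_mean + config$baseline_sd * stats::qnorm(u2)

  # cross-nutrient behaviour
  ncat_draw <- sample(names(config$nutrient_fractions), n, replace = TRUE,
                      prob = config$nutrient_fractions)
  nutrient_category <- ifelse(is_resp, ncat_draw, NA_character_)
  draw_nfc <- function(respond_flag) {
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    magr <- stats::runif(n, config$nutrient_effect_range[1],
                         config$nutrient_effect_range[2])
    nullv <- stats::runif(n, config$nutrient_null_range[1],
                          config$nutrient_null_range[2])
    ifelse(respond_flag, sgn * magr, nullv)
  }
  n_resp_flag <- is_resp & ncat_draw %in% c("S_N", "S_N_P")
  p_resp_flag <- is_resp & ncat_draw %in% c("S_P", "S_N_P")
  n_effect <- draw_nfc(n_resp_flag)
  p_effect <- draw_nfc(p_resp_flag)

  # condition means on log2 scale
  kin30 <- vapply(pattern, function(p)
    if (is.na(p)) 1 else config$kinetics[[p]][1], 0)
  kin3h <- vapply(pattern, function(p)
    if (is.na(p)) 1 else config$kinetics[[p]][2], 0)
  means <- cbind(
    FN = baseline,
    S_MINUS = baseline + s_effect,
    RESUPPLY_30M = baseline + s_effect + log2(kin30),
    RESUPPLY_3H = baseline + s_effect + log2(kin3h)
  )

  # samples
  nrep <- config$n_technical_replicates
  grid <- expand.grid(replicate = seq_len(nrep),
                      condition = core_conditions(),
                      experiment = experiments(),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("experiment", "condition", "replicate")]
  grid$sample_id <- sprintf("%s_%s_R%d", grid$experiment, grid$condition,
                            grid$replicate)
  l2 <- matrix(NA_real_, n, nrow(grid),
               dimnames = list(genes, grid$sample_id))
  noise <- matrix(stats::rnorm(n * nrow(grid), 0, max(config$noise_sd, 0)),
                  n, nrow(grid))
  if (config$noise_sd == 0) noise[] <- 0
  for (j in seq_len(nrow(grid)))
    l2[, j] <- means[, grid$condition[j]] + noise[, j]
  signal <- 2^l2

  # threshold-driven detection calls, per experiment
  call <- matrix("P", n, nrow(grid), dimnames = dimnames(l2))
  thresholds <- stats::setNames(numeric(length(experiments())), experiments())
  for (e in experiments()) {
    cols <- grid$sample_id[grid$experiment == e]
    v <- l2[, cols]
    thA <- stats::quantile(v, config$target_absent_fraction, names = FALSE)
    thM <- stats::quantile(v, min(config$target_absent_fraction +
                                    config$marginal_band, 1), names = FALSE)
    cl <- ifelse(v < thA, "A", ifelse(v < thM, "M", "P"))
    call[, cols] <- cl
    thresholds[e] <- thA
  }
  if (config$call_flip_rate > 0) {
    flip <- matrix(stats::runif(length(call)) < config$call_flip_rate,
                   nrow(call), ncol(call))
    call[flip] <- ifelse(call[flip] == "A", "P", "A")
  }

  expr <- expression_matrix(signal, call)
  design <- sample_design(grid[, c("sample_id", "experiment", "condition",
                                   "replicate")])
  truth <- data.frame(
    gene_id = genes, category = category, direction = direction,
    pattern = pattern, s_fold = 2^s_effect,
    nutrient_category = nutrient_category,
    n_fc = 2^n_effect, p_fc = 2^p_effect, stringsAsFactors = FALSE
  )
  structure(list(
    expression = expr, design = design,
    n_fc = stats::setNames(2^n_effect, genes),
    p_fc = stats::setNames(2^p_effect, genes),
    truth = truth, call_thresholds = thresholds, config = config
  ), class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("sim_data: %d genes, %d samples (seed %d)\n",
              nrow(x$expression$signal), ncol(x$expression$signal),
              x$config$seed))
  cat(sprintf("planted responders: %d (%s)\n",
              sum(x$truth$category != "NULL"),
              paste(names(which(table(x$truth$category) > 0)), collapse = ", ")))
  invisible(x)
}

#' Write a simulated study as the TSV inputs the readers consume
#'
#' Emits `expression.tsv`, `design.tsv`, `n_fc.tsv`, `p_fc.tsv` and
#' `truth.tsv` in the formats read by [read_expression_table()],
#' [read_design()] and [read_nutrient_fc()].
#'
#' @param sim A `"sim_data"` object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_simulation <- function(sim, out_dir) {
  stopifnot(inherits(sim, "sim_data"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_expression_table(sim$expression, file.path(out_dir, "expression.tsv"))
  utils::write.table(as.data.frame(sim$design),
                     file.path(out_dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  for (nut in c("n_fc", "p_fc")) {
    df <- data.frame(gene_id = names(sim[[nut]]),
                     fold_change = fmt_num(unname(sim[[nut]])))
    utils::write.table(df, file.path(out_dir, paste0(nut, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       eol = "\n")
  }
  tr <- sim$truth
  for (j in seq_along(tr)) if (is.numeric(tr[[j]])) tr[[j]] <- fmt_num(tr[[j]])
  utils::write.table(tr, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA", eol = "\n")
  invisible(out_dir)
}

#' Configuration for the synthetic metabolite generator
#'
#' @param effects Named numeric vector: planted log2 effect of starvation
#'   per metabolite (0 = null). Defaults to three 2-fold accumulating,
#'   three 2-fold depleted and two unchanged metabolites.
#' @param relaxation Multipliers on the log2 starvation effect remaining
#'   at 30 min and 3 h of resupply (default c(0.7, 0.3): gradual return
#'   toward the full-nutrition level).
#' @param cv Coefficient of variation of replicate values (> 0).
#' @param n_replicates Replicates per (metabolite, experiment, condition);
#'   default 3 independent measurements.
#' @param base Baseline abundance in arbitrary concentration units.
#' @param seed Mandatory seed.
#' @return List of class `"metabolite_config"`.
#' @export
metabolite_config <- function(effects = NULL, relaxation = c(0.7, 0.3),
                              cv = 0.1, n_replicates = 3, base = 100,
                              seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (cv <= 0) stop("cv must be > 0")
  if (is.null(effects)) {
    effects <- c(MET01 = 1, MET02 = 1, MET03 = 1,
                 MET04 = -1, MET05 = -1, MET06 = -1,
                 MET07 = 0, MET08 = 0)
  }
  structure(list(effects = effects, relaxation = relaxation, cv = cv,
                 n_replicates = n_replicates, base = base,
                 seed = as.integer(seed)),
            class = "metabolite_config")
}

#' Simulate metabolite replicate tables with planted effects
#'
#' Replicate values are Normal(condition mean, cv x mean) around condition
#' means that carry the planted starvation effect and its partial
#' relaxation on resupply, for two experiments. Identical seeds give
#' identical tables.
#'
#' @param config A [metabolite_config()].
#' @return List with `table` (long data.frame: metabolite, experiment,
#'   condition, replicate, value) and `truth` (metabolite, s_fold,
#'   condition means).
#' @export
generate_metabolites <- function(config) {
  stopifnot(inherits(config, "metabolite_config"))
  set.seed(config$seed)
  conds <- core_conditions()
  mult <- c(FN = 0, S_MINUS = 1, RESUPPLY_30M = config$relaxation[1],
            RESUPPLY_3H = config$relaxation[2])
  rows <- expand.grid(
    replicate = seq_len(config$n_replicates), condition = conds,
    experiment = experiments(), metabolite = names(config$effects),
    stringsAsFactors = FALSE
  )[, c("metabolite", "experiment", "condition", "replicate")]
  mu <- config$base * 2^(config$effects[rows$metabolite] *
                           mult[rows$condition])
  rows$value <- stats::rnorm(nrow(rows), mean = mu, sd = config$cv * mu)
  truth <- data.frame(
    metabolite = names(config$effects),
    s_fold = 2^unname(config$effects),
    stringsAsFactors = FALSE
  )
  list(table = rows, truth = truth)
}

#' Compare pipeline assignments with planted truth
#'
#' Scores, per planted category, how often the pipeline recovered (a) the
#' responder status (membership in the intersected responder set of the
#' matching direction), (b) the response class implied by the planted sign
#' pattern under the class map in use, and (c) the cross-nutrient
#' specificity category. Null genes contribute a false-positive rate
#' instead. With no planted responders at all, the per-category table is
#' empty and only false positives are reported.
#'
#' @param result A `"sulfate_screen"` object (see [sulfate_screen()]) run
#'   on the simulated data.
#' @param truth The `truth` data.frame of a `"sim_data"` object.
#' @return List of class `"recovery"`: `per_category` (category, n,
#'   responder_rate, class_rate, specificity_rate), `overall` (named
#'   rates), `false_positive_rate`.
#' @export
evaluate_recovery <- function(result, truth) {
  stopifnot(inherits(result, "sulfate_screen"))
  pipe_genes <- result$genes
  if (!all(truth$gene_id %in% pipe_genes) ||
      !all(pipe_genes %in% truth$gene_id))
    stop("gene sets of pipeline result and truth do not match")
  cls_at <- result$params$classify_at
  inter_up <- result$screens[[screen_key("UP", cls_at["UP"])]]$intersection
  inter_dn <- result$screens[[screen_key("DOWN", cls_at["DOWN"])]]$intersection
  classes <- rbind(result$classes$UP, result$classes$DOWN)
  spec <- if (!is.null(result$specificity)) result$specificity$genes else NULL

  planted <- truth[truth$category != "NULL", , drop = FALSE]
  per <- NULL
  if (nrow(planted)) {
    per <- do.call(rbind, lapply(split(planted, planted$category),
                                 function(tr) {
      dir <- tr$direction[1]
      inter <- if (dir == "UP") inter_up else inter_dn
      resp_ok <- tr$gene_id %in% inter
      cmap <- result$params$class_map[[dir]]
      expected <- unname(cmap[tr$pattern])
      got <- classes$class_label[match(tr$gene_id, classes$gene_id)]
      class_ok <- !is.na(got) & got == expected
      spec_ok <- if (!is.null(spec)) {
        gotc <- spec$category[match(tr$gene_id, spec$gene_id)]
        !is.na(gotc) & gotc == tr$nutrient_category
      } else rep(NA, nrow(tr))
      data.frame(
        category = tr$category[1], n = nrow(tr),
        responder_rate = mean(resp_ok),
        class_rate = mean(class_ok),
        specificity_rate = if (all(is.na(spec_ok))) NA_real_
                           else mean(spec_ok),
        stringsAsFactors = FALSE
      )
    }))
    rownames(per) <- NULL
  } else {
    per <- data.frame(category = character(), n = integer(),
                      responder_rate = numeric(), class_rate = numeric(),
                      specificity_rate = numeric(), stringsAsFactors = FALSE)
  }
  nulls <- truth$gene_id[truth$category == "NULL"]
  fp <- if (length(nulls))
    mean(nulls %in% union(inter_up, inter_dn)) else NA_real_
  wt <- function(col) {
    if (!nrow(per) || all(is.na(per[[col]]))) return(NA_real_)
    sum(per[[col]] * per$n, na.rm = TRUE) / sum(per$n[!is.na(per[[col]])])
  }
  overall <- c(responder = wt("responder_rate"), class = wt("class_rate"),
               specificity = wt("specificity_rate"))
  structure(list(per_category = per, overall = overall,
                 false_positive_rate = fp),
            class = "recovery")
}

#' @export
print.recovery <- function(x, ...) {
  cat("planted-truth recovery\n")
  if (nrow(x$per_category)) print(x$per_category, row.names = FALSE)
  cat(sprintf("overall: responder %.3f, class %.3f, specificity %s\n",
              x$overall["responder"], x$overall["class"],
              ifelse(is.na(x$overall["specificity"]), "NA",
                     sprintf("%.3f", x$overall["specificity"]))))
  cat(sprintf("false-positive rate (null genes): %s\n",
              ifelse(is.na(x$false_positive_rate), "NA",
                     sprintf("%.4f", x$false_positive_rate))))
  invisible(x)
}
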