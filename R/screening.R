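#' Per-condition mean signal and detection status
#'
#' Aggregates the replicate arrays of one (experiment, condition) cell into
#' a per-gene mean signal and a per-gene detection flag. The default mean is
#' geometric, the natural choice for multiplicative-noise intensity data;
#' an arithmetic mean is available. A gene counts as detected in the
#' condition when at least one replicate carries a present (`P`) or marginal
#' (`M`) call — the weakest reading consistent with a per-condition call
#' filter. `NA` signals are excluded from both the mean and the call
#' aggregation; a gene with all signals `NA` gets mean `NA` and
#' `detected = FALSE`.
#'
#' @param expr An [expression_matrix()].
#' @param design A [sample_design()] covering the matrix's samples.
#' @param experiment,condition Tokens selecting the design cell.
#' @param aggregate `"geometric"` (default) or `"arithmetic"`.
#' @return data.frame with columns `gene_id`, `mean_signal`, `detected`.
#' @export
condition_mean <- function(expr, design, experiment, condition,
                           aggregate = c("geometric", "arithmetic")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(expr, "expression_matrix"))
  sel <- design$sample_id[design$experiment == experiment &
                            design$condition == condition]
  sel <- intersect(sel, colnames(expr$signal))
  if (!length(sel))
    stop(sprintf("no samples match (%s, %s)", experiment, condition))
  sig <- expr$signal[, sel, drop = FALSE]
  cl <- expr$call[, sel, drop = FALSE]
  if (aggregate == "geometric") {
    m <- exp(rowMeans(log(sig), na.rm = TRUE))
  } else {
    m <- rowMeans(sig, na.rm = TRUE)
  }
  m[!is.finite(m) & !(m %in% 0)] <- NA_real_  # all-NA rows -> NaN -> NA
  m[rowSums(!is.na(sig)) == 0] <- NA_real_
  det <- rowSums((cl == "P" | cl == "M") & !is.na(sig)) > 0
  det[is.na(m)] <- FALSE
  data.frame(gene_id = rownames(sig), mean_signal = unname(m),
             detected = unname(det), stringsAsFactors = FALSE)
}

#' Fold change between two conditions of one experiment
#'
#' Ratio of per-gene condition means (numerator over denominator), replicate
#' means first, ratio second. A zero or `NA` denominator mean yields an `NA`
#' ratio; the number of affected genes is reported via `message()`. No
#' pseudo-count is added by default; `floor` > 0 clamps both means from
#' below before division for users who want one.
#'
#' @param expr An [expression_matrix()].
#' @param design A [sample_design()].
#' @param experiment Experiment token.
#' @param contrast One of the contrasts in [contrasts_table()].
#' @param floor Lower clamp applied to both condition means (default 0 =
#'   off).
#' @param aggregate Passed to [condition_mean()].
#' @return data.frame with columns `gene_id`, `experiment`, `contrast`,
#'   `ratio`, `log2_ratio`, `detected_num`, `detected_den`.
#' @examples
#' sim <- simulate_experiment(simulation_config(n_genes = 50, seed = 1))
#' fc <- fold_change(sim$expression, sim$design, "EXP1", "S_vs_FN")
#' @export
fold_change <- function(expr, design, experiment, contrast, floor = 0,
                        aggregate = "geometric") {
  ct <- contrasts_table()
  if (!contrast %in% ct$contrast)
    stop("unknown contrast: ", contrast)
  row <- ct[ct$contrast == contrast, ]
  num <- condition_mean(expr, design, experiment, row$numerator, aggregate)
  den <- condition_mean(expr, design, experiment, row$denominator, aggregate)
  nm <- num$mean_signal
  dm <- den$mean_signal
  if (floor > 0) {
    nm <- pmax(nm, floor)
    dm <- pmax(dm, floor)
  }
  ratio <- nm / dm
  bad <- is.na(dm) | dm == 0
  ratio[bad] <- NA_real_
  if (any(bad))
    message(sum(bad), " gene(s) with zero/NA denominator mean in ",
            experiment, " ", contrast, "; ratio set to NA")
  data.frame(
    gene_id = num$gene_id, experiment = experiment, contrast = contrast,
    ratio = ratio, log2_ratio = log2(ratio),
    detected_num = num$detected, detected_den = den$detected,
    stringsAsFactors = FALSE
  )
}

#' All contrasts for all experiments
#'
#' Convenience wrapper computing every contrast of [contrasts_table()] for
#' every experiment present in the design, stacked long.
#'
#' @inheritParams fold_change
#' @param contrasts Contrast names to compute (default: all four).
#' @return Long data.frame in the [fold_change()] format.
#' @export
fold_change_table <- function(expr, design,
                              contrasts = contrasts_table()$contrast,
                              floor = 0, aggregate = "geometric") {
  exps <- intersect(experiments(), unique(design$experiment))
  out <- lapply(exps, function(e) {
    do.call(rbind, lapply(contrasts, function(ct)
      fold_change(expr, design, e, ct, floor = floor, aggregate = aggregate)))
  })
  do.call(rbind, out)
}

#' Call-filtered responder screen for one experiment
#'
#' Selects responder genes from the starvation contrast (`S_vs_FN`) of one
#' experiment. Up-screens keep genes detected (P or M) under starvation with
#' ratio strictly above the threshold; down-screens keep genes detected
#' under full nutrition with ratio strictly below the threshold. Thresholds
#' are strict inequalities ("more than 5-fold" means ratio > 5). Genes with
#' an `NA` ratio are excluded.
#'
#' @param fc A [fold_change()] slice for contrast `S_vs_FN` of one
#'   experiment.
#' @param direction `"UP"` or `"DOWN"`.
#' @param threshold Fold cutoff: > 1 for `UP` (e.g. 5 or 2), < 1 for `DOWN`
#'   (e.g. 0.2 or 0.5).
#' @param call_filter Set `FALSE` to disable the detection-call filter
#'   (screen on ratio alone).
#' @return Character vector of responder gene identifiers.
#' @export
responder_screen <- function(fc, direction = c("UP", "DOWN"), threshold,
                             call_filter = TRUE) {
  direction <- match.arg(direction)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  if (direction == "UP" && threshold <= 1)
    stop("UP screen requires threshold > 1, got ", threshold)
  if (direction == "DOWN" && threshold >= 1)
    stop("DOWN screen requires threshold < 1, got ", threshold)
  ok <- !is.na(fc$ratio)
  if (direction == "UP") {
    keep <- ok & fc$ratio > threshold
    if (call_filter) keep <- keep & fc$detected_num
  } else {
    keep <- ok & fc$ratio < threshold
    if (call_filter) keep <- keep & fc$detected_den
  }
  fc$gene_id[keep]
}

#' Intersect per-experiment responder sets
#'
#' The replicate-intersection step: a gene is called responsive only when
#' it passes the screen in every experiment. Also reports the per-set and
#' intersection cardinalities (the Venn counts).
#'
#' @param sets Named list (one gene-identifier vector per experiment),
#'   length >= 2.
#' @param direction,threshold Metadata recorded on the result.
#' @return Object of class `"responder_set"`: list with `per_experiment`,
#'   `intersection`, `counts`, `direction`, `threshold`.
#' @export
intersect_replicates <- function(sets, direction = NA_character_,
                                 threshold = NA_real_) {
  if (!is.list(sets) || length(sets) < 2L)
    stop("need responder sets from at least two experiments")
  inter <- Reduce(intersect, sets)
  counts <- c(vapply(sets, length, 0L), intersection = length(inter))
  structure(
    list(per_experiment = sets, intersection = inter, counts = counts,
         direction = direction, threshold = threshold),
    class = "responder_set"
  )
}

#' @export
print.responder_set <- function(x, ...) {
  cat(sprintf("responder_set: %s at %s-fold\n",
              x$direction, format(x$threshold)))
  for (nm in names(x$per_experiment))
    cat(sprintf("  %s: %d genes\n", nm, length(x$per_experiment[[nm]])))
  cat(sprintf("  intersection: %d genes\n", length(x$intersection)))
  invisible(x)
}

#' Screen responders across all experiments and intersect
#'
#' Runs [responder_screen()] on the `S_vs_FN` slice of every experiment in
#' a long fold-change table and intersects the results.
#'
#' @param fc_table Output of [fold_change_table()].
#' @inheritParams responder_screen
#' @return A `"responder_set"` (see [intersect_replicates()]).
#' @export
screen_responders <- function(fc_table, direction, threshold,
                              call_filter = TRUE) {
  slice <- fc_table[fc_table$contrast == "S_vs_FN", , drop = FALSE]
  exps <- sort(unique(slice$experiment))
  if (length(exps) < 2L)
    stop("replicate intersection needs at least two experiments")
  sets <- lapply(exps, function(e)
    responder_screen(slice[slice$experiment == e, , drop = FALSE],
                     direction, threshold, call_filter))
  names(sets) <- exps
  intersect_replicates(sets, direction, threshold)
}
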