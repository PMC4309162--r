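#' Default contrast panel for co-behaviour profiles
#'
#' Three fold-change contrasts (starvation plus the two resupply-versus-
#' starved ratios) for each experiment, experiment 1 first: six positions.
#' Absolute signals are excluded on purpose — co-behaviour compares
#' fold-change patterns, not expression levels.
#'
#' @return data.frame with columns `experiment`, `contrast`.
#' @export
default_contrast_panel <- function() {
  expand.grid(
    contrast = c("S_vs_FN", "R30_vs_S", "R3H_vs_S"),
    experiment = experiments(),
    stringsAsFactors = FALSE
  )[, c("experiment", "contrast")]
}

#' Build a log2 fold-change profile for one gene
#'
#' Extracts the gene's ratios for a configured (experiment, contrast) panel
#' from a long fold-change table and log2-transforms them. By default
#' absent-called values are kept — low-expressed regulators would otherwise
#' drop out of the comparison entirely; with `include_absent = FALSE`,
#' positions whose numerator or denominator condition was undetected become
#' `NA`.
#'
#' @param gene One gene identifier (must be present in the table).
#' @param fc_table Output of [fold_change_table()].
#' @param panel data.frame of (`experiment`, `contrast`) rows; defaults to
#'   [default_contrast_panel()].
#' @param include_absent Keep values from undetected conditions (default
#'   `TRUE`).
#' @return Named numeric vector of log2 ratios, one per panel row (names
#'   `EXPERIMENT.CONTRAST`), `NA` where the ratio is undefined or masked.
#' @export
build_profile <- function(gene, fc_table, panel = default_contrast_panel(),
                          include_absent = TRUE) {
  if (!gene %in% fc_table$gene_id)
    stop("gene not present in fold-change table: ", gene)
  vals <- vapply(seq_len(nrow(panel)), function(i) {
    sl <- fc_table[fc_table$experiment == panel$experiment[i] &
                     fc_table$contrast == panel$contrast[i], ]
    j <- match(gene, sl$gene_id)
    if (is.na(j)) return(NA_real_)
    if (!include_absent && !(sl$detected_num[j] && sl$detected_den[j]))
      return(NA_real_)
    log2(sl$ratio[j])
  }, 0)
  stats::setNames(vals, paste(panel$experiment, panel$contrast, sep = "."))
}

#' Profiles for many genes at once
#'
#' @inheritParams build_profile
#' @param genes Character vector of gene identifiers.
#' @return Numeric matrix, genes in rows, panel positions in columns.
#' @export
build_profiles <- function(genes, fc_table, panel = default_contrast_panel(),
                           include_absent = TRUE) {
  out <- t(vapply(genes, build_profile, numeric(nrow(panel)),
                  fc_table = fc_table, panel = panel,
                  include_absent = include_absent))
  rownames(out) <- genes
  out
}

#' Concordance between two fold-change profiles
#'
#' Pearson correlation over the positions where both profiles are finite
#' (Spearman available for robustness). At least three paired points are
#' required for a reported correlation; fewer, or zero variance in either
#' profile, yields `NA` with an explanatory flag. The score is descriptive
#' concordance only, invariant to positive affine rescaling of either
#' profile and symmetric in its arguments.
#'
#' @param tf_profile,target_profile Numeric vectors of equal length (log2
#'   ratios from [build_profile()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `n_points`, `flag` (`""`, `"insufficient_data"`
#'   or `"zero_variance"`).
#' @examples
#' cobehavior_score(1:6, c(2, 1, 4, 3, 6, 5))  # r ~ 0.886
#' @export
cobehavior_score <- function(tf_profile, target_profile,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(tf_profile) != length(target_profile))
    stop("profiles must have equal length")
  ok <- is.finite(tf_profile) & is.finite(target_profile)
  n <- sum(ok)
  if (n < 3L)
    return(list(r = NA_real_, n_points = n, flag = "insufficient_data"))
  a <- tf_profile[ok]
  b <- target_profile[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, n_points = n, flag = "zero_variance"))
  list(r = stats::cor(a, b, method = method), n_points = n, flag = "")
}

#' Rank transcription factors by mean concordance with a target set
#'
#' Scores every (TF, target) pair with [cobehavior_score()] and ranks TFs
#' by their mean correlation over the target set, ignoring flagged
#' (unscorable) pairs; a TF appearing in the target set is not paired with
#' itself. TFs whose pairs are all flagged are excluded, with the reason
#' recorded. Ties in mean correlation break deterministically by gene
#' identifier.
#'
#' @param tf_set,target_set Character vectors of gene identifiers
#'   (non-empty).
#' @param profiles Matrix from [build_profiles()] covering all members.
#' @param method Passed to [cobehavior_score()].
#' @return List with `pairs` (tf, target, r, n_points, flag) and `ranking`
#'   (tf, mean_r, n_targets, excluded, reason; scored TFs first, sorted by
#'   decreasing mean_r).
#' @export
rank_tf_targets <- function(tf_set, target_set, profiles,
                            method = "pearson") {
  if (!length(tf_set) || !length(target_set))
    stop("tf_set and target_set must be non-empty")
  miss <- setdiff(c(tf_set, target_set), rownames(profiles))
  if (length(miss))
    stop("profiles missing for: ", paste(miss, collapse = ", "))
  pairs <- do.call(rbind, lapply(tf_set, function(tf) {
    do.call(rbind, lapply(setdiff(target_set, tf), function(tg) {
      sc <- cobehavior_score(profiles[tf, ], profiles[tg, ], method)
      data.frame(tf = tf, target = tg, r = sc$r, n_points = sc$n_points,
                 flag = sc$flag, stringsAsFactors = FALSE)
    }))
  }))
  ranking <- do.call(rbind, lapply(sort(unique(pairs$tf)), function(tf) {
    sub <- pairs[pairs$tf == tf & pairs$flag == "", , drop = FALSE]
    if (!nrow(sub)) {
      data.frame(tf = tf, mean_r = NA_real_, n_targets = 0L,
                 excluded = TRUE, reason = "all pairs unscorable",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(tf = tf, mean_r = mean(sub$r), n_targets = nrow(sub),
                 excluded = FALSE, reason = "", stringsAsFactors = FALSE)
    }
  }))
  ord <- order(ranking$excluded, -ifelse(is.na(ranking$mean_r), -Inf,
                                         ranking$mean_r), ranking$tf)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  list(pairs = pairs, ranking = ranking)
}
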