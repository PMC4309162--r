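#' Metabolite fold change between two condition groups
#'
#' Ratio of arithmetic group means (A over B) — the conventional
#' presentation for metabolite tables, where replicate values are
#' absolute concentrations, not multiplicative intensities.
#'
#' @param groupA,groupB Non-empty numeric vectors of replicate values.
#' @return List with `fold_change` (NA with `flag = "zero_denominator"`
#'   when mean(B) is 0) and `flag`.
#' @export
metabolite_fc <- function(groupA, groupB) {
  if (!length(groupA) || !length(groupB))
    stop("both groups must be non-empty")
  mB <- mean(groupB)
  if (mB == 0)
    return(list(fold_change = NA_real_, flag = "zero_denominator"))
  list(fold_change = mean(groupA) / mB, flag = "")
}

#' Welch's unequal-variance two-sample t-test
#'
#' The heteroscedastic, double-sided test: statistic
#' t = (mean A - mean B) / sqrt(sA^2/nA + sB^2/nB) with
#' Welch-Satterthwaite degrees of freedom, two-sided p from the t
#' distribution. No pooled-variance fallback. Both groups need at least
#' two values; two exactly constant groups are degenerate (no p-value,
#' flagged) rather than an error.
#'
#' @param groupA,groupB Numeric vectors, length >= 2 each.
#' @return List with `t`, `df`, `p_value`, `flag` (`""` or
#'   `"degenerate"`).
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4, p ~ 0.288
#' @export
welch_t_test <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values")
  if (anyNA(groupA) || anyNA(groupB))
    stop("missing values in input groups")
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0)
    return(list(t = NA_real_, df = NA_real_, p_value = NA_real_,
                flag = "degenerate"))
  ht <- stats::t.test(groupA, groupB, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, flag = "")
}

#' Significance flag at a strict alpha
#'
#' Strict comparison (`p < alpha`): a p-value exactly at alpha is not
#' significant.
#'
#' @param p P-value(s) in (0, 1].
#' @param alpha Significance level (default 0.05).
#' @return Logical vector (`NA` where `p` is `NA`).
#' @export
significance_flag <- function(p, alpha = 0.05) {
  p < alpha
}

#' Fold changes and Welch tests over a metabolite table
#'
#' For each metabolite and experiment, computes the fold change of group
#' means and the Welch test for each requested condition contrast. No
#' multiple-testing correction is applied; the output carries `n_tests`
#' so users can apply their own.
#'
#' @param tab Long data.frame (`metabolite`, `experiment`, `condition`,
#'   `replicate`, `value`), e.g. from [read_metabolite_table()].
#' @param contrasts data.frame of condition pairs (columns `contrast`,
#'   `numerator`, `denominator`); defaults to [contrasts_table()].
#' @param alpha Significance level for the strict flag.
#' @return data.frame: `metabolite`, `experiment`, `contrast`,
#'   `fold_change`, `t`, `df`, `p`, `significant`, `n_tests`, `flag`.
#' @export
metabolite_results <- function(tab, contrasts = contrasts_table(),
                               alpha = 0.05) {
  req <- c("metabolite", "experiment", "condition", "value")
  stopifnot(all(req %in% names(tab)))
  combos <- expand.grid(
    metabolite = unique(tab$metabolite),
    experiment = unique(tab$experiment),
    i = seq_len(nrow(contrasts)),
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    m <- combos$metabolite[k]; e <- combos$experiment[k]
    ct <- contrasts[combos$i[k], ]
    a <- tab$value[tab$metabolite == m & tab$experiment == e &
                     tab$condition == ct$numerator]
    b <- tab$value[tab$metabolite == m & tab$experiment == e &
                     tab$condition == ct$denominator]
    if (!length(a) || !length(b)) return(NULL)
    fc <- metabolite_fc(a, b)
    tt <- if (length(a) >= 2 && length(b) >= 2) welch_t_test(a, b)
          else list(t = NA_real_, df = NA_real_, p_value = NA_real_,
                    flag = "too_few_replicates")
    data.frame(
      metabolite = m, experiment = e, contrast = ct$contrast,
      fold_change = fc$fold_change, t = tt$t, df = tt$df, p = tt$p_value,
      significant = significance_flag(tt$p_value, alpha),
      flag = paste(c(fc$flag, tt$flag)[nzchar(c(fc$flag, tt$flag))],
                   collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no metabolite/contrast combination had data")
  out$n_tests <- sum(!is.na(out$p))
  rownames(out) <- NULL
  out
}
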