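#' Controlled vocabularies for the starvation/resupply design
#'
#' `conditions()` returns the condition tokens an experiment design may use:
#' full nutrition (`FN`), 48 h sulfate starvation (`S_MINUS`), and samples
#' taken 30 minutes (`RESUPPLY_30M`) or 3 hours (`RESUPPLY_3H`) after sulfate
#' was re-supplied to starved cultures, plus the mock-resupply `KCL_CONTROL`.
#' `core_conditions()` drops the mock control; a "complete" design covers the
#' four core conditions in every experiment. `experiments()` returns the two
#' biological replicate experiment labels. `contrasts_table()` enumerates the
#' four ratio contrasts the screen computes, as numerator/denominator
#' condition pairs.
#'
#' @return Character vectors, or for `contrasts_table()` a data.frame with
#'   columns `contrast`, `numerator`, `denominator`.
#' @export
conditions <- function() {
  c("FN", "S_MINUS", "RESUPPLY_30M", "RESUPPLY_3H", "KCL_CONTROL")
}

#' @rdname conditions
#' @export
core_conditions <- function() conditions()[1:4]

#' @rdname conditions
#' @export
experiments <- function() c("EXP1", "EXP2")

#' @rdname conditions
#' @export
contrasts_table <- function() {
  data.frame(
    contrast    = c("S_vs_FN", "R30_vs_S", "R3H_vs_S", "R3H_vs_R30"),
    numerator   = c("S_MINUS", "RESUPPLY_30M", "RESUPPLY_3H", "RESUPPLY_3H"),
    denominator = c("FN", "S_MINUS", "S_MINUS", "RESUPPLY_30M"),
    stringsAsFactors = FALSE
  )
}

resupply_contrasts <- function() c("R30_vs_S", "R3H_vs_S", "R3H_vs_R30")

#' Construct an expression matrix with detection calls
#'
#' Bundles a genes-by-samples matrix of nonnegative linear-scale signals with
#' a same-shaped matrix of detection calls (`"P"` present, `"M"` marginal,
#' `"A"` absent), the per-gene reliability flags that call-aware platforms
#' such as MAS 5.0-processed ATH1 arrays report. Downstream screens use the
#' calls to exclude ratios whose numerator (up-screen) or denominator
#' (down-screen) was never reliably detected.
#'
#' @param signal Numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers). Values must be
#'   nonnegative; `NA` marks a missing measurement.
#' @param call Character matrix of the same shape with values `"P"`, `"M"`
#'   or `"A"` (case-insensitive on input). If `NULL`, every cell defaults to
#'   `"P"` and a warning is issued (call-free matrices are usable but the
#'   call filter then never removes anything).
#' @return An object of class `"expression_matrix"`: a list with elements
#'   `signal` and `call`.
#' @examples
#' sig <- matrix(c(100, 400, 5, 2), 2, 2,
#'               dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' cl  <- matrix(c("P", "P", "A", "A"), 2, 2, dimnames = dimnames(sig))
#' em <- expression_matrix(sig, cl)
#' @export
expression_matrix <- function(signal, call = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix")
  if (is.null(rownames(signal)) || is.null(colnames(signal)))
    stop("`signal` must have gene rownames and sample colnames")
  dup_g <- rownames(signal)[duplicated(rownames(signal))]
  if (length(dup_g))
    stop("duplicate gene identifier(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(signal)[duplicated(colnames(signal))]
  if (length(dup_s))
    stop("duplicate sample identifier(s): ", paste(unique(dup_s), collapse = ", "))
  if (any(signal < 0, na.rm = TRUE))
    stop("negative signal value(s) found; signals must be nonnegative")
  if (is.null(call)) {
    warning("no detection calls supplied; defaulting all calls to 'P'")
    call <- matrix("P", nrow(signal), ncol(signal), dimnames = dimnames(signal))
  }
  if (!is.matrix(call) || !identical(dim(call), dim(signal)))
    stop("`call` must be a character matrix with the same shape as `signal`")
  call[] <- toupper(call)
  bad <- which(!(call %in% c("P", "M", "A")) & !is.na(call), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid detection call '%s' at gene '%s', sample '%s' (must be P/M/A)",
      call[bad[1, 1], bad[1, 2]], rownames(signal)[bad[1, 1]],
      colnames(signal)[bad[1, 2]]
    ))
  }
  dimnames(call) <- dimnames(signal)
  structure(list(signal = signal, call = call), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "expression_matrix: %d genes x %d samples\n",
    nrow(x$signal), ncol(x$signal)
  ))
  tab <- table(factor(x$call, levels = c("P", "M", "A")))
  tot <- sum(tab)
  cat(sprintf(
    "calls: P %.1f%%, M %.1f%%, A %.1f%%\n",
    100 * tab["P"] / tot, 100 * tab["M"] / tot, 100 * tab["A"] / tot
  ))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$signal)

#' Validate a sample design table
#'
#' A sample design maps each array to its biological replicate experiment,
#' its condition, and a replicate index. Token vocabularies are enforced;
#' a design lacking one of the four core conditions in some experiment is
#' accepted but flagged incomplete (attribute `"complete"`), with a warning.
#'
#' @param design data.frame with columns `sample_id`, `experiment`,
#'   `condition`, `replicate`.
#' @return The validated design (classed `"sample_design"`).
#' @export
sample_design <- function(design) {
  req <- c("sample_id", "experiment", "condition", "replicate")
  miss <- setdiff(req, names(design))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  dup <- design$sample_id[duplicated(design$sample_id)]
  if (length(dup))
    stop("duplicate sample_id(s) in design: ", paste(unique(dup), collapse = ", "))
  bad_exp <- setdiff(unique(design$experiment), experiments())
  if (length(bad_exp))
    stop("unknown experiment token(s): ", paste(bad_exp, collapse = ", "))
  bad_cond <- setdiff(unique(design$condition), conditions())
  if (length(bad_cond))
    stop("unknown condition token(s): ", paste(bad_cond, collapse = ", "))
  if (any(!is.finite(design$replicate)) || any(design$replicate < 1))
    stop("replicate indices must be positive integers")
  need <- expand.grid(
    experiment = unique(design$experiment), condition = core_conditions(),
    stringsAsFactors = FALSE
  )
  have <- unique(design[, c("experiment", "condition")])
  key <- function(d) paste(d$experiment, d$condition)
  complete <- all(key(need) %in% key(have))
  if (!complete)
    warning("incomplete design: some (experiment, condition) pairs have no sample")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  attr(design, "complete") <- complete
  class(design) <- c("sample_design", "data.frame")
  design
}
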