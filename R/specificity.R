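#' Does a gene respond to a nutrient starvation at a fold cutoff?
#'
#' Two-sided by default: a linear fold change counts as a response when
#' `fc >= cutoff` or `fc <= 1/cutoff` (equivalently |log2 fc| >= log2
#' cutoff), so down-responses under the other nutrient count as overlap. A
#' one-sided (induction-only) mode is available. Missing fold changes are
#' treated as "no response" in the default lenient mode — external nutrient
#' tables rarely cover every gene — and raise an error under `strict`.
#'
#' @param fc Linear fold change(s), > 0 (vectorised; `NA` allowed when
#'   `strict = FALSE`).
#' @param cutoff Fold cutoff >= 1 (default 2).
#' @param two_sided If `FALSE`, only `fc >= cutoff` counts.
#' @param strict Error on missing values instead of returning `FALSE`.
#' @return Logical vector.
#' @examples
#' responds(2.5)          # TRUE
#' responds(0.4)          # TRUE, down-response counts
#' responds(1.3)          # FALSE
#' @export
responds <- function(fc, cutoff = 2, two_sided = TRUE, strict = FALSE) {
  if (cutoff < 1) stop("cutoff must be >= 1")
  if (any(fc <= 0, na.rm = TRUE)) stop("fold changes must be > 0")
  if (strict && anyNA(fc)) stop("missing fold change under strict mode")
  out <- if (two_sided) fc >= cutoff | fc <= 1 / cutoff else fc >= cutoff
  out[is.na(out)] <- FALSE
  out
}

#' Cross-nutrient specificity category
#'
#' Classifies established sulfate responders by whether they also pass the
#' response cutoff under nitrate and/or phosphate starvation:
#' `S_ONLY` (neither), `S_N` (nitrate only), `S_P` (phosphate only),
#' `S_N_P` (both). The category is a pure function of the two response
#' predicates, so the four categories partition the gene list.
#'
#' @param genes Character vector of sulfate-responsive gene identifiers
#'   (scoping is the screening module's job, not re-thresholding here).
#' @param n_fc,p_fc Named numeric vectors of linear fold changes under
#'   nitrate and phosphate starvation (relative to the nutrient-sufficient
#'   control); looked up by gene identifier, missing genes lenient-default
#'   to no response.
#' @param cutoff Fold cutoff (default 2).
#' @param two_sided,strict Passed to [responds()].
#' @return data.frame with columns `gene_id`, `n_fc`, `p_fc`, `n_responds`,
#'   `p_responds`, `category`.
#' @export
categorize <- function(genes, n_fc, p_fc, cutoff = 2, two_sided = TRUE,
                       strict = FALSE) {
  nv <- unname(n_fc[match(genes, names(n_fc))])
  pv <- unname(p_fc[match(genes, names(p_fc))])
  if (!strict) {
    nmiss <- sum(is.na(nv)) + sum(is.na(pv))
    if (nmiss > 0)
      message(nmiss, " missing nutrient fold change(s) treated as no response")
  }
  nr <- responds(nv, cutoff, two_sided, strict)
  pr <- responds(pv, cutoff, two_sided, strict)
  category <- ifelse(nr & pr, "S_N_P",
              ifelse(nr, "S_N", ifelse(pr, "S_P", "S_ONLY")))
  data.frame(gene_id = genes, n_fc = nv, p_fc = pv,
             n_responds = nr, p_responds = pr, category = category,
             stringsAsFactors = FALSE)
}

#' Specificity summary, overall and restricted to a gene set
#'
#' Tabulates category-by-direction counts over all categorised genes and,
#' when a transcription-factor (or any other) set is supplied, over the
#' genes in that set only. An empty intersection yields zero-count rows,
#' not an error.
#'
#' @param assignments data.frame from [categorize()] with an added
#'   `direction` column (`"UP"`/`"DOWN"`).
#' @param tf_set Optional character vector of gene identifiers to restrict
#'   a second summary to.
#' @return List with `summary` (category x direction counts, `scope`
#'   column `ALL`/`SET`) and `genes` (the per-gene listing, set-restricted
#'   rows flagged in `in_set`).
#' @export
specificity_report <- function(assignments, tf_set = NULL) {
  stopifnot(all(c("gene_id", "category") %in% names(assignments)))
  if (!"direction" %in% names(assignments))
    assignments$direction <- NA_character_
  cats <- c("S_ONLY", "S_N", "S_P", "S_N_P")
  tab_scope <- function(df, scope) {
    if (!nrow(df)) {
      return(data.frame(scope = character(), category = character(),
                        direction = character(), n = integer(),
                        stringsAsFactors = FALSE))
    }
    tb <- as.data.frame(table(
      category = factor(df$category, levels = cats),
      direction = df$direction
    ), stringsAsFactors = FALSE)
    names(tb)[3] <- "n"
    cbind(scope = scope, tb)
  }
  out <- tab_scope(assignments, "ALL")
  genes <- assignments
  genes$in_set <- FALSE
  if (!is.null(tf_set)) {
    sub <- assignments[assignments$gene_id %in% tf_set, , drop = FALSE]
    out <- rbind(out, tab_scope(sub, "SET"))
    genes$in_set <- genes$gene_id %in% tf_set
  }
  list(summary = out, genes = genes)
}
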