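#' Sign pattern of the three resupply contrasts
#'
#' Encodes, for one gene in one experiment, whether each of the resupply
#' ratios 30'S/-S, 3hS/-S and 3hS/30'S is above or below one: `U` for ratio
#' > 1 + epsilon, `D` otherwise (a ratio of exactly 1 maps to `D` at the
#' default `epsilon = 0`, the strict ">1" reading; a dead-zone epsilon is
#' available for noisy data). Because the three ratios derive from one set
#' of condition means, 3hS/-S = (30'S/-S) x (3hS/30'S), so only six of the
#' eight triples can arise; a supplied triple violating that identity (user
#' ratios not coming from shared means) is flagged with a warning. Any `NA`
#' ratio makes the pattern undefined (`NA`), routing the gene to OTHERS.
#'
#' @param r30_vs_s,r3h_vs_s,r3h_vs_r30 Positive ratios (vectorised).
#' @param epsilon Dead-zone half-width (>= 0) around ratio 1.
#' @return Character vector of three-letter tokens over `U`/`D` (e.g.
#'   `"DDD"`), `NA` where any ratio is missing.
#' @examples
#' sign_pattern(0.5, 0.25, 0.5)   # "DDD"
#' sign_pattern(2, 1.5, 0.75)     # "UUD"
#' @export
sign_pattern <- function(r30_vs_s, r3h_vs_s, r3h_vs_r30, epsilon = 0) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  n <- max(length(r30_vs_s), length(r3h_vs_s), length(r3h_vs_r30))
  a <- rep_len(r30_vs_s, n)
  b <- rep_len(r3h_vs_s, n)
  d <- rep_len(r3h_vs_r30, n)
  if (any(c(a, b, d) <= 0, na.rm = TRUE))
    stop("ratios must be > 0")
  ok <- !is.na(a) & !is.na(b) & !is.na(d)
  # multiplicativity check only flags clear violations (user-supplied ratios)
  viol <- ok & abs(b - a * d) > 1e-6 * pmax(abs(b), abs(a * d))
  if (any(viol))
    warning(sum(viol), " ratio triple(s) violate 3hS/-S = (30'S/-S) x ",
            "(3hS/30'S); not derived from shared condition means?")
  arrow <- function(r) ifelse(r > 1 + epsilon, "U", "D")
  out <- rep(NA_character_, n)
  out[ok] <- paste0(arrow(a[ok]), arrow(b[ok]), arrow(d[ok]))
  out
}

#' The six algebraically feasible sign patterns
#'
#' Of the eight U/D triples, `UDU` and `DUD` cannot arise from condition
#' means: if both 30'S/-S and 3hS/30'S exceed one their product 3hS/-S must
#' too (and symmetrically below one). The remaining six are returned in a
#' fixed order.
#'
#' @return Character vector of six pattern tokens.
#' @export
feasible_patterns <- function() {
  all8 <- apply(expand.grid(c("U", "D"), c("U", "D"), c("U", "D")), 1, paste,
                collapse = "")
  feas <- vapply(all8, function(p) {
    s <- strsplit(p, "")[[1]]
    # b must be U when a and d both U; D when both D
    !(s[1] == "U" && s[3] == "U" && s[2] == "D") &&
      !(s[1] == "D" && s[3] == "D" && s[2] == "U")
  }, TRUE)
  sort(all8[feas])
}

#' Default pattern-to-class lookup
#'
#' Maps each feasible sign pattern to a response class label. Class I is
#' anchored: an up-regulated gene whose expression relaxes back down
#' monotonically on resupply (`DDD`) — or a down-regulated gene recovering
#' monotonically (`UUU`) — consistently in both experiments, is a genuine
#' sulfate-status responder. The remaining labels order the patterns by
#' speed of relaxation (earliest reversal toward the pre-starvation level
#' first), ending with the pattern showing no relaxation at all; this
#' ordering is a documented, provisional convention and can be overridden
#' per pattern ([read_class_map()]).
#'
#' For `UP` genes: `DDD` -> I, `DDU` -> II, `UDD` -> III, `UUD` -> IV
#' (still elevated but with a slow tendency to be repressed), `DUU` -> V,
#' `UUU` -> VI (continued induction). For `DOWN` genes the mirror images:
#' `UUU` -> I, `UUD` -> II, `DUU` -> III, `DDU` -> IV, `UDD` -> V,
#' `DDD` -> VI (stays repressed).
#'
#' @param direction `"UP"` or `"DOWN"`.
#' @return Named character vector over the six feasible patterns; total and
#'   injective.
#' @export
default_class_map <- function(direction = c("UP", "DOWN")) {
  direction <- match.arg(direction)
  if (direction == "UP") {
    c(DDD = "I", DDU = "II", UDD = "III", UUD = "IV", DUU = "V", UUU = "VI")
  } else {
    c(UUU = "I", UUD = "II", DUU = "III", DDU = "IV", UDD = "V", DDD = "VI")
  }
}

#' Assign response classes from per-experiment sign patterns
#'
#' A gene receives the mapped class label only when its sign pattern is
#' identical in both experiments; disagreement between experiments, or an
#' undefined pattern in either, routes the gene to `OTHERS` with a recorded
#' reason. This extends the cross-experiment consistency required of class I
#' to every class.
#'
#' @param gene Character vector of gene identifiers.
#' @param pattern_exp1,pattern_exp2 Pattern tokens per experiment (from
#'   [sign_pattern()]), `NA` when undefined.
#' @param direction `"UP"` or `"DOWN"` (selects the default map).
#' @param class_map Named pattern-to-label lookup; defaults to
#'   [default_class_map()].
#' @return data.frame with columns `gene_id`, `direction`, `pattern_exp1`,
#'   `pattern_exp2`, `class_label`, `reason`.
#' @export
assign_class <- function(gene, pattern_exp1, pattern_exp2,
                         direction = c("UP", "DOWN"),
                         class_map = NULL) {
  direction <- match.arg(direction)
  if (is.null(class_map)) class_map <- default_class_map(direction)
  n <- length(gene)
  p1 <- rep_len(pattern_exp1, n)
  p2 <- rep_len(pattern_exp2, n)
  label <- rep("OTHERS", n)
  reason <- rep("", n)
  undef <- is.na(p1) | is.na(p2)
  reason[undef] <- "missing contrast"
  agree <- !undef & p1 == p2
  known <- agree & p1 %in% names(class_map)
  label[known] <- unname(class_map[p1[known]])
  reason[agree & !known] <- "pattern not in class map"
  reason[!undef & !agree] <- "inconsistent between experiments"
  data.frame(
    gene_id = gene, direction = direction,
    pattern_exp1 = p1, pattern_exp2 = p2,
    class_label = label, reason = reason, stringsAsFactors = FALSE
  )
}

#' Classify intersected responders by resupply behaviour
#'
#' For every gene in a responder set's intersection, derives the sign
#' pattern of the three resupply contrasts in each experiment from a long
#' fold-change table and assigns the response class.
#'
#' @param fc_table Output of [fold_change_table()] (must contain the three
#'   resupply contrasts for both experiments).
#' @param responders A `"responder_set"` from [screen_responders()], or a
#'   plain character vector of gene identifiers.
#' @param direction `"UP"` or `"DOWN"`; defaults to the responder set's own
#'   direction.
#' @param epsilon Dead zone for [sign_pattern()].
#' @param class_map Optional pattern-to-label override.
#' @return data.frame as in [assign_class()].
#' @export
classify_responders <- function(fc_table, responders, direction = NULL,
                                epsilon = 0, class_map = NULL) {
  if (inherits(responders, "responder_set")) {
    if (is.null(direction)) direction <- responders$direction
    genes <- responders$intersection
  } else {
    genes <- responders
  }
  if (is.null(direction) || is.na(direction))
    stop("direction must be supplied")
  if (!length(genes)) {
    return(data.frame(gene_id = character(), direction = character(),
                      pattern_exp1 = character(), pattern_exp2 = character(),
                      class_label = character(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  exps <- sort(unique(fc_table$experiment))[1:2]
  pat <- lapply(exps, function(e) {
    get_ratio <- function(ct) {
      sl <- fc_table[fc_table$experiment == e & fc_table$contrast == ct, ]
      sl$ratio[match(genes, sl$gene_id)]
    }
    sign_pattern(get_ratio("R30_vs_S"), get_ratio("R3H_vs_S"),
                 get_ratio("R3H_vs_R30"), epsilon = epsilon)
  })
  assign_class(genes, pat[[1]], pat[[2]], direction, class_map)
}
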