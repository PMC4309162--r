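screen_key <- function(direction, threshold) {
  sprintf("%s_%s", direction, format(threshold, trim = TRUE))
}

#' Run the full starvation/resupply screen
#'
#' The package's central entry point: computes all contrast fold changes,
#' runs the call-filtered responder screens at every configured threshold
#' with replicate intersection, classifies the intersected responders of
#' the classification thresholds by resupply sign pattern, and — when
#' nutrient fold-change tables are supplied — categorises cross-nutrient
#' specificity, optionally summarised over a transcription-factor set.
#' Defaults encode the conventional thresholds: up-screens at more than
#' 5-fold and 2-fold, down-screens below 0.2- and 0.5-fold, classification
#' at the stricter pair, a 2-fold two-sided specificity cutoff.
#'
#' @param expr An [expression_matrix()].
#' @param design A [sample_design()].
#' @param up_thresholds,down_thresholds Screen thresholds (strict
#'   inequalities; up > 1, down < 1).
#' @param classify_at Named numeric `c(UP = , DOWN = )` choosing which
#'   screen feeds classification; must appear in the threshold lists.
#' @param epsilon Dead zone for [sign_pattern()].
#' @param class_map Optional list with elements `UP` and/or `DOWN`
#'   overriding [default_class_map()].
#' @param n_fc,p_fc Optional named nutrient fold-change vectors
#'   ([read_nutrient_fc()]); both required to run the specificity stage.
#' @param cutoff Specificity fold cutoff (default 2).
#' @param tf_set Optional gene-identifier vector for the set-restricted
#'   specificity summary.
#' @param call_filter,floor,aggregate Passed to the screening stage.
#' @return Object of class `"sulfate_screen"`: list with `fold_changes`
#'   (long table), `screens` (named `"responder_set"`s), `venn` (counts
#'   table), `classes` (list `UP`/`DOWN` of class assignments),
#'   `specificity` (or `NULL`), `genes`, `params`.
#' @examples
#' sim <- simulate_experiment(simulation_config(n_genes = 300, seed = 7))
#' res <- sulfate_screen(sim$expression, sim$design,
#'                       n_fc = sim$n_fc, p_fc = sim$p_fc)
#' summary(res)
#' @export
sulfate_screen <- function(expr, design,
                           up_thresholds = c(5, 2),
                           down_thresholds = c(0.2, 0.5),
                           classify_at = c(UP = 5, DOWN = 0.2),
                           epsilon = 0,
                           class_map = NULL,
                           n_fc = NULL, p_fc = NULL, cutoff = 2,
                           tf_set = NULL,
                           call_filter = TRUE, floor = 0,
                           aggregate = "geometric") {
  if (any(up_thresholds <= 1))
    stop("up thresholds must be > 1")
  if (any(down_thresholds >= 1))
    stop("down thresholds must be < 1")
  if (!classify_at["UP"] %in% up_thresholds ||
      !classify_at["DOWN"] %in% down_thresholds)
    stop("classify_at thresholds must appear in the screen threshold lists")
  cmap <- list(UP = default_class_map("UP"), DOWN = default_class_map("DOWN"))
  if (!is.null(class_map)) cmap[names(class_map)] <- class_map

  fc <- fold_change_table(expr, design, floor = floor, aggregate = aggregate)

  screens <- list()
  for (th in up_thresholds)
    screens[[screen_key("UP", th)]] <-
      screen_responders(fc, "UP", th, call_filter)
  for (th in down_thresholds)
    screens[[screen_key("DOWN", th)]] <-
      screen_responders(fc, "DOWN", th, call_filter)

  venn <- do.call(rbind, lapply(names(screens), function(k) {
    s <- screens[[k]]
    data.frame(screen = k, direction = s$direction, threshold = s$threshold,
               t(s$counts), stringsAsFactors = FALSE, check.names = FALSE)
  }))

  classes <- list(
    UP = classify_responders(fc, screens[[screen_key("UP", classify_at["UP"])]],
                             epsilon = epsilon, class_map = cmap$UP),
    DOWN = classify_responders(fc,
                               screens[[screen_key("DOWN",
                                                   classify_at["DOWN"])]],
                               epsilon = epsilon, class_map = cmap$DOWN)
  )

  specificity <- NULL
  if (!is.null(n_fc) && !is.null(p_fc)) {
    scope <- rbind(
      data.frame(gene_id = classes$UP$gene_id, direction = "UP",
                 stringsAsFactors = FALSE),
      data.frame(gene_id = classes$DOWN$gene_id, direction = "DOWN",
                 stringsAsFactors = FALSE)
    )
    if (nrow(scope)) {
      cat_tab <- categorize(scope$gene_id, n_fc, p_fc, cutoff = cutoff)
      cat_tab$direction <- scope$direction
      specificity <- specificity_report(cat_tab, tf_set)
    }
  }

  structure(list(
    fold_changes = fc, screens = screens, venn = venn, classes = classes,
    specificity = specificity, genes = rownames(expr$signal),
    params = list(up_thresholds = up_thresholds,
                  down_thresholds = down_thresholds,
                  classify_at = classify_at, epsilon = epsilon,
                  class_map = cmap, cutoff = cutoff,
                  call_filter = call_filter, floor = floor,
                  aggregate = aggregate)
  ), class = "sulfate_screen")
}

#' @export
print.sulfate_screen <- function(x, ...) {
  cat(sprintf("sulfate_screen: %d genes, %d experiments\n",
              length(x$genes), length(unique(x$fold_changes$experiment))))
  for (k in names(x$screens)) {
    s <- x$screens[[k]]
    cat(sprintf("  %s-screen at %s-fold: intersection %d genes\n",
                s$direction, format(s$threshold), length(s$intersection)))
  }
  invisible(x)
}

#' @export
summary.sulfate_screen <- function(object, ...) {
  cat("Starvation/resupply screen summary\n==================================\n")
  print(object)
  for (d in c("UP", "DOWN")) {
    cl <- object$classes[[d]]
    if (nrow(cl)) {
      cat(sprintf("%s response classes (at %s-fold):\n", d,
                  format(object$params$classify_at[d])))
      print(table(cl$class_label))
    }
  }
  if (!is.null(object$specificity)) {
    cat("specificity categories:\n")
    s <- object$specificity$summary
    print(s[s$scope == "ALL" & s$n > 0, ], row.names = FALSE)
  }
  invisible(object)
}

#' Collect the result tables of a screen for writing
#'
#' Assembles the standard output tables (`fold_changes`, `responders`,
#' `venn_summary`, `response_classes`, and when available `specificity` /
#' `specificity_summary`) from a `"sulfate_screen"` object, in the shape
#' [write_report()] writes.
#'
#' @param result A `"sulfate_screen"` object.
#' @return Named list of data.frames.
#' @export
result_tables <- function(result) {
  stopifnot(inherits(result, "sulfate_screen"))
  resp <- do.call(rbind, lapply(result$screens, function(s) {
    genes <- sort(unique(unlist(s$per_experiment)))
    if (!length(genes)) {
      return(data.frame(gene_id = character(), direction = character(),
                        threshold = numeric(),
                        in_exp1 = logical(), in_exp2 = logical(),
                        in_intersection = logical(),
                        stringsAsFactors = FALSE))
    }
    data.frame(
      gene_id = genes, direction = s$direction, threshold = s$threshold,
      in_exp1 = genes %in% s$per_experiment[[1]],
      in_exp2 = genes %in% s$per_experiment[[2]],
      in_intersection = genes %in% s$intersection,
      stringsAsFactors = FALSE
    )
  }))
  rownames(resp) <- NULL
  tabs <- list(
    fold_changes = result$fold_changes,
    responders = resp,
    venn_summary = result$venn,
    response_classes = rbind(result$classes$UP, result$classes$DOWN)
  )
  if (!is.null(result$specificity)) {
    tabs$specificity <- result$specificity$genes
    tabs$specificity_summary <- result$specificity$summary
  }
  tabs
}

#' Run the pipeline end-to-end from a configuration
#'
#' File-level orchestration: reads the inputs named in the configuration,
#' runs [sulfate_screen()] (and [metabolite_results()] when a metabolite
#' table is configured — stages without inputs are skipped), and writes
#' all result tables plus a manifest with [write_report()]. The in-process
#' API and this path produce identical tables on identical inputs.
#'
#' @param config Either a path to a YAML file or a list with entries:
#'   `expression`, `design` (paths, required), optional `n_fc`, `p_fc`,
#'   `tf_set`, `metabolites`, `class_map_up`, `class_map_down` (paths),
#'   and optional scalars `up_thresholds`, `down_thresholds`,
#'   `classify_up`, `classify_down`, `epsilon`, `cutoff`, `alpha`,
#'   `strict_calls`, `seed`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the `"sulfate_screen"` result, the
#'   metabolite results (or `NULL`) and the written paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (req in c("expression", "design"))
    if (is.null(config[[req]]))
      stop("pipeline config must name an input path for '", req, "'")
  up_th <- as.numeric(config$up_thresholds %||% c(5, 2))
  down_th <- as.numeric(config$down_thresholds %||% c(0.2, 0.5))
  if (any(up_th <= 1) || any(down_th >= 1))
    stop("invalid thresholds in config: up must be > 1, down < 1")
  classify_at <- c(UP = as.numeric(config$classify_up %||% up_th[1]),
                   DOWN = as.numeric(config$classify_down %||% down_th[1]))
  expr <- read_expression_table(config$expression,
                                strict_calls = isTRUE(config$strict_calls))
  design <- read_design(config$design)
  n_fc <- if (!is.null(config$n_fc)) read_nutrient_fc(config$n_fc)
  p_fc <- if (!is.null(config$p_fc)) read_nutrient_fc(config$p_fc)
  tf_set <- if (!is.null(config$tf_set)) {
    sets <- read_gene_set(config$tf_set)
    unique(unlist(sets))
  }
  class_map <- list()
  if (!is.null(config$class_map_up))
    class_map$UP <- read_class_map(config$class_map_up)
  if (!is.null(config$class_map_down))
    class_map$DOWN <- read_class_map(config$class_map_down)
  if (!length(class_map)) class_map <- NULL

  result <- sulfate_screen(
    expr, design, up_thresholds = up_th, down_thresholds = down_th,
    classify_at = classify_at,
    epsilon = as.numeric(config$epsilon %||% 0), class_map = class_map,
    n_fc = n_fc, p_fc = p_fc, cutoff = as.numeric(config$cutoff %||% 2),
    tf_set = tf_set
  )
  tabs <- result_tables(result)

  metab <- NULL
  if (!is.null(config$metabolites)) {
    mt <- read_metabolite_table(config$metabolites)
    metab <- metabolite_results(mt, alpha = as.numeric(config$alpha %||% 0.05))
    tabs$metabolite_results <- metab
  }
  inputs <- unlist(config[intersect(names(config),
                                    c("expression", "design", "n_fc", "p_fc",
                                      "tf_set", "metabolites", "class_map_up",
                                      "class_map_down"))])
  paths <- write_report(tabs, out_dir, config = config,
                        seed = config$seed %||% NULL, inputs = inputs)
  invisible(list(result = result, metabolites = metab, paths = paths))
}
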