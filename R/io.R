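#' Read an expression table with detection calls
#'
#' Two dialects are supported. The `tsv` dialect is the package's native
#' format: a header `gene_id` followed by paired `<sample>_signal` /
#' `<sample>_call` columns, tab-delimited, `"NA"` for missing. The
#' `geo_series_matrix` dialect reads the table block of a GEO series-matrix
#' file (`!`-prefixed metadata lines, a quoted table between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`); series
#' matrices carry signals only, so calls default to `"P"` with a warning,
#' and the `!Sample_*` metadata lines are parsed into a provisional design
#' (attached as attribute `"design"`) with conditions left unassigned.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"geo_series_matrix"`.
#' @param strict_calls If `TRUE`, a file without call columns is an error
#'   instead of defaulting calls to present.
#' @return An [expression_matrix()]. For the GEO dialect, the provisional
#'   sample table is available as `attr(x, "design")`.
#' @export
read_expression_table <- function(path,
                                  dialect = c("tsv", "geo_series_matrix"),
                                  strict_calls = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") read_expr_tsv(path, strict_calls)
  else read_expr_geo(path, strict_calls)
}

read_expr_tsv <- function(path, strict_calls) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = "NA")
  if (names(df)[1] != "gene_id")
    stop("expression table must start with a 'gene_id' column, got '",
         names(df)[1], "'")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  cols <- names(df)[-1]
  sig_cols <- grep("_signal$", cols, value = TRUE)
  call_cols <- grep("_call$", cols, value = TRUE)
  if (!length(sig_cols)) stop("no '<sample>_signal' columns found")
  sids <- sub("_signal$", "", sig_cols)
  sig <- sapply(sig_cols, function(cn) {
    x <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(x) & !is.na(df[[cn]]))
    if (length(bad))
      stop(sprintf("non-numeric signal '%s' at row %d, column '%s'",
                   df[[cn]][bad[1]], bad[1], cn))
    x
  })
  sig <- matrix(sig, nrow = nrow(df),
                dimnames = list(df$gene_id, sids))
  if (any(sig < 0, na.rm = TRUE)) {
    bad <- which(sig < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative signal at gene '%s', sample '%s'",
                 rownames(sig)[bad[1]], colnames(sig)[bad[2]]))
  }
  if (length(call_cols)) {
    have <- sub("_call$", "", call_cols)
    missing_calls <- setdiff(sids, have)
    if (length(missing_calls) && strict_calls)
      stop("missing call column for sample(s): ",
           paste(missing_calls, collapse = ", "))
    call <- matrix("P", nrow(df), length(sids),
                   dimnames = list(df$gene_id, sids))
    for (s in intersect(sids, have)) {
      v <- toupper(df[[paste0(s, "_call")]])
      bad <- which(!(v %in% c("P", "M", "A")) & !is.na(v))
      if (length(bad))
        stop(sprintf("unparseable call token '%s' at row %d, column '%s_call'",
                     df[[paste0(s, "_call")]][bad[1]], bad[1], s))
      call[, s] <- v
    }
    if (length(missing_calls))
      warning("no call column for sample(s) ",
              paste(missing_calls, collapse = ", "), "; defaulting to 'P'")
    expression_matrix(sig, call)
  } else {
    if (strict_calls) stop("no '_call' columns found and strict_calls = TRUE")
    expression_matrix(sig)  # warns about the P default
  }
}

read_expr_geo <- function(path, strict_calls) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^!", lines, value = TRUE)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("no series-matrix table block found in ", path)
  tab <- utils::read.delim(
    text = paste(lines[(beg + 1L):(end - 1L)], collapse = "\n"),
    check.names = FALSE, quote = "\""
  )
  gene_ids <- as.character(tab[[1]])
  sig <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(sig) <- "double"
  rownames(sig) <- gene_ids
  if (strict_calls)
    stop("series-matrix files carry no detection calls and strict_calls = TRUE")
  em <- expression_matrix(sig)  # warns: calls default to P
  # provisional design from !Sample_* metadata; condition/experiment unassigned
  get_meta <- function(key) {
    ln <- grep(paste0("^!", key, "\\b"), meta, value = TRUE)
    if (!length(ln)) return(NULL)
    v <- strsplit(ln[1], "\t")[[1]][-1]
    gsub("^\"|\"$", "", v)
  }
  acc <- get_meta("Sample_geo_accession") %||% colnames(sig)
  ttl <- get_meta("Sample_title") %||% rep(NA_character_, length(acc))
  attr(em, "design") <- data.frame(
    sample_id = acc, title = ttl,
    experiment = NA_character_, condition = NA_character_,
    replicate = NA_integer_, stringsAsFactors = FALSE
  )
  em
}

#' Read a sample design table
#'
#' Tab-delimited with columns `sample_id`, `experiment`, `condition`,
#' `replicate`; tokens are validated against [conditions()] and
#' [experiments()].
#'
#' @param path Path to the TSV file.
#' @return A validated [sample_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, colClasses = c(
    sample_id = "character", experiment = "character",
    condition = "character", replicate = "integer"
  ))
  sample_design(df)
}

#' Read gene sets
#'
#' Either a two-column TSV (`set_name<TAB>gene_id`, with header) or a
#' GMT-like file (one set per line: name, description, then member ids,
#' tab-separated, no header). Duplicate members within a set are collapsed
#' with a warning; an empty set is an error.
#'
#' @param path Path to the file.
#' @param format `"two_column_tsv"` or `"gmt_like"`.
#' @return A named list of character vectors (one element per set).
#' @export
read_gene_set <- function(path, format = c("two_column_tsv", "gmt_like")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sets <- if (format == "two_column_tsv") {
    df <- utils::read.delim(path, colClasses = "character")
    if (ncol(df) < 2) stop("two-column gene-set file needs >= 2 columns")
    split(df[[2]], df[[1]])
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    stats::setNames(
      lapply(parts, function(p) if (length(p) >= 3) p[-(1:2)] else character()),
      vapply(parts, `[`, "", 1L)
    )
  }
  out <- lapply(names(sets), function(nm) {
    m <- sets[[nm]]
    if (!length(m)) stop("gene set '", nm, "' is empty")
    if (anyDuplicated(m)) {
      warning("gene set '", nm, "' contains duplicate identifiers; collapsed")
      m <- unique(m)
    }
    m
  })
  stats::setNames(out, names(sets))
}

#' Read a nutrient starvation fold-change table
#'
#' Per-gene linear-scale fold changes under one nutrient starvation (e.g.
#' nitrate or phosphate) relative to the nutrient-sufficient control, as a
#' two-column TSV `gene_id<TAB>fold_change`.
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of fold changes (> 0).
#' @export
read_nutrient_fc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path)
  if (!all(c("gene_id", "fold_change") %in% names(df)))
    stop("nutrient fold-change table needs columns gene_id, fold_change")
  fc <- as.numeric(df$fold_change)
  if (any(fc <= 0, na.rm = TRUE))
    stop("fold changes must be > 0")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in nutrient fold-change table")
  stats::setNames(fc, df$gene_id)
}

#' Read a long-format metabolite replicate table
#'
#' Columns: `metabolite`, `experiment`, `condition`, `replicate`, `value`.
#'
#' @param path Path to the TSV file.
#' @return data.frame in the same long format.
#' @export
read_metabolite_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path)
  req <- c("metabolite", "experiment", "condition", "replicate", "value")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("metabolite table missing column(s): ", paste(miss, collapse = ", "))
  df$value <- as.numeric(df$value)
  df
}

#' Read a class-map override table
#'
#' TSV with columns `pattern` (three-letter token over U/D, e.g. `DDD`) and
#' `class_label`, overriding the shipped pattern-to-class lookup.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping pattern tokens to labels.
#' @export
read_class_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("pattern", "class_label") %in% names(df)))
    stop("class map needs columns pattern, class_label")
  stats::setNames(df$class_label, df$pattern)
}

#' Write result tables and a run manifest
#'
#' Writes each table as a deterministic, byte-stable TSV: fixed column
#' order as given, numeric columns formatted to 6 significant digits, rows
#' sorted by `gene_id` when that column is present, `"NA"` for missing. A
#' `manifest.json` records the package version, configuration, seed and
#' md5 checksums of the declared input files. Writing the same tables twice
#' yields byte-identical files.
#'
#' @param tables Named list of data.frames; names become `<name>.tsv`.
#' @param out_dir Output directory (created if needed).
#' @param config List of configuration values recorded in the manifest.
#' @param seed Integer seed recorded verbatim in the manifest (or `NULL`).
#' @param inputs Character vector of input file paths to checksum.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(tables, out_dir, config = list(), seed = NULL,
                         inputs = character()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  if (file.access(out_dir, 2) != 0) stop("directory not writable: ", out_dir)
  stopifnot(is.list(tables), !is.null(names(tables)))
  paths <- character()
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]], stringsAsFactors = FALSE)
    if ("gene_id" %in% names(tab) && nrow(tab))
      tab <- tab[order(tab$gene_id), , drop = FALSE]
    for (j in seq_along(tab)) {
      if (is.numeric(tab[[j]]) && !is.integer(tab[[j]]))
        tab[[j]] <- fmt_num(tab[[j]])
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA", eol = "\n")
    paths <- c(paths, p)
  }
  checksums <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else {
    stats::setNames(list(), character())
  }
  manifest <- list(
    package = "sulfateScreen",
    version = as.character(utils::packageVersion("sulfateScreen")),
    seed = seed,
    config = config,
    input_md5 = checksums,
    tables = names(tables)
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(paths, mp))
}

#' Write an expression matrix in the native TSV dialect
#'
#' Inverse of [read_expression_table()]'s `tsv` dialect: signals to 6
#' significant digits, calls verbatim, rows sorted by gene identifier.
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  ord <- order(rownames(em$signal))
  sig <- em$signal[ord, , drop = FALSE]
  cl <- em$call[ord, , drop = FALSE]
  out <- data.frame(gene_id = rownames(sig), stringsAsFactors = FALSE)
  for (s in colnames(sig)) {
    out[[paste0(s, "_signal")]] <- fmt_num(sig[, s])
    out[[paste0(s, "_call")]] <- cl[, s]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", eol = "\n")
  invisible(path)
}
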