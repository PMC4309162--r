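# internal helpers shared across modules

#' @keywords internal
#' @noRd
geomean <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  # exp(mean(log)) maps any zero to a zero mean, which is the desired limit
  exp(mean(log(x)))
}

# format a numeric column to 6 significant digits as a character vector,
# byte-stable across runs; NA stays "NA"
fmt_num <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- "NA"
  out
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
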