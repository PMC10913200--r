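# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(...) stop(..., call. = FALSE)

#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Row variances of a numeric matrix (denominator n - 1).
#' @noRd
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

#' Exact two-group permutation p-value on the absolute difference of means.
#' Used as the fallback when both groups have zero within-group variance but
#' unequal means, where the Welch statistic is undefined.
#' @noRd
perm_p_two_group <- function(values, n_a) {
  n <- length(values)
  obs <- abs(mean(values[seq_len(n_a)]) - mean(values[-seq_len(n_a)]))
  splits <- utils::combn(n, n_a)
  tot <- sum(values)
  stat <- apply(splits, 2L, function(idx) {
    ma <- mean(values[idx])
    mb <- (tot - sum(values[idx])) / (n - n_a)
    abs(ma - mb)
  })
  mean(stat >= obs - 1e-12)
}

#' Read a TSV table, skipping "#"-prefixed provenance/comment lines.
#' @noRd
read_tsv_checked <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Parse a character vector as numeric, reporting the offending row/column.
#' @noRd
parse_numeric_column <- function(x, column, what = "value") {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(is.na(x) | x == ""))
  if (length(bad)) {
    abort(sprintf("malformed numeric %s '%s' at row %d, column '%s'",
                  what, x[bad[1L]], bad[1L], column))
  }
  out
}

package_version_string <- function() {
  as.character(utils::packageVersion("triadex"))
}

#' Provenance header written at the top of every output table.
#' @noRd
provenance_line <- function(command, seed = NULL) {
  seed_part <- if (is.null(seed)) "" else sprintf(" seed=%s", seed)
  sprintf("#triadex %s %s%s", package_version_string(), command, seed_part)
}
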