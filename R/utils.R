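# Internal helpers shared across modules.

dx_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dauerx_error")))
}

dx_format_error <- function(msg) dx_error(msg, "dauerx_format_error")
dx_validation_error <- function(msg) dx_error(msg, "dauerx_validation_error")

#' Weighted median
#'
#' Median of `x` under non-negative weights `w`: the smallest `x` whose
#' cumulative weight reaches half the total. Zero-weight values are ignored.
#'
#' @param x numeric vector.
#' @param w non-negative weights, recycled to `length(x)`.
#' @return A single numeric value (`NA` if no positive weight).
#' @keywords internal
weighted_median <- function(x, w = rep(1, length(x))) {
  w <- rep_len(w, length(x))
  keep <- is.finite(x) & w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  # symmetric rule: average the two straddling values at exactly 0.5
  i <- which(cw >= 0.5)[1L]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1L]) / 2 else x[i]
}

# read a TSV with '#' comments; header optional
dx_read_tsv <- function(path, header) {
  if (!file.exists(path)) dx_format_error(sprintf("file not found: %s", path))
  utils::read.delim(path, header = header, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    blank.lines.skip = TRUE, quote = "")
}

dx_write_tsv <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names)
}

# deterministic child seed for pipeline stages; kept < 2^31
dx_child_seed <- function(seed, stage_index) {
  (as.integer(seed) + 1000L * as.integer(stage_index)) %% .Machine$integer.max
}
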