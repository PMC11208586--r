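# Shared argument / coordinate validation helpers.
#
# All genomic coordinates inside the package are 0-based, half-open
# [start, end): BED-family files are read as-is, GTF is converted from
# 1-based inclusive on input. Every data frame of intervals crossing a
# module boundary goes through check_intervals().

#' Validate 0-based half-open interval columns
#'
#' Asserts the package-wide coordinate convention (`start >= 0`,
#' `end > start`, non-empty `chrom`) on a data frame of intervals.
#' Called at module boundaries; returns its input invisibly.
#'
#' @param df data frame holding interval columns.
#' @param chrom,start,end column names to check.
#' @param what label used in error messages.
#' @return `df`, invisibly.
#' @keywords internal
check_intervals <- function(df, chrom = "chrom", start = "start", end = "end",
                            what = "interval") {
  missing_cols <- setdiff(c(chrom, start, end), names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s table lacks column(s): %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  ch <- df[[chrom]]
  s <- df[[start]]
  e <- df[[end]]
  bad <- which(is.na(ch) | !nzchar(as.character(ch)) |
                 is.na(s) | is.na(e) | s < 0 | e <= s)
  if (length(bad) > 0L) {
    stop(sprintf(
      "%s violates the 0-based half-open convention at row(s) %s (need start >= 0, end > start, non-empty chrom)",
      what, paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# scalar checks used across modules
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stopf("'%s' must be a single number in [%s, %s]", name,
          format(lower), format(upper))
  }
  invisible(x)
}
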