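# BEDPE-style loop I/O.
#
# Loop files are tab-separated with six coordinate columns (anchor A,
# anchor B), a name, a read count and an FDR. hichipper-style outputs
# shuffle the extra columns, so the count/FDR positions are configurable
# through a dialect object.

#' Column dialect for BEDPE loop files
#'
#' Describes which 1-based columns of a tab-separated loop file carry
#' each field. The default matches plain BEDPE with `name`, `read count`
#' and `FDR` in columns 7-9.
#'
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b coordinate columns.
#' @param name name column (may be `NA` for files without one).
#' @param read_count,fdr support and significance columns.
#' @return A named list of class `loop_dialect`.
#' @examples
#' loop_dialect(read_count = 8, fdr = 9)
#' @export
loop_dialect <- function(chrom_a = 1L, start_a = 2L, end_a = 3L,
                         chrom_b = 4L, start_b = 5L, end_b = 6L,
                         name = 7L, read_count = 8L, fdr = 9L) {
  d <- list(chrom_a = chrom_a, start_a = start_a, end_a = end_a,
            chrom_b = chrom_b, start_b = start_b, end_b = end_b,
            name = name, read_count = read_count, fdr = fdr)
  idx <- unlist(d[!is.na(unlist(d))])
  if (any(idx < 1L) || anyDuplicated(idx) > 0L) {
    stopf("loop dialect columns must be distinct positive indices")
  }
  structure(d, class = "loop_dialect")
}

#' Read chromatin loops from a BEDPE-like file
#'
#' Reads a tab-separated loop file, validates every record (coordinates
#' 0-based half-open, read count a non-negative integer, FDR in
#' \[0, 1\]) and normalizes intra-chromosomal anchor order so that
#' anchor A starts at or before anchor B. Malformed lines are reported
#' with their line numbers.
#'
#' @param path file path.
#' @param dialect a [loop_dialect()] describing the column layout.
#' @param assay assay label attached to every loop (e.g. `"H3K27Ac"`,
#'   `"METTL3"`).
#' @param condition condition label (e.g. `"growing"`, `"senescent"`).
#' @return A data frame with columns `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, `name`, `read_count`, `fdr`,
#'   `assay`, `condition`.
#' @seealso [write_loops()]
#' @export
read_loops <- function(path, dialect = loop_dialect(), assay = NA_character_,
                       condition = NA_character_) {
  if (!file.exists(path)) stopf("loop file not found: %s", path)
  stopifnot(inherits(dialect, "loop_dialect"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track\\b)", lines)]
  empty <- empty_loop_frame(assay, condition)
  if (length(lines) == 0L || all(!nzchar(lines))) {
    warnf("loop file '%s' is empty", path)
    return(empty)
  }
  keep <- nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  need <- max(unlist(dialect), na.rm = TRUE)
  nf <- lengths(fields)
  if (any(nf < need)) {
    stopf("line %d of '%s' has %d tab-separated fields; dialect needs >= %d",
          lineno[which(nf < need)[1L]], path, min(nf), need)
  }
  col <- function(j) vapply(fields, `[[`, character(1L), j)
  num <- function(j, label) {
    v <- suppressWarnings(as.numeric(col(j)))
    if (anyNA(v)) {
      stopf("line %d of '%s': non-numeric %s field '%s'",
            lineno[which(is.na(v))[1L]], path, label, col(j)[which(is.na(v))[1L]])
    }
    v
  }
  out <- data.frame(
    chrom_a = col(dialect$chrom_a),
    start_a = num(dialect$start_a, "start_a"),
    end_a = num(dialect$end_a, "end_a"),
    chrom_b = col(dialect$chrom_b),
    start_b = num(dialect$start_b, "start_b"),
    end_b = num(dialect$end_b, "end_b"),
    name = if (is.na(dialect$name)) "." else col(dialect$name),
    read_count = num(dialect$read_count, "read_count"),
    fdr = num(dialect$fdr, "fdr"),
    stringsAsFactors = FALSE
  )
  bad <- which(out$start_a < 0 | out$start_b < 0 |
                 out$end_a <= out$start_a | out$end_b <= out$start_b)
  if (length(bad) > 0L) {
    stopf("line %d of '%s': anchor coordinates violate 0-based half-open convention",
          lineno[bad[1L]], path)
  }
  bad <- which(out$fdr < 0 | out$fdr > 1)
  if (length(bad) > 0L) {
    stopf("line %d of '%s': FDR %.4g outside [0, 1]", lineno[bad[1L]], path,
          out$fdr[bad[1L]])
  }
  bad <- which(out$read_count < 0 | out$read_count != round(out$read_count))
  if (length(bad) > 0L) {
    stopf("line %d of '%s': read count must be a non-negative integer",
          lineno[bad[1L]], path)
  }
  out$read_count <- as.integer(out$read_count)
  # canonical intra-chromosomal orientation: anchor A first on the chromosome
  swap <- out$chrom_a == out$chrom_b & out$start_a > out$start_b
  if (any(swap)) {
    tmp <- out[swap, c("start_a", "end_a")]
    out[swap, c("start_a", "end_a")] <- out[swap, c("start_b", "end_b")]
    out[swap, c("start_b", "end_b")] <- tmp
  }
  out$assay <- assay
  out$condition <- condition
  check_intervals(out, "chrom_a", "start_a", "end_a", what = "loop anchor A")
  check_intervals(out, "chrom_b", "start_b", "end_b", what = "loop anchor B")
  out
}

empty_loop_frame <- function(assay = NA_character_, condition = NA_character_) {
  data.frame(chrom_a = character(), start_a = numeric(), end_a = numeric(),
             chrom_b = character(), start_b = numeric(), end_b = numeric(),
             name = character(), read_count = integer(), fdr = numeric(),
             assay = character(), condition = character(),
             stringsAsFactors = FALSE)
}

#' Write loops to a BEDPE file
#'
#' Emits the nine canonical columns (anchor A, anchor B, name, read
#' count, FDR), tab-separated with LF line endings, in a fixed order so
#' output is byte-deterministic.
#'
#' @param loops loop data frame as returned by [read_loops()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loops <- function(loops, path) {
  cols <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
            "name", "read_count", "fdr")
  missing_cols <- setdiff(cols, names(loops))
  if (length(missing_cols) > 0L) {
    stopf("loop table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  out <- loops[, cols, drop = FALSE]
  out$start_a <- format_coord(out$start_a)
  out$end_a <- format_coord(out$end_a)
  out$start_b <- format_coord(out$start_b)
  out$end_b <- format_coord(out$end_b)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, eol = "\n")
  invisible(path)
}

# integer-valued coordinates without scientific notation
format_coord <- function(x) formatC(x, format = "d")
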