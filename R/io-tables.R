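# Schema-validated CSV/TSV tables.
#
# Expression tables, m6A peak tables, isotopologue tables and Ct tables
# all flow through read_table() so that a missing column or a
# non-numeric cell fails loudly at the boundary instead of deep inside
# an analysis.

#' Ready-made column schemas
#'
#' Named character vectors mapping column name to type
#' (`"character"`, `"integer"` or `"numeric"`), for use with
#' [read_table()].
#'
#' @format NULL
#' @name table_schemas
NULL

#' @rdname table_schemas
#' @export
schema_expression <- c(gene_id = "character", contrast = "character",
                       score = "numeric", log_fc = "numeric", padj = "numeric")

#' @rdname table_schemas
#' @export
schema_m6a_peaks <- c(transcript_id = "character", start = "numeric",
                      end = "numeric", signal = "numeric")

#' @rdname table_schemas
#' @export
schema_ct <- c(sample = "character", target = "character",
               target_ct = "numeric", reference_ct = "numeric")

#' Read a delimited table against a declared schema
#'
#' The header must contain every schema column; extra columns are kept
#' as read. Schema columns are coerced to their declared types and any
#' cell that fails coercion is reported with its column and row.
#'
#' @param path CSV (default) or TSV path.
#' @param schema named character vector, column name -> type, e.g.
#'   [schema_expression].
#' @param sep field separator, `","` or `"\t"`.
#' @return A data frame with typed columns; row count equals the file's
#'   data-row count.
#' @seealso [write_table()]
#' @export
read_table <- function(path, schema, sep = ",") {
  if (!file.exists(path)) stopf("table not found: %s", path)
  stopifnot(is.character(schema), !is.null(names(schema)))
  tab <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "")
  missing_cols <- setdiff(names(schema), names(tab))
  if (length(missing_cols) > 0L) {
    stopf("table '%s' is missing required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type %in% c("numeric", "integer", "double")) {
      v <- suppressWarnings(as.numeric(tab[[col]]))
      bad <- which(is.na(v) & !is.na(tab[[col]]) &
                     !tab[[col]] %in% c("NA", ""))
      if (length(bad) > 0L) {
        stopf("table '%s', column '%s': non-numeric value '%s' at data row %d",
              path, col, tab[[col]][bad[1L]], bad[1L])
      }
      tab[[col]] <- if (type == "integer") as.integer(v) else v
    } else {
      tab[[col]] <- as.character(tab[[col]])
    }
  }
  tab
}

#' Write a table deterministically
#'
#' CSV with a header, no row names, no quoting of numerics, LF line
#' endings — byte-stable for identical input.
#'
#' @param tab data frame.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_table <- function(tab, path, sep = ",") {
  write.table(tab, path, sep = sep, quote = TRUE, row.names = FALSE,
              col.names = TRUE, eol = "\n", qmethod = "double")
  invisible(path)
}
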