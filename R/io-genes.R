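# Gene model I/O: BED12 and GTF readers producing a gene_catalog.
#
# A gene_catalog is the coordinate frame for promoter windows and for
# assigning m6A peaks to 5'UTR/CDS/3'UTR segments. Coordinates are
# 0-based half-open; the TSS of a + strand gene is its start, of a -
# strand gene its last base (end - 1).

REGION_LEVELS <- c("5'UTR", "CDS", "3'UTR")

new_gene_catalog <- function(genes, regions) {
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  rownames(regions) <- NULL
  check_intervals(genes, what = "gene span")
  if (nrow(regions) > 0L) {
    check_intervals(regions, what = "gene region")
    bad <- setdiff(unique(regions$region), REGION_LEVELS)
    if (length(bad) > 0L) {
      stopf("unknown region label(s): %s", paste(bad, collapse = ", "))
    }
  }
  structure(list(genes = genes, regions = regions), class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("<gene_catalog> %d genes on %d chromosome(s), %d region segments\n",
              nrow(x$genes), length(unique(x$genes$chrom)), nrow(x$regions)))
  invisible(x)
}

#' Read gene models from BED12 or GTF
#'
#' Builds a gene catalog giving, per gene, the span, strand, TSS and the
#' 5'UTR/CDS/3'UTR segments. BED12 thickStart/thickEnd delimit the CDS;
#' the UTR side is chosen from the strand. GTF coordinates (1-based
#' inclusive) are converted to the internal 0-based half-open
#' convention; region features are taken from `five_prime_utr`/`5UTR`,
#' `CDS` and `three_prime_utr`/`3UTR` records.
#'
#' @param path file path.
#' @param format `"bed12"` or `"gtf"` (must be stated explicitly).
#' @return An object of class `gene_catalog`: a list with
#'   `genes` (`gene_id`, `chrom`, `strand`, `start`, `end`, `tss`) and
#'   `regions` (`gene_id`, `chrom`, `region`, `start`, `end`).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t600\tgeneA\t0\t+\t200\t500\t0\t1\t500\t0", bed)
#' read_gene_models(bed, "bed12")$genes$tss  # + strand: TSS = start
#' @export
read_gene_models <- function(path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("gene model file not found: %s", path)
  cat_ <- switch(format,
                 bed12 = read_gene_models_bed12(path),
                 gtf = read_gene_models_gtf(path))
  check_duplicate_genes(cat_$genes)
  cat_
}

check_duplicate_genes <- function(genes) {
  dup_ids <- unique(genes$gene_id[duplicated(genes$gene_id)])
  offenders <- character()
  for (id in dup_ids) {
    g <- genes[genes$gene_id == id, , drop = FALSE]
    for (ch in unique(g$chrom)) {
      gc <- g[g$chrom == ch, , drop = FALSE]
      if (nrow(gc) < 2L) next
      o <- order(gc$start)
      if (any(gc$start[o][-1L] < gc$end[o][-nrow(gc)])) offenders <- c(offenders, id)
    }
  }
  if (length(offenders) > 0L) {
    stopf("overlapping duplicate gene_id(s): %s",
          paste(unique(offenders), collapse = ", "))
  }
  if (length(dup_ids) > 0L) {
    warnf("duplicate (non-overlapping) gene_id(s): %s",
          paste(dup_ids, collapse = ", "))
  }
  invisible(genes)
}

read_gene_models_bed12 <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "")
  if (ncol(tab) < 12L) stopf("BED12 file '%s' has %d columns; 12 required", path, ncol(tab))
  names(tab)[1:12] <- c("chrom", "start", "end", "name", "score", "strand",
                        "thick_start", "thick_end", "rgb", "block_count",
                        "block_sizes", "block_starts")
  if (!all(tab$strand %in% c("+", "-"))) {
    stopf("unknown strand character '%s' in '%s' (must be + or -)",
          setdiff(tab$strand, c("+", "-"))[1L], path)
  }
  genes <- data.frame(gene_id = tab$name, chrom = tab$chrom, strand = tab$strand,
                      start = tab$start, end = tab$end,
                      tss = ifelse(tab$strand == "+", tab$start, tab$end - 1L),
                      stringsAsFactors = FALSE)
  regions <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    sizes <- as.numeric(strsplit(as.character(tab$block_sizes[i]), ",")[[1]])
    offs <- as.numeric(strsplit(as.character(tab$block_starts[i]), ",")[[1]])
    exon_s <- tab$start[i] + offs
    exon_e <- exon_s + sizes
    ts <- tab$thick_start[i]
    te <- tab$thick_end[i]
    if (te <= ts) next  # non-coding entry: no CDS/UTR segments
    seg <- rbind(
      clip_segments(exon_s, exon_e, tab$start[i], ts,
                    if (tab$strand[i] == "+") "5'UTR" else "3'UTR"),
      clip_segments(exon_s, exon_e, ts, te, "CDS"),
      clip_segments(exon_s, exon_e, te, tab$end[i],
                    if (tab$strand[i] == "+") "3'UTR" else "5'UTR"))
    if (is.null(seg) || nrow(seg) == 0L) next
    seg$gene_id <- tab$name[i]
    seg$chrom <- tab$chrom[i]
    regions[[i]] <- seg
  }
  regions <- do.call(rbind, regions)
  if (is.null(regions)) {
    regions <- data.frame(region = character(), start = numeric(), end = numeric(),
                          gene_id = character(), chrom = character(),
                          stringsAsFactors = FALSE)
  }
  new_gene_catalog(genes, regions[, c("gene_id", "chrom", "region", "start", "end")])
}

# intersect exon blocks with a window, labelling the surviving pieces
clip_segments <- function(exon_s, exon_e, lo, hi, label) {
  s <- pmax(exon_s, lo)
  e <- pmin(exon_e, hi)
  keep <- e > s
  if (!any(keep)) return(NULL)
  data.frame(region = label, start = s[keep], end = e[keep],
             stringsAsFactors = FALSE)
}

read_gene_models_gtf <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "gtf"))
  if (!"gene_id" %in% names(gr)) {
    stopf("GTF '%s' lacks a gene_id attribute", path)
  }
  strand_chr <- as.character(gr$strand)
  if (any(strand_chr == "*")) {
    stopf("unknown strand character '*' in GTF '%s'", path)
  }
  df <- data.frame(gene_id = gr$gene_id,
                   chrom = as.character(gr$seqnames),
                   strand = strand_chr,
                   start = gr$start - 1L,  # to 0-based half-open
                   end = gr$end,
                   type = as.character(gr$type),
                   stringsAsFactors = FALSE)
  span <- do.call(rbind, lapply(split(df, df$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L], strand = g$strand[1L],
               start = min(g$start), end = max(g$end), stringsAsFactors = FALSE)
  }))
  span$tss <- ifelse(span$strand == "+", span$start, span$end - 1L)
  type_map <- c(five_prime_utr = "5'UTR", `5UTR` = "5'UTR",
                five_prime_UTR = "5'UTR", CDS = "CDS",
                three_prime_utr = "3'UTR", `3UTR` = "3'UTR",
                three_prime_UTR = "3'UTR")
  reg <- df[df$type %in% names(type_map), , drop = FALSE]
  regions <- data.frame(gene_id = reg$gene_id, chrom = reg$chrom,
                        region = unname(type_map[reg$type]),
                        start = reg$start, end = reg$end,
                        stringsAsFactors = FALSE)
  new_gene_catalog(span, regions)
}
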