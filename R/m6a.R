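# m6A polymethylation: unique-site counting, polymethylated-transcript
# classification, and intersection with downregulated transcripts.

#' Count unique m6A sites per transcript
#'
#' Peaks are grouped by transcript; overlapping peaks on the same
#' transcript are merged into a single site whose signal is the maximum
#' of its members (this avoids double-counting summit-split peaks).
#' Each merged site is assigned to the transcript region (5'UTR, CDS,
#' 3'UTR) containing its midpoint; a site whose midpoint falls in no
#' annotated region keeps an `NA` region but still counts. Peaks on
#' transcripts absent from the catalog are skipped with a warning.
#'
#' @param peaks data frame with `transcript_id`, `start`, `end`,
#'   `signal` (coordinates in the same frame as the catalog regions).
#' @param catalog `gene_catalog` whose `gene_id`s are transcript ids.
#' @return Data frame of merged sites: `transcript_id`, `start`, `end`,
#'   `signal`, `region`.
#' @export
count_unique_sites <- function(peaks, catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  check_intervals(cbind(peaks, chrom = "x"), "chrom", "start", "end",
                  what = "m6A peak")
  if (any(peaks$signal < 0)) stopf("negative m6A peak signal")
  known <- peaks$transcript_id %in% catalog$genes$gene_id
  if (any(!known)) {
    warnf("skipping %d peak(s) on transcript(s) absent from the catalog: %s",
          sum(!known),
          paste(utils::head(unique(peaks$transcript_id[!known]), 5L),
                collapse = ", "))
    peaks <- peaks[known, , drop = FALSE]
  }
  if (nrow(peaks) == 0L) {
    return(data.frame(transcript_id = character(), start = numeric(),
                      end = numeric(), signal = numeric(),
                      region = character(), stringsAsFactors = FALSE))
  }
  out <- lapply(split(peaks, peaks$transcript_id), function(p) {
    ir <- IRanges::IRanges(start = p$start + 1L, end = p$end)
    merged <- IRanges::reduce(ir, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(merged)$revmap
    data.frame(
      transcript_id = p$transcript_id[1L],
      start = IRanges::start(merged) - 1L,
      end = IRanges::end(merged),
      signal = vapply(revmap, function(i) max(p$signal[i]), numeric(1L)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  mid <- (out$start + out$end) / 2
  out$region <- NA_character_
  reg <- catalog$regions
  for (i in seq_len(nrow(out))) {
    r <- reg[reg$gene_id == out$transcript_id[i] &
               reg$start <= mid[i] & mid[i] < reg$end, , drop = FALSE]
    if (nrow(r) > 0L) out$region[i] <- r$region[1L]
  }
  out[order(out$transcript_id, out$start), , drop = FALSE]
}

#' Classify transcripts as polymethylated
#'
#' A transcript is polymethylated when it carries strictly more than
#' `min_sites_exclusive` merged m6A sites (default: more than three).
#' The representative signal is the highest site signal on the
#' transcript.
#'
#' @param sites merged site table from [count_unique_sites()].
#' @param min_sites_exclusive exclusive site-count threshold (default 3).
#' @param all_transcripts optional character vector of transcript ids to
#'   report even with zero sites.
#' @return Data frame with `transcript_id`, `site_count`,
#'   `is_polymethylated`, `representative_signal` (`NA` when no sites).
#' @export
classify_polymethylated <- function(sites, min_sites_exclusive = 3L,
                                    all_transcripts = NULL) {
  assert_scalar_number(min_sites_exclusive, "min_sites_exclusive", lower = 0)
  ids <- unique(c(sites$transcript_id, all_transcripts))
  counts <- table(factor(sites$transcript_id, levels = ids))
  rep_sig <- vapply(ids, function(id) {
    s <- sites$signal[sites$transcript_id == id]
    if (length(s) == 0L) NA_real_ else max(s)
  }, numeric(1L))
  out <- data.frame(transcript_id = ids,
                    site_count = as.integer(counts),
                    is_polymethylated = as.integer(counts) > min_sites_exclusive,
                    representative_signal = unname(rep_sig),
                    stringsAsFactors = FALSE)
  out[order(out$transcript_id), , drop = FALSE]
}

#' Intersect polymethylated transcripts with downregulated ones
#'
#' Keeps polymethylated transcripts that are significantly
#' downregulated in the senescent-vs-growing contrast
#' (`log_fc <= -down_lfc` and `padj < alpha`). Called transcripts with
#' no expression record are excluded with a warning.
#'
#' @param calls classification table from [classify_polymethylated()].
#' @param expression data frame with `gene_id`, `log_fc`, `padj`
#'   (a single contrast).
#' @param down_lfc,alpha thresholds (defaults 1 and 0.05).
#' @return Character vector of transcript ids, sorted.
#' @export
intersect_downregulated <- function(calls, expression, down_lfc = 1,
                                    alpha = 0.05) {
  poly <- calls$transcript_id[calls$is_polymethylated]
  idx <- match(poly, expression$gene_id)
  if (anyNA(idx)) {
    warnf("excluding %d polymethylated transcript(s) without expression records",
          sum(is.na(idx)))
    poly <- poly[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  keep <- expression$log_fc[idx] <= -down_lfc & expression$padj[idx] < alpha
  sort(poly[keep])
}
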