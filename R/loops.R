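# Loop-level analytics: significance filtering, distance classes,
# promoter windows, enhancer-promoter (EP) assignment and per-gene EP
# counting.

#' Filter loops by assay-specific significance rules
#'
#' H3K27Ac HiChIP loops are kept when `fdr < 0.01` with at least 4
#' supporting reads; METTL3 HiChIP loops when `fdr < 0.05` with no read
#' floor. Both thresholds can be overridden.
#'
#' @param loops loop data frame ([read_loops()]).
#' @param assay `"H3K27Ac"` or `"METTL3"`; every loop's own `assay`
#'   label (when present and non-NA) must match.
#' @param fdr,min_reads optional overrides of the assay defaults.
#' @return The subset of `loops` passing the rule.
#' @examples
#' loops <- data.frame(chrom_a = "chr1", start_a = 0, end_a = 100,
#'                     chrom_b = "chr1", start_b = 5000, end_b = 5100,
#'                     name = ".", read_count = c(4L, 3L), fdr = 0.005,
#'                     assay = "H3K27Ac", condition = "growing")
#' nrow(filter_significant_loops(loops, "H3K27Ac"))  # 1: read floor drops one
#' @export
filter_significant_loops <- function(loops, assay = c("H3K27Ac", "METTL3"),
                                     fdr = NULL, min_reads = NULL) {
  assay <- match.arg(assay)
  if ("assay" %in% names(loops)) {
    lab <- loops$assay[!is.na(loops$assay)]
    if (length(lab) > 0L && !all(lab == assay)) {
      stopf("loop table carries assay label(s) %s but '%s' was requested",
            paste(unique(setdiff(lab, assay)), collapse = ", "), assay)
    }
  }
  if (is.null(fdr)) fdr <- switch(assay, H3K27Ac = 0.01, METTL3 = 0.05)
  if (is.null(min_reads)) min_reads <- switch(assay, H3K27Ac = 4L, METTL3 = 0L)
  assert_scalar_number(fdr, "fdr", 0, 1)
  keep <- loops$fdr < fdr & loops$read_count >= min_reads
  loops[keep, , drop = FALSE]
}

#' Classify loops into distance categories
#'
#' Intra-chromosomal loops are classified by the separation of anchor
#' midpoints `d`: short (`d < 5 kb`), medium (`5 kb <= d <= 2 Mb`,
#' closed on both ends) or long (`d > 2 Mb`); inter-chromosomal loops
#' are `trans`. The three intra classes form an exact partition.
#'
#' @param loops loop data frame.
#' @return Character vector, one of `"short"`, `"medium"`, `"long"`,
#'   `"trans"` per loop.
#' @export
classify_distance <- function(loops) {
  if (nrow(loops) == 0L) return(character())
  mid_a <- (loops$start_a + loops$end_a) / 2
  mid_b <- (loops$start_b + loops$end_b) / 2
  d <- abs(mid_b - mid_a)
  cls <- ifelse(loops$chrom_a != loops$chrom_b, "trans",
                ifelse(d < 5e3, "short",
                       ifelse(d <= 2e6, "medium", "long")))
  cls
}

#' Tally loop distance classes per condition
#'
#' @param loops loop data frame (already significance-filtered).
#' @return Data frame with `condition`, `class`, `count`, `pct`
#'   (percentages within condition; they sum to 100).
#' @export
distance_distribution <- function(loops) {
  classes <- c("short", "medium", "long", "trans")
  if (nrow(loops) == 0L) {
    warnf("no loops supplied; distance distribution is all zero")
    return(data.frame(condition = character(), class = character(),
                      count = integer(), pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  cond <- if ("condition" %in% names(loops)) loops$condition else "all"
  cls <- classify_distance(loops)
  out <- do.call(rbind, lapply(unique(cond), function(cd) {
    tab <- table(factor(cls[cond == cd], levels = classes))
    data.frame(condition = cd, class = classes,
               count = as.integer(tab),
               pct = 100 * as.integer(tab) / sum(tab),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Promoter windows around each TSS
#'
#' One window per gene, `[tss - flank, tss + flank)` clipped at the
#' chromosome start; symmetric, hence strand-independent.
#'
#' @param catalog a `gene_catalog` ([read_gene_models()]).
#' @param flank half-width in bp (default 1000: 1 kb upstream and
#'   downstream of the TSS).
#' @return Data frame with `gene_id`, `chrom`, `start`, `end`, `tss`.
#' @export
define_promoters <- function(catalog, flank = 1000) {
  stopifnot(inherits(catalog, "gene_catalog"))
  assert_scalar_number(flank, "flank", lower = 1)
  g <- catalog$genes
  out <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                    start = pmax(0, g$tss - flank), end = g$tss + flank,
                    tss = g$tss, stringsAsFactors = FALSE)
  check_intervals(out, what = "promoter window")
  out
}

#' Assign enhancer-promoter status to loops
#'
#' A loop is an EP interaction when either anchor overlaps at least one
#' promoter window by >= 1 bp (half-open overlap). The gene set
#' attributed to a loop is the union over both anchors, and a
#' promoter-promoter loop counts for every gene it touches. Each
#' (loop, gene) pair is reported once.
#'
#' @param loops significance-filtered loop data frame.
#' @param promoters promoter windows ([define_promoters()]).
#' @return Data frame with `loop` (row index into `loops`), `gene_id`,
#'   and `condition` (carried over when present).
#' @export
assign_ep <- function(loops, promoters) {
  check_intervals(promoters, what = "promoter window")
  empty <- data.frame(loop = integer(), gene_id = character(),
                      condition = character(), stringsAsFactors = FALSE)
  if (nrow(loops) == 0L || nrow(promoters) == 0L) return(empty)
  prom_gr <- GenomicRanges::GRanges(
    promoters$chrom,
    IRanges::IRanges(start = promoters$start + 1L, end = promoters$end))
  hit_pairs <- function(chrom, start, end) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
    h <- GenomicRanges::findOverlaps(gr, prom_gr, minoverlap = 1L)
    data.frame(loop = S4Vectors::queryHits(h),
               gene_id = promoters$gene_id[S4Vectors::subjectHits(h)],
               stringsAsFactors = FALSE)
  }
  pairs <- rbind(hit_pairs(loops$chrom_a, loops$start_a, loops$end_a),
                 hit_pairs(loops$chrom_b, loops$start_b, loops$end_b))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs$loop, pairs$gene_id), , drop = FALSE]
  pairs$condition <- if ("condition" %in% names(loops)) {
    loops$condition[pairs$loop]
  } else NA_character_
  rownames(pairs) <- NULL
  pairs
}

#' Per-gene EP counts and their change between two conditions
#'
#' Counts, per gene, the EP loops assigned in each of two conditions and
#' forms the difference. By default `delta_ep` is treatment minus
#' baseline (senescent minus growing), so enhanced contacts are
#' positive; the opposite orientation is available via `sign`.
#'
#' @param assignments EP assignment table from [assign_ep()] with a
#'   `condition` column covering both conditions.
#' @param gene_ids genes to report (zero counts included).
#' @param baseline,treatment condition labels.
#' @param sign `"treatment_minus_baseline"` (default) or
#'   `"baseline_minus_treatment"`.
#' @return Data frame with `gene_id`, `ep_baseline`, `ep_treatment`,
#'   `delta_ep`; the condition labels are stored in attributes
#'   `baseline`/`treatment`.
#' @export
count_ep_per_gene <- function(assignments, gene_ids,
                              baseline = "growing", treatment = "senescent",
                              sign = c("treatment_minus_baseline",
                                       "baseline_minus_treatment")) {
  sign <- match.arg(sign)
  present <- unique(assignments$condition)
  for (cond in c(baseline, treatment)) {
    if (nrow(assignments) > 0L && !cond %in% present) {
      stopf("condition '%s' absent from EP assignments (have: %s)",
            cond, paste(present, collapse = ", "))
    }
  }
  count_for <- function(cond) {
    sub <- assignments[assignments$condition == cond, , drop = FALSE]
    tab <- table(factor(sub$gene_id, levels = gene_ids))
    as.integer(tab)
  }
  out <- data.frame(gene_id = gene_ids,
                    ep_baseline = count_for(baseline),
                    ep_treatment = count_for(treatment),
                    stringsAsFactors = FALSE)
  out$delta_ep <- if (sign == "treatment_minus_baseline") {
    out$ep_treatment - out$ep_baseline
  } else {
    out$ep_baseline - out$ep_treatment
  }
  attr(out, "baseline") <- baseline
  attr(out, "treatment") <- treatment
  attr(out, "sign") <- sign
  out
}
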