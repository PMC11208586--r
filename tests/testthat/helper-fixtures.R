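# Fixture builders shared across test files. Everything is constructed
# in code; no binary fixtures.

# loop row(s) with sensible defaults
make_loops <- function(start_a, end_a, start_b, end_b,
                       chrom_a = "chr1", chrom_b = chrom_a,
                       read_count = 10L, fdr = 0.001, name = ".",
                       assay = "H3K27Ac", condition = "growing") {
  data.frame(chrom_a = chrom_a, start_a = start_a, end_a = end_a,
             chrom_b = chrom_b, start_b = start_b, end_b = end_b,
             name = name, read_count = as.integer(read_count), fdr = fdr,
             assay = assay, condition = condition, stringsAsFactors = FALSE)
}

# loops whose anchor-midpoint separation is exactly `d` (100-bp anchors)
make_loops_at_distance <- function(d, x = 10000, ...) {
  make_loops(start_a = x, end_a = x + 100,
             start_b = x + d, end_b = x + d + 100, ...)
}

# a catalog built directly from per-gene vectors (bypasses file I/O)
make_catalog <- function(gene_id, chrom, strand, start, end,
                         regions = NULL, chrom_sizes = NULL) {
  genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      start = start, end = end,
                      tss = ifelse(strand == "+", start, end - 1),
                      stringsAsFactors = FALSE)
  if (is.null(regions)) {
    regions <- data.frame(gene_id = character(), chrom = character(),
                          region = character(), start = numeric(),
                          end = numeric(), stringsAsFactors = FALSE)
  }
  cat_ <- loopmet:::new_gene_catalog(genes, regions)
  if (!is.null(chrom_sizes)) attr(cat_, "chrom_sizes") <- chrom_sizes
  cat_
}

# random loop set spanning all distance classes and both chromosomes
random_loops <- function(n, seed) {
  set.seed(seed)
  chrom_a <- sample(c("chr1", "chr2"), n, replace = TRUE)
  trans <- runif(n) < 0.1
  chrom_b <- ifelse(trans, ifelse(chrom_a == "chr1", "chr2", "chr1"), chrom_a)
  s1 <- round(runif(n, 0, 5e6))
  d <- round(10^runif(n, 2, 6.7))  # ~100 bp .. ~5 Mb separations
  make_loops(start_a = s1, end_a = s1 + 100, start_b = s1 + d,
             end_b = s1 + d + 100, chrom_a = chrom_a, chrom_b = chrom_b,
             read_count = sample(0:20, n, replace = TRUE),
             fdr = runif(n),
             condition = sample(c("growing", "senescent"), n, replace = TRUE))
}

# brute-force EP oracle: all (loop, promoter) pairs, half-open overlap
brute_force_ep <- function(loops, promoters) {
  hits <- list()
  for (i in seq_len(nrow(loops))) {
    for (j in seq_len(nrow(promoters))) {
      ov_a <- loops$chrom_a[i] == promoters$chrom[j] &&
        loops$start_a[i] < promoters$end[j] &&
        promoters$start[j] < loops$end_a[i]
      ov_b <- loops$chrom_b[i] == promoters$chrom[j] &&
        loops$start_b[i] < promoters$end[j] &&
        promoters$start[j] < loops$end_b[i]
      if (ov_a || ov_b) {
        hits[[length(hits) + 1L]] <- data.frame(
          loop = i, gene_id = promoters$gene_id[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(loop = integer(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$loop, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force per-transcript merge-and-count of m6A peaks
brute_force_m6a_counts <- function(peaks) {
  sapply(split(peaks, peaks$transcript_id), function(p) {
    p <- p[order(p$start), , drop = FALSE]
    n_sites <- 0L
    cur_end <- -Inf
    for (i in seq_len(nrow(p))) {
      if (p$start[i] >= cur_end) {
        n_sites <- n_sites + 1L
        cur_end <- p$end[i]
      } else {
        cur_end <- max(cur_end, p$end[i])
      }
    }
    n_sites
  })
}
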