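# Synthetic-data generation with planted ground truth.
#
# Every generator is a pure function of the config (seed included):
# identical configs give identical output. Each stage derives its own
# stream from config$seed + a fixed offset so that, e.g., regenerating
# expression does not perturb the genome.

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the study design at roughly 1/10 scale: ~500 genes,
#' ~2,000 loops over two conditions, a coupling of expression change to
#' EP change with slope 0.05 and Gaussian noise SD 0.1, EP changes in
#' -3..+3, a 10-gene planted knockdown-reversed subset, ~52
#' polymethylated transcripts of which 4 downregulated, a five-group
#' tracing design with 3 replicates, lognormal multiplicative intensity
#' noise and 0.2-cycle Gaussian Ct noise.
#'
#' @param seed integer master seed.
#' @param n_chromosomes,chrom_sizes genome shape.
#' @param n_genes number of genes.
#' @param gene_length_range min/max gene length (bp).
#' @param min_gene_gap minimum gap between adjacent genes (bp); kept
#'   above twice the promoter flank so promoter windows never overlap.
#' @param promoter_flank promoter half-width (bp).
#' @param delta_levels planted per-gene EP-change values.
#' @param max_baseline_ep upper bound of the baseline EP count draw.
#' @param n_background_loops non-EP, non-significant loops per condition.
#' @param conditions named character vector, roles `baseline`/`treatment`.
#' @param assay assay label stamped on generated loops.
#' @param coupling_alpha,coupling_sigma slope / noise SD of
#'   `log_fc = alpha * delta_ep + N(0, sigma)`.
#' @param n_mtc_genes size of the planted knockdown-reversed,
#'   contact-enhanced gene subset.
#' @param poly_fraction fraction of transcripts planted polymethylated.
#' @param n_poly_down planted polymethylated-and-downregulated count.
#' @param poly_site_range,nonpoly_site_range m6A site-count ranges.
#' @param metabolite_panel data frame from [default_metabolite_panel()].
#' @param p13c natural 13C abundance used in forward convolution.
#' @param n_replicates tracing replicates per group.
#' @param intensity_sdlog lognormal sdlog of intensity noise.
#' @param fraction_sd replicate-level SD of the planted labeled fraction.
#' @param ct_noise_sd Gaussian SD of Ct noise (cycles).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_chromosomes = 2L,
                             chrom_sizes = rep(25e6, n_chromosomes),
                             n_genes = 500L,
                             gene_length_range = c(5000, 20000),
                             min_gene_gap = 5000,
                             promoter_flank = 1000,
                             delta_levels = -3:3,
                             max_baseline_ep = 3L,
                             n_background_loops = 250L,
                             conditions = c(baseline = "growing",
                                            treatment = "senescent"),
                             assay = "H3K27Ac",
                             coupling_alpha = 0.05,
                             coupling_sigma = 0.1,
                             n_mtc_genes = 10L,
                             poly_fraction = 0.104,
                             n_poly_down = 4L,
                             poly_site_range = c(4L, 8L),
                             nonpoly_site_range = c(0L, 3L),
                             metabolite_panel = default_metabolite_panel(),
                             p13c = 0.0107,
                             n_replicates = 3L,
                             intensity_sdlog = 0.05,
                             fraction_sd = 0.02,
                             ct_noise_sd = 0.2) {
  stopifnot(length(chrom_sizes) == n_chromosomes,
            all(chrom_sizes > 0), n_genes >= 0,
            coupling_sigma >= 0, fraction_sd >= 0, intensity_sdlog >= 0,
            ct_noise_sd >= 0, poly_fraction >= 0, poly_fraction <= 1,
            all(c("baseline", "treatment") %in% names(conditions)))
  if (min_gene_gap < 2 * promoter_flank) {
    stopf("min_gene_gap must be at least twice promoter_flank so promoter windows stay disjoint")
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> seed %d: %d genes on %d chromosome(s), %d+ loops/condition, %d tracing replicates\n",
              x$seed, x$n_genes, x$n_chromosomes, x$n_background_loops,
              x$n_replicates))
  invisible(x)
}

#' Generate a synthetic gene catalog
#'
#' Places non-overlapping genes with random strands along the
#' configured chromosomes, at least `min_gene_gap` apart, and splits
#' each gene 10% / 60% / 30% into 5'UTR / CDS / 3'UTR oriented by
#' strand. Deterministic under the config seed.
#'
#' @param config a [generator_config()].
#' @return A `gene_catalog` with a `chrom_sizes` attribute.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_genes
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  if (n == 0L) {
    return(new_gene_catalog(
      data.frame(gene_id = character(), chrom = character(),
                 strand = character(), start = numeric(), end = numeric(),
                 tss = numeric(), stringsAsFactors = FALSE),
      data.frame(gene_id = character(), chrom = character(),
                 region = character(), start = numeric(), end = numeric(),
                 stringsAsFactors = FALSE)))
  }
  chrom_of <- rep(chroms, length.out = n)
  lens <- round(runif(n, config$gene_length_range[1], config$gene_length_range[2]))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  genes <- vector("list", n)
  cursor <- setNames(rep(config$promoter_flank + config$min_gene_gap,
                         length(chroms)), chroms)
  for (i in seq_len(n)) {
    ch <- chrom_of[i]
    gap <- config$min_gene_gap + round(runif(1, 0, config$min_gene_gap))
    start <- cursor[[ch]] + gap
    end <- start + lens[i]
    if (end + config$promoter_flank > config$chrom_sizes[match(ch, chroms)]) {
      stopf("genes do not fit on %s; increase chrom_sizes or reduce n_genes",
            ch)
    }
    cursor[[ch]] <- end
    genes[[i]] <- data.frame(gene_id = sprintf("G%04d", i), chrom = ch,
                             strand = strands[i], start = start, end = end,
                             stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  regions <- do.call(rbind, lapply(seq_len(n), function(i) {
    g <- genes[i, ]
    len <- g$end - g$start
    b1 <- g$start + round(0.1 * len)
    b2 <- g$start + round(0.7 * len)
    lab <- if (g$strand == "+") c("5'UTR", "CDS", "3'UTR") else
      c("3'UTR", "CDS", "5'UTR")
    data.frame(gene_id = g$gene_id, chrom = g$chrom, region = lab,
               start = c(g$start, b1, b2), end = c(b1, b2, g$end),
               stringsAsFactors = FALSE)
  }))
  out <- new_gene_catalog(genes, regions)
  attr(out, "chrom_sizes") <- setNames(config$chrom_sizes, chroms)
  out
}

# TRUE where [s, e) overlaps any promoter window on chromosome `ch`
overlaps_promoter <- function(ch, s, e, promoters) {
  p <- promoters[promoters$chrom == ch, , drop = FALSE]
  any(p$start < e & s < p$end)
}

#' Generate loop files with planted per-gene EP counts
#'
#' For each gene and condition, exactly the planted number of EP loops
#' is emitted: one anchor inside the promoter window, the other at a
#' distal site 10 kb - 1.5 Mb away kept clear of every promoter window
#' (re-placed when a draw lands in one). Planted loops draw FDR/read
#' counts that pass the assay's significance rule; background loops
#' avoid promoters on both anchors and draw FDR/read counts that fail
#' every rule, so the significance filter keeps exactly the planted
#' loops.
#'
#' @param config a [generator_config()].
#' @param catalog catalog from [generate_genome()].
#' @return List with `loops` (both conditions, [read_loops()] layout)
#'   and `truth` (data frame `gene_id`, `ep_baseline`, `ep_treatment`,
#'   `delta_ep`).
#' @export
generate_loops <- function(config, catalog) {
  stopifnot(inherits(config, "generator_config"),
            inherits(catalog, "gene_catalog"))
  set.seed(config$seed + 1L)
  genes <- catalog$genes
  sizes <- attr(catalog, "chrom_sizes")
  promoters <- define_promoters(catalog, config$promoter_flank)
  delta <- sample(config$delta_levels, nrow(genes), replace = TRUE)
  ep_base <- sample(0:config$max_baseline_ep, nrow(genes), replace = TRUE) +
    pmax(0L, -delta)
  ep_treat <- ep_base + delta
  truth <- data.frame(gene_id = genes$gene_id, ep_baseline = ep_base,
                      ep_treatment = ep_treat, delta_ep = delta,
                      stringsAsFactors = FALSE)
  passing_fdr <- function(k) runif(k, 1e-5, 0.009)
  passing_reads <- function(k) sample(4:30, k, replace = TRUE)
  failing_fdr <- function(k) runif(k, 0.06, 0.9)
  failing_reads <- function(k) sample(0:3, k, replace = TRUE)
  place_distal <- function(ch, tss) {
    size <- sizes[[ch]]
    for (try in 1:100) {
      d <- round(runif(1, 1e4, 1.5e6))
      right <- runif(1) < 0.5
      s <- if (right) tss + d else tss - d - 1000
      if (s < 0 || s + 1000 > size) next
      if (!overlaps_promoter(ch, s, s + 1000, promoters)) return(c(s, s + 1000))
    }
    stopf("could not place a distal anchor clear of promoters on %s", ch)
  }
  conds <- config$conditions
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    for (role in c("baseline", "treatment")) {
      k <- if (role == "baseline") ep_base[i] else ep_treat[i]
      if (k == 0L) next
      for (j in seq_len(k)) {
        distal <- place_distal(g$chrom, g$tss)
        a <- c(max(0, g$tss - 250), g$tss + 250)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom_a = g$chrom, start_a = min(a[1], distal[1]),
          end_a = NA_real_, chrom_b = g$chrom, start_b = NA_real_,
          end_b = NA_real_, name = sprintf("%s_%s_%d", g$gene_id, role, j),
          read_count = passing_reads(1L), fdr = passing_fdr(1L),
          assay = config$assay, condition = unname(conds[[role]]),
          .a1 = a[1], .a2 = a[2], .b1 = distal[1], .b2 = distal[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  planted <- do.call(rbind, rows)
  if (!is.null(planted)) {
    left_first <- planted$.a1 <= planted$.b1
    planted$start_a <- ifelse(left_first, planted$.a1, planted$.b1)
    planted$end_a <- ifelse(left_first, planted$.a2, planted$.b2)
    planted$start_b <- ifelse(left_first, planted$.b1, planted$.a1)
    planted$end_b <- ifelse(left_first, planted$.b2, planted$.a2)
    planted <- planted[, !grepl("^\\.", names(planted)), drop = FALSE]
  }
  background <- list()
  chroms <- names(sizes)
  for (cond in unname(conds)) {
    k <- config$n_background_loops
    made <- 0L
    while (made < k) {
      ch <- sample(chroms, 1L)
      s1 <- round(runif(1, 0, sizes[[ch]] - 2e6))
      s2 <- s1 + round(runif(1, 2e4, 1.5e6))
      if (overlaps_promoter(ch, s1, s1 + 1000, promoters) ||
          overlaps_promoter(ch, s2, s2 + 1000, promoters)) next
      made <- made + 1L
      background[[length(background) + 1L]] <- data.frame(
        chrom_a = ch, start_a = s1, end_a = s1 + 1000,
        chrom_b = ch, start_b = s2, end_b = s2 + 1000,
        name = sprintf("bg_%s_%d", cond, made),
        read_count = failing_reads(1L), fdr = failing_fdr(1L),
        assay = config$assay, condition = cond, stringsAsFactors = FALSE)
    }
  }
  loops <- rbind(planted, do.call(rbind, background))
  rownames(loops) <- NULL
  list(loops = loops, truth = truth)
}

#' Generate expression tables coupled to planted EP changes
#'
#' The senescent-vs-growing log fold-change is
#' `coupling_alpha * delta_ep + N(0, coupling_sigma)`. A planted subset
#' of `n_mtc_genes` contact-enhanced genes (`delta_ep > 0`) is forced
#' strongly up in senescence with small adjusted p, and reversed
#' (strongly down, small p) in both knockdown contrasts; all other
#' genes draw adjusted p above 0.05, so the candidate funnel recovers
#' the planted subset. Pass `n_mtc_genes = 0` in the config for a pure
#' coupling table (no overrides).
#'
#' @param config a [generator_config()].
#' @param truth loop truth table from [generate_loops()].
#' @return List with `expression` (long table: `gene_id`, `contrast`,
#'   `score`, `log_fc`, `padj`) and `truth` (list with `mtc_genes`).
#' @export
generate_expression <- function(config, truth) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 2L)
  n <- nrow(truth)
  lfc_sen <- config$coupling_alpha * truth$delta_ep +
    rnorm(n, 0, config$coupling_sigma)
  enhanced <- truth$gene_id[truth$delta_ep > 0]
  n_mtc <- min(config$n_mtc_genes, length(enhanced))
  mtc <- sort(sample(enhanced, n_mtc))
  planted <- truth$gene_id %in% mtc
  lfc_sen[planted] <- 2 + abs(rnorm(sum(planted), 0, 0.3))
  padj_sen <- ifelse(planted, runif(n, 1e-6, 1e-3), runif(n, 0.06, 1))
  score <- exp(rnorm(n, log(50), 1))
  kd_tab <- function(contrast) {
    lfc <- rnorm(n, 0, 0.2)
    lfc[planted] <- -(2 + abs(rnorm(sum(planted), 0, 0.3)))
    padj <- ifelse(planted, runif(n, 1e-6, 1e-3), runif(n, 0.06, 1))
    data.frame(gene_id = truth$gene_id, contrast = contrast, score = score,
               log_fc = lfc, padj = padj, stringsAsFactors = FALSE)
  }
  expr <- rbind(
    data.frame(gene_id = truth$gene_id, contrast = "sen_vs_growing",
               score = score, log_fc = lfc_sen, padj = padj_sen,
               stringsAsFactors = FALSE),
    kd_tab("shMETTL3_vs_sen"),
    kd_tab("shMETTL14_vs_sen"))
  rownames(expr) <- NULL
  list(expression = expr, truth = list(mtc_genes = mtc))
}

#' Generate m6A peaks with planted polymethylation
#'
#' Plants `round(poly_fraction * n_genes)` transcripts with more than
#' three disjoint m6A sites (the rest draw 0-3), placed inside the
#' transcript's region segments, and marks a planted subset of the
#' polymethylated transcripts as downregulated in the accompanying
#' expression table (all other transcripts draw adjusted p above 0.05).
#'
#' @param config a [generator_config()].
#' @param catalog catalog from [generate_genome()].
#' @return List with `peaks` (`transcript_id`, `start`, `end`,
#'   `signal`), `expression` (sen-vs-growing contrast), and `truth`
#'   (list `poly`, `poly_down`, `site_counts`).
#' @export
generate_m6a <- function(config, catalog) {
  stopifnot(inherits(config, "generator_config"),
            inherits(catalog, "gene_catalog"))
  set.seed(config$seed + 3L)
  genes <- catalog$genes
  n <- nrow(genes)
  n_poly <- round(config$poly_fraction * n)
  poly <- sort(sample(genes$gene_id, n_poly))
  counts <- ifelse(genes$gene_id %in% poly,
                   sample(config$poly_site_range[1]:config$poly_site_range[2],
                          n, replace = TRUE),
                   sample(config$nonpoly_site_range[1]:config$nonpoly_site_range[2],
                          n, replace = TRUE))
  peaks <- list()
  for (i in seq_len(n)) {
    k <- counts[i]
    if (k == 0L) next
    g <- genes[i, ]
    slot <- (g$end - g$start) / k
    starts <- g$start + (seq_len(k) - 1) * slot +
      round(runif(k, 0, max(0, slot - 60)))
    peaks[[length(peaks) + 1L]] <- data.frame(
      transcript_id = g$gene_id, start = round(starts),
      end = round(starts) + 50,
      signal = round(runif(k, 1, 10), 3), stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, peaks)
  rownames(peaks) <- NULL
  down <- sort(sample(poly, min(config$n_poly_down, length(poly))))
  is_down <- genes$gene_id %in% down
  expr <- data.frame(
    gene_id = genes$gene_id, contrast = "sen_vs_growing",
    score = exp(rnorm(n, log(50), 1)),
    log_fc = ifelse(is_down, -(2 + abs(rnorm(n, 0, 0.3))), rnorm(n, 0, 0.3)),
    padj = ifelse(is_down, runif(n, 1e-6, 1e-3), runif(n, 0.06, 1)),
    stringsAsFactors = FALSE)
  list(peaks = peaks, expression = expr,
       truth = list(poly = poly, poly_down = down,
                    site_counts = setNames(counts, genes$gene_id)))
}

#' Default metabolite panel for the tracing generator
#'
#' Per-group planted labeled fractions at the tracer-diagnostic
#' isotopologue (`M+5` for the purine-like species). The purine-like
#' metabolites follow the screen's a/b/c pattern (up in senescence,
#' down on knockdown, rescued by wild type only); the pentose-like
#' species moves the other way and the null species is flat.
#'
#' @return Data frame with `metabolite`, `n_carbons`, `m_label` and one
#'   fraction column per group role.
#' @export
default_metabolite_panel <- function() {
  data.frame(
    metabolite = c("IMP_like", "ATP_like", "R5P_like", "null_metab"),
    n_carbons = c(10L, 10L, 5L, 6L),
    m_label = c(5L, 5L, 5L, 6L),
    control = c(0.10, 0.15, 0.50, 0.30),
    sen = c(0.50, 0.55, 0.30, 0.30),
    kd = c(0.20, 0.25, 0.45, 0.30),
    wt = c(0.45, 0.50, 0.32, 0.30),
    mut = c(0.19, 0.24, 0.44, 0.30),
    stringsAsFactors = FALSE)
}

#' Generate a raw isotopologue intensity table
#'
#' For every metabolite, group and replicate: a replicate-level labeled
#' fraction is drawn around the planted value (`fraction_sd`), the true
#' MID (`M+0 = 1 - f`, `M+m = f`) is forward-convolved with natural
#' 13C abundance, scaled to an arbitrary intensity, and multiplied by
#' element-wise lognormal noise (`intensity_sdlog`).
#'
#' @param config a [generator_config()].
#' @return List with `intensities` (long table: `metabolite`,
#'   `n_carbons`, `m_label`, `group`, `replicate`, `mz`, `intensity`)
#'   and `truth` (the panel of planted fractions).
#' @export
generate_isotopologues <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 4L)
  panel <- config$metabolite_panel
  roles <- c("control", "sen", "kd", "wt", "mut")
  labels <- tracing_groups()
  rows <- list()
  for (i in seq_len(nrow(panel))) {
    nc <- panel$n_carbons[i]
    corr <- natural_abundance_matrix(nc, config$p13c)
    for (role in roles) {
      for (rep_ in seq_len(config$n_replicates)) {
        f <- panel[[role]][i] + rnorm(1, 0, config$fraction_sd)
        f <- min(max(f, 0.01), 0.95)
        mid <- numeric(nc + 1L)
        mid[1L] <- 1 - f
        mid[panel$m_label[i] + 1L] <- f
        raw <- as.numeric(corr %*% mid) * 1e6 *
          exp(rnorm(nc + 1L, 0, config$intensity_sdlog))
        rows[[length(rows) + 1L]] <- data.frame(
          metabolite = panel$metabolite[i], n_carbons = nc,
          m_label = panel$m_label[i], group = unname(labels[[role]]),
          replicate = rep_, mz = 0:nc, intensity = raw,
          stringsAsFactors = FALSE)
      }
    }
  }
  intensities <- do.call(rbind, rows)
  rownames(intensities) <- NULL
  list(intensities = intensities, truth = panel)
}

#' Correct a raw isotopologue table and extract labeled fractions
#'
#' Applies [correct_mid()] per (metabolite, group, replicate) and
#' returns both the corrected MIDs and the labeled fraction at each
#' metabolite's diagnostic `m_label`, ready for
#' [screen_metabolites()].
#'
#' @param intensities long table as produced by
#'   [generate_isotopologues()].
#' @param p13c natural 13C abundance used for the correction matrix.
#' @return List with `mids` (long: `metabolite`, `group`, `replicate`,
#'   `mz`, `fraction`) and `fractions` (`metabolite`, `group`,
#'   `replicate`, `fraction`).
#' @export
correct_isotopologue_table <- function(intensities, p13c = 0.0107) {
  key <- interaction(intensities$metabolite, intensities$group,
                     intensities$replicate, drop = TRUE)
  mids <- list()
  fracs <- list()
  for (grp in levels(key)) {
    sub <- intensities[key == grp, , drop = FALSE]
    sub <- sub[order(sub$mz), , drop = FALSE]
    nc <- sub$n_carbons[1L]
    mid <- correct_mid(sub$intensity, natural_abundance_matrix(nc, p13c))
    mids[[length(mids) + 1L]] <- data.frame(
      metabolite = sub$metabolite[1L], group = sub$group[1L],
      replicate = sub$replicate[1L], mz = 0:nc, fraction = mid,
      stringsAsFactors = FALSE)
    fracs[[length(fracs) + 1L]] <- data.frame(
      metabolite = sub$metabolite[1L], group = sub$group[1L],
      replicate = sub$replicate[1L],
      fraction = labeled_fraction(mid, sub$m_label[1L]),
      stringsAsFactors = FALSE)
  }
  list(mids = do.call(rbind, mids), fractions = do.call(rbind, fracs))
}

#' Generate a qPCR Ct table with planted fold changes
#'
#' Two samples (baseline / treatment) over a small target panel; the
#' treatment target Ct is shifted by `-log2(planted fold)` relative to
#' baseline, with Gaussian noise of `ct_noise_sd` cycles on every Ct.
#'
#' @param config a [generator_config()].
#' @param folds named numeric vector of planted treatment-vs-baseline
#'   fold changes per target.
#' @return List with `ct` (`sample`, `target`, `target_ct`,
#'   `reference_ct`) and `truth` (the planted folds).
#' @export
generate_ct <- function(config, folds = c(HK2 = 4, CDCA8 = 0.5, GAPDHL = 1)) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 5L)
  conds <- config$conditions
  rows <- list()
  for (tg in names(folds)) {
    base_ct <- runif(1, 20, 26)
    for (role in c("baseline", "treatment")) {
      shift <- if (role == "treatment") -log2(folds[[tg]]) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        sample = unname(conds[[role]]), target = tg,
        target_ct = base_ct + shift + rnorm(1, 0, config$ct_noise_sd),
        reference_ct = 18 + rnorm(1, 0, config$ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  list(ct = do.call(rbind, rows), truth = folds)
}
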