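# Significance filtering, distance classes, promoters, EP assignment
# and per-gene EP counting.

test_that("assay-specific significance rules are applied", {
  loops <- rbind(make_loops(0, 100, 5000, 5100, read_count = 4, fdr = 0.005),
                 make_loops(0, 100, 5000, 5100, read_count = 3, fdr = 0.005),
                 make_loops(0, 100, 5000, 5100, read_count = 50, fdr = 0.02))
  kept <- filter_significant_loops(loops, "H3K27Ac")
  expect_equal(nrow(kept), 1L)      # fdr < 0.01 AND reads >= 4
  expect_equal(kept$read_count, 4L)

  m3 <- make_loops(0, 100, 5000, 5100, read_count = 1, fdr = 0.04,
                   assay = "METTL3")
  expect_equal(nrow(filter_significant_loops(m3, "METTL3")), 1L)
  expect_equal(nrow(filter_significant_loops(
    make_loops(0, 100, 5000, 5100, fdr = 0.06, assay = "METTL3"), "METTL3")), 0L)

  expect_error(filter_significant_loops(loops, "ChIA-PET"))
  expect_error(filter_significant_loops(m3, "H3K27Ac"), "assay")
})

test_that("relaxing the FDR threshold never removes a kept loop", {
  loops <- random_loops(500, seed = 1)
  loops$assay <- "H3K27Ac"
  strict <- filter_significant_loops(loops, "H3K27Ac", fdr = 0.01)
  for (f in c(0.02, 0.05, 0.2, 1)) {
    relaxed <- filter_significant_loops(loops, "H3K27Ac", fdr = f)
    expect_true(all(strict$name %in% relaxed$name) &&
                  nrow(relaxed) >= nrow(strict))
  }
})

test_that("distance classes follow the printed thresholds with midpoint separation", {
  expect_equal(classify_distance(make_loops(1000, 2000, 4000, 5000)), "short")
  # boundary values: strict < 5 kb, closed [5 kb, 2 Mb], strict > 2 Mb
  expect_equal(classify_distance(make_loops_at_distance(4999)), "short")
  expect_equal(classify_distance(make_loops_at_distance(5000)), "medium")
  expect_equal(classify_distance(make_loops_at_distance(2000000)), "medium")
  expect_equal(classify_distance(make_loops_at_distance(2000001)), "long")
  expect_equal(classify_distance(make_loops(0, 100, 500, 600, chrom_b = "chr2")),
               "trans")
})

test_that("every intra-chromosomal loop falls in exactly one distance class", {
  loops <- random_loops(2000, seed = 3)
  cls <- classify_distance(loops)
  expect_length(cls, nrow(loops))
  expect_true(all(cls %in% c("short", "medium", "long", "trans")))
  intra <- loops$chrom_a == loops$chrom_b
  expect_true(all(cls[intra] != "trans"))
  expect_true(all(cls[!intra] == "trans"))
})

test_that("distance_distribution matches a brute-force tally", {
  loops <- rbind(make_loops_at_distance(1000), make_loops_at_distance(2000),
                 make_loops_at_distance(3000), make_loops_at_distance(3e6))
  d <- distance_distribution(loops)
  expect_equal(d$pct[d$class == "short"], 75)
  expect_equal(d$pct[d$class == "long"], 25)

  one <- distance_distribution(make_loops_at_distance(10000))
  expect_equal(one$pct[one$class == "medium"], 100)

  loops <- random_loops(1000, seed = 8)
  d <- distance_distribution(loops)
  cls <- classify_distance(loops)
  for (cond in unique(loops$condition)) {
    for (cl in c("short", "medium", "long", "trans")) {
      expect_equal(d$count[d$condition == cond & d$class == cl],
                   sum(cls == cl & loops$condition == cond))
    }
    expect_equal(sum(d$pct[d$condition == cond]), 100, tolerance = 1e-9)
  }
  expect_warning(distance_distribution(loops[0, ]), "zero")
})

test_that("promoter windows are symmetric around the TSS and clipped at zero", {
  cat_ <- make_catalog(c("gP", "gClip", "gMinus"), "chr1",
                       c("+", "+", "-"),
                       start = c(10000, 500, 20000),
                       end = c(15000, 4000, 24001))
  p <- define_promoters(cat_, flank = 1000)
  expect_equal(p[p$gene_id == "gP", c("start", "end")],
               data.frame(start = 9000, end = 11000), ignore_attr = TRUE)
  expect_equal(p$start[p$gene_id == "gClip"], 0)
  expect_equal(p$end[p$gene_id == "gClip"], 1500)
  # minus-strand gene: same +/- flank around tss = end - 1
  expect_equal(p[p$gene_id == "gMinus", c("start", "end")],
               data.frame(start = 23000, end = 25000), ignore_attr = TRUE)
  expect_equal(p$end[p$gene_id == "gMinus"] - p$start[p$gene_id == "gMinus"],
               2 * 1000)
})

test_that("EP assignment uses 1-bp half-open overlap on either anchor", {
  prom <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                     start = c(9000, 50000), end = c(11000, 52000),
                     stringsAsFactors = FALSE)
  # anchor A overlaps g1's window
  ep <- assign_ep(make_loops(10500, 15500, 100000, 101000), prom)
  expect_equal(ep$gene_id, "g1")
  # touching but not overlapping (half-open): no assignment
  ep <- assign_ep(make_loops(11000, 12000, 100000, 101000), prom)
  expect_equal(nrow(ep), 0L)
  # promoter-promoter loop: attributed to both genes
  ep <- assign_ep(make_loops(10000, 10500, 50500, 51000), prom)
  expect_setequal(ep$gene_id, c("g1", "g2"))
})

test_that("EP assignment equals the brute-force all-pairs oracle", {
  set.seed(21)
  n_genes <- 40
  tss <- sort(sample(seq(5000, 4e6, by = 7000), n_genes))
  cat_ <- make_catalog(sprintf("g%02d", 1:n_genes), "chr1", "+",
                       start = tss, end = tss + 3000)
  prom <- define_promoters(cat_)
  loops <- random_loops(400, seed = 22)
  got <- assign_ep(loops, prom)[, c("loop", "gene_id")]
  rownames(got) <- NULL
  expect_equal(got, brute_force_ep(loops, prom))
})

test_that("per-gene EP counts difference follows the configured sign", {
  asg <- data.frame(
    loop = 1:6,
    gene_id = c("gA", "gA", "gA", "gA", "gB", "gB"),
    condition = c("senescent", "senescent", "senescent", "growing",
                  "growing", "senescent"),
    stringsAsFactors = FALSE)
  tab <- count_ep_per_gene(asg, c("gA", "gB", "gC"))
  expect_equal(tab$delta_ep[tab$gene_id == "gA"], 2)  # 3 senescent - 1 growing
  expect_equal(unlist(tab[tab$gene_id == "gC", c("ep_baseline", "ep_treatment",
                                                 "delta_ep")]),
               c(ep_baseline = 0, ep_treatment = 0, delta_ep = 0))
  flipped <- count_ep_per_gene(asg, c("gA", "gB", "gC"),
                               sign = "baseline_minus_treatment")
  expect_equal(flipped$delta_ep, -tab$delta_ep)
  expect_error(count_ep_per_gene(asg, "gA", baseline = "quiescent"),
               "quiescent")
})
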