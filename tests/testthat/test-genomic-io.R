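# Reading and writing loops, gene models and schema-validated tables.

test_that("BEDPE lines map directly onto loop records", {
  path <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr1\t1000\t2000\tchr1\t4000\t5000\t.\t7\t0.003", path)
  loops <- read_loops(path, assay = "H3K27Ac", condition = "growing")
  expect_equal(nrow(loops), 1L)
  expect_equal(loops$read_count, 7L)
  expect_equal(loops$fdr, 0.003)
  expect_equal(loops$start_a, 1000)
  expect_equal(loops$end_b, 5000)
  expect_equal(loops$assay, "H3K27Ac")
})

test_that("intra-chromosomal anchors are normalized so anchor A comes first", {
  path <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr1\t4000\t5000\tchr1\t1000\t2000\t.\t5\t0.01", path)
  loops <- read_loops(path)
  expect_true(loops$start_a <= loops$start_b)
  expect_equal(loops$start_a, 1000)
  expect_equal(loops$end_a, 2000)
})

test_that("an empty loop file yields an empty table with a warning", {
  path <- withr::local_tempfile(fileext = ".bedpe")
  file.create(path)
  expect_warning(loops <- read_loops(path), "empty")
  expect_equal(nrow(loops), 0L)
  expect_true(all(c("chrom_a", "read_count", "fdr") %in% names(loops)))
})

test_that("malformed loop lines fail hard with their line number", {
  path <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t1000\t2000\tchr1\t4000\t5000\t.\t7\t0.003",
               "chr1\t1000\t2000\tchr1\t4000\t5000\t.\t7\t1.7"), path)
  expect_error(read_loops(path), "line 2.*FDR")
  writeLines("chr1\t-5\t2000\tchr1\t4000\t5000\t.\t7\t0.003", path)
  expect_error(read_loops(path), "line 1")
  writeLines("chr1\t1000\t2000\tchr1\t4000\t5000\t.\tseven\t0.003", path)
  expect_error(read_loops(path), "non-numeric")
  expect_error(read_loops(tempfile()), "not found")
})

test_that("write_loops / read_loops round-trips record content", {
  loops <- random_loops(200, seed = 42)
  path <- withr::local_tempfile(fileext = ".bedpe")
  write_loops(loops, path)
  back <- read_loops(path, assay = loops$assay[1])
  cols <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
            "read_count")
  expect_equal(back[, cols], loops[, cols])
  expect_equal(back$fdr, loops$fdr, tolerance = 1e-12)
  # second write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".bedpe")
  write_loops(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("a custom dialect relocates the count and FDR columns", {
  path <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr1\t1000\t2000\tchr1\t4000\t5000\t0.003\t12", path)
  loops <- read_loops(path, loop_dialect(name = NA, fdr = 7, read_count = 8))
  expect_equal(loops$read_count, 12L)
  expect_equal(loops$fdr, 0.003)
  expect_error(loop_dialect(read_count = 2), "distinct")
})

test_that("BED12 TSS follows the strand convention", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t600\tplusG\t0\t+\t150\t500\t0\t1\t500\t0",
    "chr1\t1100\t1600\tminusG\t0\t-\t1150\t1500\t0\t1\t500\t0"), path)
  cat_ <- read_gene_models(path, "bed12")
  g <- cat_$genes
  expect_equal(g$tss[g$gene_id == "plusG"], 100)   # + strand: start
  expect_equal(g$tss[g$gene_id == "minusG"], 1599) # - strand: end - 1
})

test_that("BED12 thick coordinates split exons into UTRs and CDS", {
  path <- withr::local_tempfile(fileext = ".bed")
  # two blocks [100,300) and [400,600); CDS [250,450)
  writeLines("chr1\t100\t600\tg1\t0\t+\t250\t450\t0\t2\t200,200\t0,300", path)
  cat_ <- read_gene_models(path, "bed12")
  r <- cat_$regions
  fiveutr <- r[r$region == "5'UTR", ]
  cds <- r[r$region == "CDS", ]
  threeutr <- r[r$region == "3'UTR", ]
  expect_equal(fiveutr[, c("start", "end")],
               data.frame(start = 100, end = 250), ignore_attr = TRUE)
  expect_equal(cds[, c("start", "end")],
               data.frame(start = c(250, 400), end = c(300, 450)),
               ignore_attr = TRUE)
  expect_equal(threeutr[, c("start", "end")],
               data.frame(start = 450, end = 600), ignore_attr = TRUE)
})

test_that("a toy GTF parses to the hand-derived catalog", {
  path <- withr::local_tempfile(fileext = ".gtf")
  attr_ <- function(id) sprintf('gene_id "%s";', id)
  writeLines(c(
    paste("chr1", "test", "gene", 101, 600, ".", "+", ".", attr_("gA"), sep = "\t"),
    paste("chr1", "test", "five_prime_utr", 101, 150, ".", "+", ".", attr_("gA"), sep = "\t"),
    paste("chr1", "test", "CDS", 151, 500, ".", "+", ".", attr_("gA"), sep = "\t"),
    paste("chr1", "test", "three_prime_utr", 501, 600, ".", "+", ".", attr_("gA"), sep = "\t"),
    paste("chr1", "test", "gene", 1001, 1500, ".", "-", ".", attr_("gB"), sep = "\t"),
    paste("chr1", "test", "CDS", 1001, 1500, ".", "-", ".", attr_("gB"), sep = "\t"),
    paste("chr2", "test", "gene", 51, 250, ".", "+", ".", attr_("gC"), sep = "\t")),
    path)
  cat_ <- read_gene_models(path, "gtf")
  expect_equal(nrow(cat_$genes), 3L)
  gA <- cat_$genes[cat_$genes$gene_id == "gA", ]
  expect_equal(gA$start, 100)  # 1-based 101 -> 0-based 100
  expect_equal(gA$end, 600)
  expect_equal(gA$tss, 100)
  gB <- cat_$genes[cat_$genes$gene_id == "gB", ]
  expect_equal(gB$tss, 1499)  # - strand
  rA <- cat_$regions[cat_$regions$gene_id == "gA", ]
  expect_setequal(rA$region, c("5'UTR", "CDS", "3'UTR"))
  expect_equal(rA$start[rA$region == "CDS"], 150)
  expect_equal(rA$end[rA$region == "CDS"], 500)
})

test_that("gene-model validation rejects bad strands and overlapping duplicates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t600\tg1\t0\t?\t100\t600\t0\t1\t500\t0", path)
  expect_error(read_gene_models(path, "bed12"), "strand")
  writeLines(c("chr1\t100\t600\tdupG\t0\t+\t100\t600\t0\t1\t500\t0",
               "chr1\t400\t900\tdupG\t0\t+\t400\t900\t0\t1\t500\t0"), path)
  expect_error(read_gene_models(path, "bed12"), "dupG")
})

test_that("read_table types columns and reports schema violations", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- data.frame(gene_id = c("a", "b"), contrast = "sen_vs_growing",
                    score = c(1.5, 2.5), log_fc = c(-1, 2),
                    padj = c(0.01, 0.2), stringsAsFactors = FALSE)
  write_table(tab, path)
  back <- read_table(path, schema_expression)
  expect_identical(back, tab)
  expect_type(back$padj, "double")

  write_table(tab[, setdiff(names(tab), "padj")], path)
  expect_error(read_table(path, schema_expression), "padj")

  tab2 <- tab
  tab2$score <- c("1.5", "not-a-number")
  write_table(tab2, path)
  expect_error(read_table(path, schema_expression), "non-numeric.*not-a-number")
})

test_that("a large synthetic table round-trips through write_table", {
  set.seed(9)
  tab <- data.frame(gene_id = sprintf("G%04d", 1:1000),
                    contrast = "sen_vs_growing",
                    score = round(exp(rnorm(1000, 3, 1)), 6),
                    log_fc = round(rnorm(1000), 6),
                    padj = round(runif(1000), 6), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(tab, path)
  back <- read_table(path, schema_expression)
  expect_equal(back, tab)
  expect_equal(nrow(back), 1000L)
})
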