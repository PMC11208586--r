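# Grouped resampling, Pearson correlation and the candidate funnel.

make_ep_expr <- function(n, deltas, slope, sigma, seed) {
  set.seed(seed)
  ep <- data.frame(gene_id = sprintf("g%04d", 1:n),
                   delta_ep = sample(deltas, n, replace = TRUE),
                   stringsAsFactors = FALSE)
  expr <- data.frame(gene_id = ep$gene_id,
                     log_fc = slope * ep$delta_ep + rnorm(n, 0, sigma),
                     stringsAsFactors = FALSE)
  list(ep = ep, expr = expr)
}

test_that("noise-free linear coupling gives r = 1 through resampling", {
  d <- make_ep_expr(300, -3:3, slope = 0.1, sigma = 0, seed = 1)
  rs <- group_resample_logfc(d$ep, d$expr, seed = 99)
  expect_equal(rs$pearson_r, 1, tolerance = 1e-12)
  expect_equal(rs$groups$grand_mean, 0.1 * rs$groups$delta_ep,
               tolerance = 1e-12)
})

test_that("a single-gene group resamples with replacement to its own value", {
  ep <- data.frame(gene_id = c("lonely", sprintf("g%02d", 1:80)),
                   delta_ep = c(5, rep(0, 80)))
  expr <- data.frame(gene_id = ep$gene_id, log_fc = c(0.7, rnorm(80)))
  rs <- group_resample_logfc(ep, expr, group_size = 70, reps = 50, seed = 3)
  lone <- which(rs$groups$delta_ep == 5)
  expect_true(rs$groups$replace[lone])
  expect_equal(rs$groups$n_genes[lone], 1L)
  expect_true(all(rs$draw_means[lone, ] == 0.7))
})

test_that("resampling is reproducible under a fixed seed and seed-sensitive otherwise", {
  d <- make_ep_expr(400, -2:2, slope = 0.05, sigma = 0.2, seed = 7)
  a <- group_resample_logfc(d$ep, d$expr, seed = 11)
  b <- group_resample_logfc(d$ep, d$expr, seed = 11)
  expect_identical(a$draw_means, b$draw_means)
  expect_identical(a$pearson_r, b$pearson_r)
  c_ <- group_resample_logfc(d$ep, d$expr, seed = 12)
  expect_false(identical(a$draw_means, c_$draw_means))
  expect_identical(a$groups[, c("delta_ep", "n_genes")],
                   c_$groups[, c("delta_ep", "n_genes")])
})

test_that("degenerate resampling inputs raise explicit errors", {
  ep <- data.frame(gene_id = c("a", "b"), delta_ep = c(1, 1))
  expr <- data.frame(gene_id = c("a", "b"), log_fc = c(0, 1))
  expect_error(group_resample_logfc(ep, expr, seed = 1), "2 distinct")
  ep$delta_ep <- c(1, 2)
  expect_error(group_resample_logfc(ep, expr[1, ], seed = 1), "log_fc")
  expect_error(group_resample_logfc(ep, expr), "seed")
})

test_that("candidate correlation matches the textbook Pearson computation", {
  expect_equal(correlate_candidates(1:5, 2 * (1:5) + 3)$pearson_r, 1)
  anti <- correlate_candidates(c(1, 2, 3), c(3, 2, 1))
  expect_equal(anti$pearson_r, -1)

  set.seed(13)
  x <- rnorm(10)
  y <- rnorm(10)
  got <- correlate_candidates(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r_manual * sqrt(8 / (1 - r_manual^2))
  p_manual <- 2 * stats::pt(-abs(t_stat), df = 8)
  expect_equal(got$pearson_r, r_manual, tolerance = 1e-12)
  expect_equal(got$p_value, p_manual, tolerance = 1e-12)

  expect_error(correlate_candidates(1:2, 1:2), "3 pairs")
  expect_error(correlate_candidates(c(1, 1, 1), 1:3), "variance")
})

toy_expression <- function() {
  # hand-enumerated at (up_lfc=1, down_lfc=1, alpha=0.05):
  #   up in sen:            g1 g2 g3 g5
  #   down on METTL3 KD:    g1 g2 g5 g6
  #   down on METTL14 KD:   g1 g3 g5
  #   both-KD candidates:   g1 g5 ; either-KD adds g2 g3
  g <- sprintf("g%d", 1:6)
  rbind(
    data.frame(gene_id = g, contrast = "sen_vs_growing", score = 10,
               log_fc = c(2.0, 1.5, 1.2, 0.4, 3.0, 2.2),
               padj = c(0.01, 0.01, 0.01, 0.01, 0.001, 0.2)),
    data.frame(gene_id = g, contrast = "shMETTL3_vs_sen", score = 10,
               log_fc = c(-2.0, -1.1, -0.2, -1.5, -2.5, -1.2),
               padj = c(0.01, 0.02, 0.01, 0.01, 0.001, 0.01)),
    data.frame(gene_id = g, contrast = "shMETTL14_vs_sen", score = 10,
               log_fc = c(-1.8, -0.3, -1.4, -1.2, -2.2, -0.9),
               padj = c(0.01, 0.01, 0.04, 0.3, 0.001, 0.01)))
}

test_that("the funnel reproduces the hand-enumerated toy selection", {
  expr <- toy_expression()
  both <- select_mtc_dependent_genes(expr)
  expect_equal(both$up, c("g1", "g2", "g3", "g5"))
  expect_equal(both$candidates, c("g1", "g5"))
  either <- select_mtc_dependent_genes(expr, mode = "either")
  expect_equal(either$candidates, c("g1", "g2", "g3", "g5"))
  # g2 is down on METTL3 KD only: excluded in both-KD, included in either-KD
  expect_false("g2" %in% both$candidates)
  expect_true("g2" %in% either$candidates)
})

test_that("funnel edge cases and threshold monotonicity behave", {
  expr <- toy_expression()
  none <- select_mtc_dependent_genes(expr, up_lfc = 10)
  expect_length(none$candidates, 0L)
  expect_error(select_mtc_dependent_genes(expr[expr$contrast != "shMETTL14_vs_sen", ]),
               "shMETTL14_vs_sen")
  loose <- select_mtc_dependent_genes(expr, alpha = 0.05)$candidates
  for (a in c(0.02, 0.009, 0.001)) {
    tight <- select_mtc_dependent_genes(expr, alpha = a)$candidates
    expect_true(all(tight %in% loose))
    loose <- tight
  }
})

test_that("enhanced-contact intersection keeps strictly positive delta only", {
  expr <- toy_expression()
  cand <- select_mtc_dependent_genes(expr)
  ep <- data.frame(gene_id = sprintf("g%d", 1:6),
                   delta_ep = c(2, 1, -1, 0, 0, 3))
  out <- intersect_enhanced_contacts(cand, ep)
  expect_equal(out$contact_enhanced, "g1")  # g5 has delta_ep = 0: dropped
  expect_equal(out$pairs$delta_ep, 2)
  expect_equal(out$pairs$log_fc, 2.0)
  expect_error(intersect_enhanced_contacts(cand, ep[-1, ]), "g1")
})

test_that("resampled p-values are calibrated under the null coupling", {
  # planted slope 0: group means should rarely correlate with delta_ep
  hits <- 0L
  for (seed in 1:40) {
    d <- make_ep_expr(350, -3:3, slope = 0, sigma = 0.1, seed = seed)
    rs <- group_resample_logfc(d$ep, d$expr, reps = 50, seed = seed + 1000)
    if (rs$p_value > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 36L)  # >= 90% of null runs non-significant
})
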