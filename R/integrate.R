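# Coupling EP changes to nascent transcription: grouped resampling,
# Pearson correlation, and the knockdown candidate-gene funnel.

#' Grouped resampling of log fold-changes by EP change
#'
#' Genes are partitioned by their `delta_ep` value. Within each group,
#' `group_size` genes are drawn `reps` times (without replacement when
#' the group has at least `group_size` members, with replacement
#' otherwise, so sparse tails are kept rather than dropped) and the mean
#' log fold-change of each draw is recorded. The per-group grand mean of
#' the draw means is then correlated with the group's `delta_ep` value
#' (Pearson, two-sided p). Resampling damps the influence of outlier
#' genes on the trend.
#'
#' @param ep_table EP count table ([count_ep_per_gene()]) or any data
#'   frame with `gene_id` and `delta_ep`.
#' @param expression data frame with `gene_id` and `log_fc`; every gene
#'   in `ep_table` must have a fold change.
#' @param group_size genes per draw (default 70).
#' @param reps draws per group (default 200).
#' @param seed integer seed; resampling is reproducible for a fixed
#'   seed.
#' @return An object of class `resample_result`: list with `groups`
#'   (data frame `delta_ep`, `n_genes`, `replace`, `grand_mean`),
#'   `draw_means` (matrix, groups x reps), `pearson_r`, `p_value`.
#' @export
group_resample_logfc <- function(ep_table, expression, group_size = 70L,
                                 reps = 200L, seed) {
  if (missing(seed)) stopf("an explicit 'seed' is required")
  assert_scalar_number(group_size, "group_size", lower = 1)
  assert_scalar_number(reps, "reps", lower = 1)
  lfc <- expression$log_fc[match(ep_table$gene_id, expression$gene_id)]
  if (anyNA(lfc)) {
    stopf("no log_fc for gene(s): %s",
          paste(utils::head(ep_table$gene_id[is.na(lfc)], 5L), collapse = ", "))
  }
  levels_ <- sort(unique(ep_table$delta_ep))
  if (length(levels_) < 2L) {
    stopf("fewer than 2 distinct delta_ep groups; correlation undefined")
  }
  set.seed(as.integer(seed))
  draw_means <- matrix(NA_real_, nrow = length(levels_), ncol = reps)
  n_genes <- integer(length(levels_))
  with_repl <- logical(length(levels_))
  for (i in seq_along(levels_)) {
    vals <- lfc[ep_table$delta_ep == levels_[i]]
    n_genes[i] <- length(vals)
    with_repl[i] <- length(vals) < group_size
    for (r in seq_len(reps)) {
      draw_means[i, r] <- mean(sample(vals, group_size, replace = with_repl[i]))
    }
  }
  grand <- rowMeans(draw_means)
  if (length(levels_) >= 3L) {
    ct <- stats::cor.test(levels_, grand, method = "pearson",
                          alternative = "two.sided")
    r <- unname(ct$estimate)
    p <- ct$p.value
  } else {
    # two groups: r is +/-1 by construction and the t transform has no df
    r <- unname(stats::cor(levels_, grand))
    p <- NA_real_
  }
  structure(list(
    groups = data.frame(delta_ep = levels_, n_genes = n_genes,
                        replace = with_repl, grand_mean = grand),
    draw_means = draw_means,
    pearson_r = r,
    p_value = p,
    group_size = group_size, reps = reps, seed = as.integer(seed)
  ), class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf("<resample_result> %d delta_ep groups, %d draws of %d genes\n",
              nrow(x$groups), x$reps, x$group_size))
  cat(sprintf("  Pearson r = %.4f, two-sided p = %.3g\n", x$pearson_r, x$p_value))
  invisible(x)
}

#' Pearson correlation of per-gene (delta EP, log fold-change) pairs
#'
#' Product-moment correlation with a two-sided p-value from the t
#' transform on n - 2 degrees of freedom.
#'
#' @param delta_ep,log_fc numeric vectors of equal length (>= 3 pairs).
#' @return List with `pearson_r`, `p_value`, `n`.
#' @export
correlate_candidates <- function(delta_ep, log_fc) {
  if (length(delta_ep) != length(log_fc)) stopf("input lengths differ")
  if (length(delta_ep) < 3L) stopf("need at least 3 pairs")
  if (stats::sd(delta_ep) == 0 || stats::sd(log_fc) == 0) {
    stopf("zero variance in one coordinate; correlation undefined")
  }
  ct <- stats::cor.test(delta_ep, log_fc, method = "pearson",
                        alternative = "two.sided")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n = length(delta_ep))
}

#' Candidate funnel: senescence-up, knockdown-down genes
#'
#' Selects genes upregulated in senescence (`log_fc >= up_lfc`,
#' `padj < alpha` in the senescent-vs-growing contrast) and
#' downregulated on methyltransferase-complex knockdown
#' (`log_fc <= -down_lfc`, `padj < alpha`). In `"both"` mode (the
#' Venn-overlap reading) a gene must be down in both knockdown
#' contrasts; in `"either"` mode one suffices.
#'
#' @param expression long data frame with columns `gene_id`,
#'   `contrast`, `log_fc`, `padj` covering the three contrasts.
#' @param up_lfc,down_lfc log2 fold-change thresholds (defaults 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param mode `"both"` or `"either"`.
#' @param contrasts named character vector mapping roles `up`, `kd1`,
#'   `kd2` to contrast labels in `expression`.
#' @return An object of class `candidate_genes`: list with the stage
#'   sets `up`, `down_kd1`, `down_kd2`, the final `candidates`, and
#'   `pairs_log_fc` (named log fold-changes of the candidates in the up
#'   contrast).
#' @export
select_mtc_dependent_genes <- function(expression, up_lfc = 1, down_lfc = 1,
                                       alpha = 0.05,
                                       mode = c("both", "either"),
                                       contrasts = c(up = "sen_vs_growing",
                                                     kd1 = "shMETTL3_vs_sen",
                                                     kd2 = "shMETTL14_vs_sen")) {
  mode <- match.arg(mode)
  stopifnot(all(c("up", "kd1", "kd2") %in% names(contrasts)))
  have <- unique(expression$contrast)
  missing_c <- setdiff(unname(contrasts), have)
  if (length(missing_c) > 0L) {
    stopf("contrast(s) missing from expression table: %s",
          paste(missing_c, collapse = ", "))
  }
  pick <- function(label, dir, thr) {
    sub <- expression[expression$contrast == label, , drop = FALSE]
    ok <- if (dir == "up") sub$log_fc >= thr else sub$log_fc <= -thr
    sort(unique(sub$gene_id[ok & sub$padj < alpha]))
  }
  up <- pick(contrasts[["up"]], "up", up_lfc)
  down1 <- pick(contrasts[["kd1"]], "down", down_lfc)
  down2 <- pick(contrasts[["kd2"]], "down", down_lfc)
  kd <- if (mode == "both") intersect(down1, down2) else union(down1, down2)
  candidates <- intersect(up, kd)
  up_tab <- expression[expression$contrast == contrasts[["up"]], , drop = FALSE]
  pairs_log_fc <- setNames(up_tab$log_fc[match(candidates, up_tab$gene_id)],
                           candidates)
  structure(list(up = up, down_kd1 = down1, down_kd2 = down2,
                 candidates = candidates, pairs_log_fc = pairs_log_fc,
                 mode = mode,
                 thresholds = c(up_lfc = up_lfc, down_lfc = down_lfc,
                                alpha = alpha)),
            class = "candidate_genes")
}

#' @export
print.candidate_genes <- function(x, ...) {
  cat(sprintf("<candidate_genes> up: %d | down KD1: %d | down KD2: %d | %s-KD candidates: %d\n",
              length(x$up), length(x$down_kd1), length(x$down_kd2),
              x$mode, length(x$candidates)))
  if (!is.null(x$contact_enhanced)) {
    cat(sprintf("  contact-enhanced (delta_ep > 0): %d\n",
                length(x$contact_enhanced)))
  }
  invisible(x)
}

#' Restrict candidates to genes with enhanced chromatin contacts
#'
#' Keeps candidates with strictly positive `delta_ep` and attaches the
#' (delta EP, log fold-change) pairs used for the final correlation.
#'
#' @param candidates a `candidate_genes` object.
#' @param ep_table EP count table with `gene_id` and `delta_ep`; every
#'   candidate must be present.
#' @return The `candidate_genes` object augmented with
#'   `contact_enhanced` (gene ids) and `pairs` (data frame `gene_id`,
#'   `delta_ep`, `log_fc`).
#' @export
intersect_enhanced_contacts <- function(candidates, ep_table) {
  stopifnot(inherits(candidates, "candidate_genes"))
  idx <- match(candidates$candidates, ep_table$gene_id)
  if (anyNA(idx)) {
    stopf("no delta_ep for candidate(s): %s",
          paste(utils::head(candidates$candidates[is.na(idx)], 5L),
                collapse = ", "))
  }
  delta <- ep_table$delta_ep[idx]
  keep <- delta > 0
  candidates$contact_enhanced <- candidates$candidates[keep]
  candidates$pairs <- data.frame(
    gene_id = candidates$candidates[keep],
    delta_ep = delta[keep],
    log_fc = unname(candidates$pairs_log_fc[keep]),
    stringsAsFactors = FALSE)
  candidates
}
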