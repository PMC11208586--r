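# 13C isotope tracing: natural-abundance correction of isotopologue
# intensity vectors, labeled fractions, protein normalization and the
# three-criterion metabolite screen.

#' Natural 13C abundance correction matrix
#'
#' For a metabolite with `n_carbons` carbons, column `k` (0-based: the
#' species with `k` tracer-labeled carbons) holds the binomial mass
#' distribution of the remaining `n_carbons - k` unlabeled positions at
#' natural 13C abundance `p13c`, shifted up by `k`. The matrix is lower
#' triangular and every column sums to 1. Measured intensities are the
#' product of this matrix with the true mass-isotopomer distribution
#' (MID).
#'
#' @param n_carbons number of carbons (>= 1).
#' @param p13c natural 13C abundance (default 0.0107). Carbon-only
#'   correction; N/H/O isotopes are not modeled.
#' @return `(n_carbons + 1) x (n_carbons + 1)` matrix.
#' @examples
#' natural_abundance_matrix(1)  # columns (0.9893, 0.0107) and (0, 1)
#' @export
natural_abundance_matrix <- function(n_carbons, p13c = 0.0107) {
  assert_scalar_number(n_carbons, "n_carbons", lower = 1)
  assert_scalar_number(p13c, "p13c", lower = 0)
  if (p13c >= 1) stopf("'p13c' must be < 1")
  n <- as.integer(n_carbons)
  m <- matrix(0, n + 1L, n + 1L)
  for (k in 0:n) {
    m[(k:n) + 1L, k + 1L] <- stats::dbinom(0:(n - k), size = n - k, prob = p13c)
  }
  m
}

#' Correct a raw isotopologue vector for natural abundance
#'
#' Solves `matrix %*% x = raw` for `x >= 0` and normalizes the solution
#' to sum 1, yielding the corrected mass-isotopomer distribution. The
#' triangular system is inverted directly (exact on clean data) with a
#' non-negative least-squares fallback whenever noise drives the
#' inverse negative, so noisy measurements never produce negative
#' fractions. The raw intensity scale does not affect the result.
#'
#' @param raw non-negative intensity vector `M+0 ... M+n`.
#' @param matrix correction matrix from [natural_abundance_matrix()].
#' @return Numeric vector of fractions summing to 1.
#' @export
correct_mid <- function(raw, matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (length(raw) != nrow(matrix)) {
    stopf("raw vector length %d does not match matrix dimension %d",
          length(raw), nrow(matrix))
  }
  if (any(raw < 0)) stopf("raw intensities must be non-negative")
  if (sum(raw) == 0) stopf("all-zero raw vector: no signal to correct")
  b <- as.numeric(raw) / sum(raw)  # intensity scale does not affect the MID
  # the correction matrix is triangular and nonsingular: direct solve is
  # exact on clean data; fall back to NNLS when noise drives it negative
  x <- tryCatch(solve(matrix, b), error = function(e) rep(-1, length(b)))
  if (any(x < -1e-8)) x <- pracma::lsqnonneg(matrix, b)$x
  x[x < 0] <- 0
  if (sum(x) == 0) stopf("degenerate correction solution (all zero)")
  x / sum(x)
}

#' Labeled fraction M+m of a corrected MID
#'
#' @param corrected_mid fraction vector from [correct_mid()].
#' @param m isotopologue index, `0 <= m <= n_carbons`.
#' @return The fraction of the `M+m` species.
#' @export
labeled_fraction <- function(corrected_mid, m) {
  assert_scalar_number(m, "m", lower = 0, upper = length(corrected_mid) - 1L)
  if (m != round(m)) stopf("'m' must be an integer")
  corrected_mid[[m + 1L]]
}

#' Normalize intensities to protein content
#'
#' @param intensity numeric vector of metabolite intensities.
#' @param protein_conc positive scalar or vector of protein
#'   concentrations (the per-sample divisor).
#' @return `intensity / protein_conc`.
#' @export
normalize_to_protein <- function(intensity, protein_conc) {
  if (any(protein_conc <= 0)) stopf("protein concentration must be positive")
  intensity / protein_conc
}

#' Default group labels of the five-arm tracing design
#'
#' Roles: proliferating control; senescent + control shRNA; senescent +
#' shHK2; senescent + shHK2 rescued with wild-type HK2; senescent +
#' shHK2 rescued with catalytic-mutant HK2.
#'
#' @return Named character vector with roles `control`, `sen`, `kd`,
#'   `wt`, `mut`.
#' @export
tracing_groups <- function() {
  c(control = "control", sen = "sen_shControl", kd = "sen_shHK2",
    wt = "sen_shHK2_wtHK2", mut = "sen_shHK2_mutHK2")
}

#' Three-criterion metabolite screen
#'
#' Per metabolite, tests on replicate labeled fractions with two-tailed
#' t-tests at level `alpha`:
#' criterion (a) more extensive labeling in senescent than control
#' cells; (b) decreased labeling in senescent cells on HK2 knockdown;
#' (c) the decrease is rescued by wild-type HK2 (significant increase
#' over knockdown) but not by the catalytic mutant (mutant not
#' significantly above knockdown). `passes_all` is the conjunction.
#'
#' @param fractions data frame with columns `metabolite`, `group`,
#'   `replicate`, `fraction` (one labeled fraction per replicate).
#' @param alpha significance level (default 0.05).
#' @param groups named character vector mapping roles to group labels;
#'   see [tracing_groups()].
#' @param var_equal equal-variance Student's t (default `TRUE`);
#'   `FALSE` gives the Welch variant.
#' @param mutant_effect_gate additionally require the mutant-rescue mean
#'   to lie below the midpoint of the knockdown and wild-type means
#'   (default `FALSE`).
#' @return Data frame, one row per metabolite: criterion booleans,
#'   per-criterion p-values, `testable`, `passes_all`. Metabolites with
#'   a missing group or fewer than 2 replicates in any group are flagged
#'   untestable.
#' @export
screen_metabolites <- function(fractions, alpha = 0.05,
                               groups = tracing_groups(),
                               var_equal = TRUE,
                               mutant_effect_gate = FALSE) {
  assert_scalar_number(alpha, "alpha", 0, 1)
  stopifnot(all(c("control", "sen", "kd", "wt", "mut") %in% names(groups)))
  mets <- sort(unique(fractions$metabolite))
  rows <- lapply(mets, function(met) {
    sub <- fractions[fractions$metabolite == met, , drop = FALSE]
    vals <- lapply(groups, function(g) sub$fraction[sub$group == g])
    if (any(vapply(vals, length, integer(1L)) < 2L)) {
      return(data.frame(metabolite = met, testable = FALSE,
                        criterion_a = NA, criterion_b = NA, criterion_c = NA,
                        p_a = NA_real_, p_b = NA_real_, p_c_wt = NA_real_,
                        p_c_mut = NA_real_, passes_all = FALSE,
                        stringsAsFactors = FALSE))
    }
    tt <- function(x, y) stats::t.test(x, y, var.equal = var_equal)$p.value
    p_a <- tt(vals$sen, vals$control)
    p_b <- tt(vals$kd, vals$sen)
    p_c_wt <- tt(vals$wt, vals$kd)
    p_c_mut <- tt(vals$mut, vals$kd)
    a <- mean(vals$sen) > mean(vals$control) && p_a < alpha
    b <- mean(vals$kd) < mean(vals$sen) && p_b < alpha
    mut_rescues <- mean(vals$mut) > mean(vals$kd) && p_c_mut < alpha
    cc <- mean(vals$wt) > mean(vals$kd) && p_c_wt < alpha && !mut_rescues
    if (cc && mutant_effect_gate) {
      cc <- mean(vals$mut) < (mean(vals$kd) + mean(vals$wt)) / 2
    }
    data.frame(metabolite = met, testable = TRUE,
               criterion_a = a, criterion_b = b, criterion_c = cc,
               p_a = p_a, p_b = p_b, p_c_wt = p_c_wt, p_c_mut = p_c_mut,
               passes_all = a && b && cc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(!out$testable)) {
    warnf("%d metabolite(s) untestable (missing group or < 2 replicates)",
          sum(!out$testable))
  }
  rownames(out) <- NULL
  out
}
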