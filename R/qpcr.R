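# Comparative-Ct quantitation utilities shared by expression, 3C and
# polysome analyses.

# geometric mean of reference-gene Ct values; a single gene degenerates
# to that gene's Ct
geo_mean_ct <- function(ct) {
  ct <- as.numeric(ct)
  if (any(!is.finite(ct)) || any(ct <= 0)) stopf("Ct values must be positive and finite")
  exp(mean(log(ct)))
}

#' 2^-ddCt relative fold change
#'
#' Computes `dCt = target_ct - reference_ct` for sample and calibrator,
#' `ddCt = dCt(sample) - dCt(calibrator)`, and returns `2^-ddCt`.
#' Multiple reference genes are combined by the geometric mean of their
#' Cts before the subtraction. Vectorized over samples.
#'
#' @param target_ct,reference_ct sample Cts. `reference_ct` may be a
#'   vector (one reference gene, one value per sample) or a matrix with
#'   one row per sample and one column per reference gene.
#' @param calib_target_ct,calib_reference_ct calibrator Cts, same shapes
#'   as above (single calibrator, recycled across samples).
#' @return Numeric vector of fold changes (strictly positive;
#'   identically 1 when sample equals calibrator).
#' @examples
#' ddct_fold_change(20, 18, 22, 18)  # dCt 2 vs 4 -> fold 4
#' @export
ddct_fold_change <- function(target_ct, reference_ct,
                             calib_target_ct, calib_reference_ct) {
  ref <- if (is.matrix(reference_ct)) {
    apply(reference_ct, 1L, geo_mean_ct)
  } else {
    vapply(as.numeric(reference_ct), geo_mean_ct, numeric(1L))
  }
  calib_ref <- geo_mean_ct(calib_reference_ct)
  if (any(!is.finite(c(target_ct, calib_target_ct))) ||
      any(c(target_ct, calib_target_ct) <= 0)) {
    stopf("Ct values must be positive and finite")
  }
  dct <- target_ct - ref
  dct_cal <- mean(calib_target_ct) - calib_ref
  2^-(dct - dct_cal)
}

#' Relative ligation frequency from 3C-qPCR Ct panels
#'
#' Comparative-Ct quantitation across anchor-primer pairs: per pair,
#' the relative quantity versus a calibrator sample is
#' `2^-(dCt_sample - dCt_calibrator)` with `dCt` the target minus
#' loading-control Ct. The non-peak control (NPC) pair is flagged in the
#' output as the background reference; when no NPC is identified a
#' warning is issued and quantities are still returned.
#'
#' @param ct data frame with columns `pair`, `target_ct`,
#'   `reference_ct` for the sample of interest.
#' @param calibrator data frame with the same columns for the
#'   calibrator sample (matched by `pair`).
#' @param npc name of the non-peak control pair, or `NA`.
#' @return Data frame with `pair`, `rel_frequency`, `is_npc`.
#' @export
ligation_frequency <- function(ct, calibrator, npc = "NPC") {
  need <- c("pair", "target_ct", "reference_ct")
  stopifnot(all(need %in% names(ct)), all(need %in% names(calibrator)))
  idx <- match(ct$pair, calibrator$pair)
  if (anyNA(idx)) {
    stopf("calibrator lacks primer pair(s): %s",
          paste(ct$pair[is.na(idx)], collapse = ", "))
  }
  if (any(!is.finite(c(ct$target_ct, ct$reference_ct,
                       calibrator$target_ct, calibrator$reference_ct)))) {
    stopf("Ct values must be finite")
  }
  # calibrator dCt is taken pair-by-pair
  fold <- 2^-((ct$target_ct - ct$reference_ct) -
                (calibrator$target_ct[idx] - calibrator$reference_ct[idx]))
  is_npc <- !is.na(npc) & ct$pair == npc
  if (!is.na(npc) && !any(is_npc)) {
    warnf("non-peak control pair '%s' not found; absolute quantities returned without background reference",
          npc)
  }
  data.frame(pair = ct$pair, rel_frequency = fold, is_npc = is_npc,
             stringsAsFactors = FALSE)
}

#' Translational efficiency
#'
#' Polysome-associated mRNA signal normalized to the free mRNA level of
#' the same gene. By default callers pass the summed monosome +
#' polysome fraction signal as `polysome_level`.
#'
#' @param polysome_level non-negative numeric vector.
#' @param free_level strictly positive numeric vector.
#' @return `polysome_level / free_level`, element-wise.
#' @export
translational_efficiency <- function(polysome_level, free_level) {
  if (any(free_level <= 0)) stopf("free mRNA level must be positive")
  if (any(polysome_level < 0)) stopf("polysome signal must be non-negative")
  polysome_level / free_level
}
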