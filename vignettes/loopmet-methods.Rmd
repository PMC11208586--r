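---
title: "Methods: loop-transcription-m6A-tracing integration in loopmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loop-transcription-m6A-tracing integration in loopmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopmet)
```

`loopmet` connects four senescence readouts — HiChIP chromatin loops,
nascent-transcription fold changes, m⁶A peak calls and ¹³C-glucose
isotopologue intensities — through a set of small, explicitly specified
procedures. This vignette describes each procedure, its assumptions,
the tunable parameters and their defaults, the numerical choices, and
what the synthetic-data tests do and do not establish.

## Coordinate conventions

All genomic coordinates inside the package are 0-based, half-open
`[start, end)`. BED-family inputs (BEDPE loops, BED12 gene models, peak
tables) are read as-is; GTF input is converted from 1-based inclusive
on entry. The TSS of a `+` strand gene is its `start`; of a `-` strand
gene its last base, `end - 1`. Overlap anywhere in the package means a
shared length of at least 1 bp under the half-open convention; two
intervals that merely touch do not overlap. Every interval table
crossing a module boundary is validated against these rules.

## Loop significance and distance classes

H3K27Ac HiChIP loops are significant when `fdr < 0.01` with at least 4
supporting reads; METTL3 HiChIP loops when `fdr < 0.05`. The METTL3
rule deliberately carries no read floor — the two assays' published
thresholds differ, and attaching the read floor only to the stricter
FDR rule reproduces that asymmetry; both the FDR cut and the floor are
arguments of `filter_significant_loops()` for sensitivity analysis.
The FDR column is treated as an opaque probability: loop callers
differ in whether it is a q-value or a permutation FDR, and nothing
downstream depends on the distinction.

Loop distance is the absolute separation of the two anchor midpoints.
Anchor widths vary with restriction-fragment padding, so midpoint
separation is more stable than gap distance; this choice only matters
near class boundaries. The classes are short (`d < 5` kb), medium
(`5 kb <= d <= 2 Mb`) and long (`d > 2 Mb`): the outer inequalities
are strict and the medium class is closed on both ends, which makes
the three printed ranges a true partition (checked on 10⁴ random loops
including the boundary separations 4,999/5,000/2,000,000/2,000,001).
Inter-chromosomal loops are reported as `trans` and excluded from the
three distance classes, which are defined for intra-chromosomal
contacts only.

## Promoters, EP assignment and ΔEP#

Promoter windows are `TSS ± 1 kb` (clipped at the chromosome start),
symmetric and therefore strand-independent. A significant loop is an
enhancer–promoter (EP) interaction when **either** anchor overlaps at
least one promoter window; the gene set attributed to the loop is the
union over both anchors, so a promoter–promoter loop counts for every
gene it touches — "either side" is read inclusively. When both anchors
of one loop hit the same gene's promoter the loop still counts once
for that gene: EP# counts loops per (loop, gene) pair, not per anchor.
This is the more conservative reading; the alternative (per anchor)
would double-count self-loops around dense promoters.

EP# is the per-gene count of EP loops in one condition and
`delta_ep = EP#(senescent) − EP#(growing)` by default, so that
enhanced contacts in senescence are positive — matching the narrative
direction ("enhanced chromatin contacts"). The printed methods
convention elsewhere uses the opposite order, so the sign is a flag
(`sign = "baseline_minus_treatment"`) and both orientations are
covered by tests.

Overlap is computed with GenomicRanges; an independent brute-force
all-pairs oracle lives in the test suite and the acceptance script,
and EP assignment must match it exactly on every random instance.

## ICE balancing and display capping

`ice_balance()` removes multiplicative per-bin biases from a symmetric
non-negative contact matrix. Each round estimates the bias vector from
the row sums, renormalizes it to mean 1 over bins with signal, and
divides every entry by the product of its row and column biases. The
default is a fixed 30 rounds; an optional tolerance stops early when
the coefficient of variation of the active row sums falls below it.
Bins with a zero marginal on input are excluded from bias estimation
and stay exactly zero, and the output is rescaled to the input's total
mass, so the balanced matrix is comparable in magnitude to the raw
one. On random positive 50×50 matrices 30 rounds drive the row-sum CV
below 10⁻⁶ with mass conserved to 10⁻⁹ and symmetry preserved.

For display, `cap_top_quantile()` truncates values above the
`(1 − q)` quantile of the nonzero entries (default `q = 0.05`: the
maximum displayed intensity corresponds to the top-5% score). The
quantile is computed as an attained data value (inverse ECDF, type 1)
rather than by interpolation: with an interpolated threshold the set of
nonzero values changes after capping and a second cap would truncate
again, whereas the type-1 threshold makes capping exactly idempotent.

## Grouped resampling of expression against ΔEP#

Per-gene fold changes are noisy and heavy-tailed; correlating raw
(ΔEP#, log FC) pairs lets a handful of outliers dominate. The
resampling estimator bins genes by their ΔEP# value and, within each
bin, draws 70 genes 200 times, recording each draw's mean log₂ fold
change; the per-bin grand mean is then correlated with the bin's ΔEP#
(Pearson, two-sided *p* from the *t* transform). Bins with at least 70
genes are drawn without replacement; smaller bins — including
singletons — are drawn with replacement rather than dropped, so sparse
ΔEP# tails stay on the curve; the per-bin `n_genes` and `replace`
columns expose where this happened. The draw seed is an explicit
argument: a fixed seed is bit-reproducible, and changing it changes
draw means but never bin membership. With exactly two bins the
correlation is ±1 by construction and its *p*-value is reported as
`NA` (the *t* transform has zero degrees of freedom); at least three
bins are required for inference.

Under the generator's planted coupling
(`log_fc = 0.05 · delta_ep + N(0, 0.1)`, 500 genes, ΔEP# ∈ −3…+3) the
estimator recovers *r* > 0.9 in ≥ 19/20 seeds, and under a planted
null slope its *p* exceeds 0.05 in ≥ 90/100 seeds — a type-I sanity
check at the bin level.

## The candidate funnel

`select_mtc_dependent_genes()` intersects three differential calls:
up in senescence, down on METTL3 knockdown, down on METTL14 knockdown.
No published thresholds exist for these calls, so the defaults are the
field's conventional `|log₂FC| ≥ 1` with adjusted `p < 0.05`, fully
configurable and recorded in the run manifest. The default combination
requires both knockdowns (the Venn-overlap reading); `mode = "either"`
implements the weaker prose reading ("METTL3 or METTL14"). The funnel
is monotone: tightening any threshold never adds a gene.
`intersect_enhanced_contacts()` then keeps candidates with strictly
positive ΔEP# (a gene with unchanged contacts is not
"contact-enhanced") and attaches the (ΔEP#, log FC) pairs on which
`correlate_candidates()` computes the final Pearson correlation — the
resampled curve and the raw candidate correlation are two distinct
operations, and both are exposed.

## m⁶A polymethylation

Peak callers split summits, so "unique sites" are defined by merging
overlapping peaks within a transcript (merged signal = the maximum of
the members). Each merged site is assigned to the 5′UTR/CDS/3′UTR
segment containing its midpoint — the simplest unambiguous rule for a
peak spanning a junction; a site whose midpoint lies in no annotated
segment keeps an `NA` region but still counts toward the transcript.
A transcript is polymethylated when it has **strictly more than
three** sites: exactly three is never called, four always is, and
raising the threshold can only shrink the set. The package accepts
either genomic or transcript-space peak coordinates, provided peaks
and catalog share a frame; which frame was used is the caller's
declaration, not an inference. The per-transcript representative
signal is the highest site signal, the quantity used when comparing
polymethylated signal between conditions (default condition-comparison
threshold 1.5×, configurable). The downregulation intersection reuses
the funnel's (1, 0.05) thresholds for consistency.

## Isotopologue correction and the metabolite screen

Measured isotopologue intensities mix tracer-derived ¹³C with natural
¹³C (abundance 0.0107 by default, exposed as `p13c`). For a metabolite
with *n* carbons the measured vector is `M · x` where `x` is the true
mass-isotopomer distribution (MID) and column *k* of `M` is the
binomial mass of the `n − k` unlabeled positions shifted by *k*; every
column sums to 1 and `M` is lower triangular. Correction solves for
`x ≥ 0`: the package inverts the triangular system directly (exact on
clean data, after normalizing the raw vector — the MID is scale-free)
and falls back to non-negative least squares (`pracma::lsqnonneg`)
whenever noise drives the inverse negative, then renormalizes to sum 1.
Corrected MIDs are therefore non-negative and sum to one by
construction. Only carbon is corrected; N/H/O isotopes are a documented
simplification consistent with analyzing carbon isotopologues. On
random MIDs up to 12 carbons the forward-convolve/correct round trip is
exact to 10⁻⁹, and 1% multiplicative noise perturbs entries by less
than 0.02.

The screen takes one labeled fraction per replicate — the diagnostic
`M+m` entry (M+5 for the purine-derived species, since five ribose
carbons come from glucose), not the summed `1 − M+0`, which is also
computable — across the five-group design with *n* = 3 replicates.
Criteria, each by two-tailed Student's *t* (equal variances by
default; Welch by flag) at `alpha = 0.05`: (a) senescent shControl
above control; (b) shHK2 below shControl; (c) wild-type rescue above
shHK2 **and** mutant rescue not significantly above shHK2. "Not by the
mutant" is encoded as non-significance of the mutant-vs-knockdown
increase; an optional effect-size gate additionally requires the
mutant mean below the midpoint of the knockdown and wild-type means.
A metabolite missing a group or replicates is flagged untestable and
never passes. Criteria (a) and (b) are monotone in `alpha`; (c) is
not, because the mutant arm flips direction — which is why it is
reported with both of its *p*-values.

## Comparative-Ct utilities

`ddct_fold_change()` implements 2^−ΔΔCt with reference-gene Cts
combined by geometric mean (a single reference degenerates correctly);
fold changes are strictly positive and invariant to a global Ct shift.
3C-qPCR ligation frequencies use the same comparative-Ct transform
pair-by-pair against a calibrator sample, with the non-peak control
(NPC) pair flagged as the background reference — the NPC convention is
an inference from common assay design, and a missing NPC degrades to a
warning rather than an error. Translational efficiency is
polysome-associated signal over free-mRNA signal; which gradient
fractions enter the numerator is the caller's grouping decision, with
summed monosome + polysome as the documented default.

## The synthetic-data generator

The generator emulates the study's data shapes at roughly 1/10 scale
so the full suite runs in minutes: 500 genes on two 25-Mb chromosomes,
planted ΔEP# drawn from −3…+3 realized as actual promoter-anchored
loops (one anchor in the promoter window, the other 10 kb–1.5 Mb away
and kept clear of all promoter windows), ~2,000 loops per run,
expression coupled to ΔEP# with slope 0.05 and Gaussian noise SD 0.1,
a 10-gene knockdown-reversed contact-enhanced subset, 52 polymethylated
transcripts of which 4 downregulated (the published funnel's 523 → 35
shape at 1/10, rounded), a four-metabolite tracing panel over the
five-group design with 3 replicates, and Ct tables with 0.2-cycle
noise. Noise models are the conventional ones for each platform —
Gaussian on log fold-changes and Cts, lognormal multiplicative on
intensities — with all levels exposed in `generator_config()`.

Choices worth stating. Background loops are generated to fail the
significance filter *and* avoid promoters, so planted EP counts
round-trip exactly; recovery tests would otherwise need a tolerance
that hides real off-by-one errors. Planted differential genes receive
small adjusted *p* and all other genes draw `padj` above 0.05: the
generator plants calls, it does not simulate a differential test, so
funnel recovery is exact rather than approximate. In the tracing
panel the mutant-rescue means sit at or slightly below the knockdown
means: the planted truth "the mutant does not rescue" must not place
the mutant above the knockdown within replicate noise, or the truth
itself would be ambiguous. Each generator seeds its own stream from
the master seed plus a fixed offset, so regenerating one data type
never perturbs another and every generator is a pure function of its
config.

What passing these tests shows — and does not. Exact planted-truth
recovery demonstrates that the bookkeeping (interval logic, counting,
thresholds, set algebra, solver) is correct, and the noisy variants
show the statistical operations behave at realistic effect-to-noise
ratios. It does not validate upstream loop calling, peak calling or
differential testing (all out of scope), nor does it establish that
real HiChIP FDRs, m⁶A peak structure or LC-MS noise match the
generator's idealizations: real anchors overlap multiple promoters,
real padj values correlate with fold changes, and real isotopologue
noise is heteroscedastic. Results on real data should therefore be
read through the configurable thresholds, not the defaults alone.

## Pipeline and reproducibility

`run_pipeline()` executes io → loops → integration and io → m6a,
io → tracing from a single seeded config (R list or YAML), writing
deterministic CSVs and a `manifest.json` that records the package
version, every result-affecting parameter, and per-file checksums and
row counts. Reruns skip stages whose config fingerprint and output
checksums are unchanged; `force = TRUE` overrides. Two runs from one
config are byte-identical — the manifest contains no timestamps for
exactly this reason. Problem sizes in the test suite are scaled to the
generator's defaults or below (60–200 genes for most unit tests, the
full 500-gene default for the funnel cardinalities), which keeps the
complete suite and the acceptance script within a few minutes on one
CPU.

## Known limitations

- EP counting ignores loop strength: a loop with 4 reads and one with
  400 contribute equally to EP#.
- Region assignment by midpoint misattributes peaks that straddle a
  UTR/CDS junction asymmetrically.
- Carbon-only natural-abundance correction slightly over-estimates
  high-mass isotopologues for N-rich metabolites.
- The ligation-frequency NPC is reported, not subtracted; background
  correction policy is left to the caller.
- With two ΔEP# bins the resampling correlation has no p-value; the
  estimator is descriptive there.
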