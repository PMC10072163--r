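---
title: "Calling MET amplification versus chromosome 7 polysomy from targeted NGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling MET amplification versus chromosome 7 polysomy from targeted NGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metpoly)
```

## The problem

A raised MET gene copy number on a targeted NGS panel is ambiguous. It can
reflect focal amplification of the MET locus — an oncogenic driver and a
target for MET inhibitors — or polysomy of chromosome 7, where the whole
chromosome (or arm) is present in extra copies and the MET gain is merely
proportional. FISH separates the two with the MET/CEP7 ratio, because the
centromere count rises along with the gene under polysomy; a single-gene
copy number from NGS cannot. The distinction matters clinically: patients
with polysomy respond poorly to MET inhibition compared with patients with
focal amplification.

`metpoly` makes the distinction from the NGS data alone by looking at the
*spatial extent* of the copy-number gain along chromosome arm 7q. Focal
amplification is confined to a small window around MET; polysomy raises the
whole arm; an intermediate "pan-MET" gain covers a substantial contiguous
stretch containing the locus.

## The procedure

The input is a per-bin copy-number table as produced by an upstream panel
CNV caller (capture bins of roughly 120 bp over targeted genes, off-target
bins of roughly 150 kb elsewhere), already normalised against a
leukocyte background so that the diploid level is 2.0 linear copies.
Coverage normalisation itself is upstream and out of scope here.

1. **Band aggregation** (`assign_bins_to_bands()`). Off-target bins on 7q
   are assigned to the cytoband containing the bin midpoint. Bands with
   fewer than 2 bins cannot support a t-test and are pre-merged into the
   neighbouring band with the closer mean copy number (a band with no bins
   at all is absorbed leftwards, a degenerate rule that only conserves
   genomic extent).
2. **Between-band tests** (`band_ttest()`). Every pair of bands is compared
   with a two-sided Welch t-test on their bin copy numbers. P values at or
   above 0.1 are treated as "no difference". A pooled-variance test can be
   selected (`segmentation_config(var_equal = TRUE)`); the Welch default
   makes no equal-variance assumption across bands of different coverage.
   When both bands have zero variance the P value is defined as 1 for equal
   means and 0 otherwise.
3. **Region formation** (`form_initial_regions()`). Regions grow greedily
   left to right; a band joins the current region only while it shows no
   significant difference from *every* band already in the region. The
   "every band" reading is the stricter of the two plausible
   interpretations of a region with "no significant internal differences";
   the adjacent-only variant is available via
   `segmentation_config(pair_rule = "adjacent")`.
4. **Region merging** (`merge_regions()`). For each adjacent pair of
   regions, let f be the fraction of cross-region band pairs without a
   significant difference. The pair merges when (i) f exceeds 50%, or
   (ii) the larger region has more than seven bands and f exceeds 30%.
   The leftmost eligible pair merges first, region statistics are
   recomputed from the member bins, and sweeps repeat until a fixpoint.
   Because band profiles never change after pre-merging, all tests are
   computed once on a band-pair matrix.
5. **Gain calling and arm fraction** (`amplified_fraction()`). A region is
   a copy-number gain (CNG) when its mean copy number over all member bins
   (bins, not band means, are the measurement unit) is strictly above 2.3.
   The amplified fraction is the summed genomic length of CNG regions over
   the arm span.
6. **Status call** (`met_decision_rule()`, `classify_met()`). With the MET
   gene copy number (mean of the MET capture bins, or supplied externally):
   below 2.3 is **negative**; otherwise an amplified fraction at or above
   80% is **polysomy**; otherwise a MET-band region without gain, or a
   fraction at or below 10%, is **MET amplification**; the remainder (MET
   region gained, 10–80% of the arm) is **pan-MET amplification**.
   Evaluating the polysomy clause before the amplification clause is what
   makes the overlapping published conditions deterministic: a gained MET
   region covering 85% of the arm is polysomy, never focal amplification.

Boundary semantics throughout follow the wording they derive from:
"higher than" thresholds (merge fractions, CNG 2.3) are strict,
"P ≥ 0.1", the 10% and the 80% fraction boundaries are inclusive, so a
fraction of exactly 0.10 with a gained MET region is amplification and
exactly 0.80 is polysomy, while a gene copy number of exactly 2.3 is not
negative.

The MET anchor band is located from the MET capture bins by default. The
band label 7q31.2 contains the MET locus in standard band maps; published
descriptions of the method sometimes anchor on 7q32.1 instead, and the
anchor is therefore overridable (`met_band =`) rather than asserted.

## The cutoff and the agreement statistics

The 2.3-copy threshold separating polysomy from normal copy number is a
Youden-optimal ROC cutoff (`roc_curve()`): candidate thresholds are
midpoints between consecutive sorted unique copy numbers plus sentinels,
a sample is positive when its value is at or above the threshold, the AUC
is the Mann–Whitney rank statistic with ties counted half, and among
thresholds tied on J = sensitivity + specificity − 1 the smallest is
reported (the most sensitive operating point, fitting a screening use).
`bootstrap_auc_ci()` adds a stratified percentile bootstrap interval; the
percentile method is a choice, not a reproduction of any published CI
mechanics, and like all percentile intervals it undercovers when the AUC
sits near 1.

Method agreement is summarised by `confusion()` (test on rows, reference
on columns — the orientation is fixed here because published tables leave
it implicit), one-vs-rest `class_metrics()` per status, and unweighted
`cohen_kappa()`. Metrics with a zero denominator are reported as
undefined (`NA`), never as 0, because several published plasma metrics are
not reconstructible from printed counts and silently zeroed cells would
fabricate agreement. Displayed percentages use round-half-up at one
decimal (tissue metrics) or to the nearest percent (the stratified plasma
metrics), via `as_percent()`.

On the bundled 53-patient tissue cohort (`example_fish_ngs_cohort()`) the
standard kappa formula gives 1498/1657 ≈ 0.904; the value printed in the
source cohort's report (0.886) is not derivable from its own matrix by
the standard formula, so this package reports the formula value and
documents the discrepancy rather than matching it.

For tissue–plasma comparison, `stratified_agreement()` computes positive
and negative percent agreement (the tissue call is a comparator, not a
gold standard) within a filtered subset — typically plasma MSAF above 5%,
MSAF being the maximum somatic variant allele fraction and a proxy for
ctDNA content (`msaf()`). The bundled 261-pair cohort
(`example_tissue_plasma_cohort()`) is reconstructed from published
aggregate counts; its documentation lists exactly which cells the counts
pin down and which are filled by convention.

## The synthetic generator

`simulate_tissue_profile()` emulates the panel's data model on a bundled
synthetic chromosome 7 (15 q-bands over a 100 Mb arm, MET inside q31.2):
150 kb off-target bins tile every band (about 40 bins per band, enough
that between-band tests are well powered) and 20 capture bins of 120 bp
cover MET. Event geometry is exact by construction — the focal window is
the MET band (7% of the arm), polysomy raises the whole chromosome, and
the pan-MET window grows band-aligned around MET until it reaches its
target fraction (drawn uniformly on 0.15–0.60), so truth fractions snap
to band boundaries. Default event magnitudes: focal height uniform on
5–15 copies, arm gain uniform on 2.5–4 copies.

Per-bin noise is Gaussian on the linear copy-number scale with SD 0.15
(tissue) and 0.25 (plasma); no noise model is published for the assay, and
these defaults were chosen once so that tissue calling is near-perfect
while plasma calling degrades at low ctDNA content, mirroring the
qualitative published pattern. `simulate_plasma_profile()` attenuates the
tissue signal as `2 + tf · (cn − 2)` for tumour fraction `tf` and reports
MSAF as `min(1, tf/2)` (a heterozygous clonal variant carries roughly half
the tumour fraction as allele fraction). `simulate_cohort()` draws
statuses multinomially, derives per-sample seeds deterministically from
the master seed, and can emit FISH raw counts consistent with the truth;
FISH has no pan-MET category, so pan events present amplification-like
ratios there.

What the generator does *not* model: GC and mappability bias, read-level
sampling, segmentation artefacts of the upstream caller, subclonal
heterogeneity, and focal events not centred on MET. Passing recovery tests
on this generator therefore demonstrates the internal consistency of the
segmentation and decision rule under the stated noise model, not clinical
performance on real libraries.

## Numerical and design notes

* Coordinates are 0-based half-open everywhere (UCSC/BED convention),
  matching both input dialects; bins are assigned to arms by band lookup,
  never by a hard-coded centromere.
* QC gates (`qc_check()`): more than 98% of exons at ≥ 100X (strict),
  mean depth ≥ 200X and mapping rate ≥ 95% (inclusive) — strictness taken
  literally from the wording each derives from.
* The merge sweep is deterministic (leftmost-first, recompute after each
  merge); ties cannot arise under this order. Whether eligibility should
  be re-tested mid-sweep or end-of-sweep is not specified anywhere;
  recompute-after-each-merge was chosen and is what the brute-force
  oracle in the test suite replicates.
* No multiplicity correction is applied to the band t-tests, by design:
  the procedure being implemented applies none.
* Test problem sizes: the segmentation is checked against a brute-force
  enumeration of all contiguous band partitions on arms of up to 8 bands
  (500 random profiles), truth recovery on 200 default-noise synthetic
  tissue samples, and cutoff recovery on 100 simulated 10-vs-30 cohorts;
  these sizes give the properties enough resolution while keeping the
  suite quick to run.

## Worked example

```{r example}
spec <- synthetic_spec(status = "pan_met_amplification", seed = 42)
prof <- simulate_tissue_profile(spec)
call <- call_met_status(prof$bins, synthetic_band_map(), sample = "demo")
call
call$segmentation$regions[, c("start_band", "end_band", "n_bins",
                              "mean_cn", "is_cng", "contains_met")]
```

## Limitations

* Tumour purity is not corrected for (the upstream pipeline this mirrors
  does none); low-purity tissue behaves like low-tumour-fraction plasma.
* The polysomy-vs-normal cutoff of 2.3 was established on one cohort with
  one panel; other assays should re-derive it with `roc_curve()` on their
  own labelled data.
* The published per-patient copy numbers behind the cutoff cohort are not
  available, so its AUC and CI are exercised only on synthetic analogues.
* FISH polysomy has no published rule; `classify_fish()` implements the
  simplest rule consistent with the three published discordant cases
  (ratio first, then mean copies ≥ 5) and accepts external labels instead.
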