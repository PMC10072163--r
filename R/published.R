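# Example cohorts reconstructed from aggregate counts reported in the
# clinical literature on NGS-based MET status calling in NSCLC. Only
# summary counts were published; these constructors expand them into
# per-sample tables. Where the published text does not pin a cell down,
# the choice made here is arbitrary and documented inline — such cells
# must not be used as comparison targets.

#' Example tissue cohort: FISH vs NGS MET status in 53 patients
#'
#' The published 3x3 confusion matrix of a 53-patient NSCLC tissue cohort
#' typed by both FISH (reference) and NGS: NGS rows
#' amplification (13, 0, 0), polysomy (0, 9, 1), negative (1, 1, 28)
#' against FISH columns amplification / polysomy / negative.
#'
#' @return A `confusion_matrix` (see [confusion_from_counts()]).
#' @seealso [confusion_pairs()] to expand into the 53 sample pairs.
#' @export
example_fish_ngs_cohort <- function() {
  confusion_from_counts(
    matrix(c(13, 0, 0,
             0, 9, 1,
             1, 1, 28), nrow = 3, byrow = TRUE),
    classes = c("amplification", "polysomy", "negative")
  )
}

#' Example paired cohort: tissue vs plasma NGS MET status in 261 patients
#'
#' Reconstruction of a published 261-patient NSCLC cohort with concurrent
#' tissue and plasma NGS. The published counts fix: tissue calls of 19
#' amplification / 8 pan-MET amplification / 48 polysomy / 186 negative;
#' plasma-concordant calls in 10 / 2 / 6 / 181 of them; no false-positive
#' plasma amplification; all 42 discordant tissue-polysomy cases negative
#' in plasma; 10 tissue-amplification patients with plasma MSAF > 5\%, 7 of
#' them plasma-amplified; 12 tissue-polysomy patients with MSAF > 5\%, 5 of
#' them plasma-polysomy; 6 tissue-amplification patients with plasma EGFR
#' VAF > 5\%, 3 of them plasma-amplified; 8 tissue-polysomy patients with
#' plasma EGFR VAF > 0.5\%, 1 of them plasma-polysomy.
#'
#' Unpinned cells are filled by convention: the 5 discordant
#' tissue-negative cases are set to plasma polysomy, the 6 discordant
#' tissue-pan cases to plasma negative, and MSAF / EGFR VAF values are
#' placed at 0.10 / 0.01 (above/below the 5\% gate) rather than real
#' measurements.
#'
#' @return A `data.frame` of paired samples (see [read_paired_samples()]).
#' @export
example_tissue_plasma_cohort <- function() {
  block <- function(n, tissue, plasma, msaf, egfr) {
    if (n == 0) return(NULL)
    data.frame(tissue_status = rep(tissue, n), plasma_status = rep(plasma, n),
               msaf_plasma = rep(msaf, n), egfr_vaf_plasma = rep(egfr, n),
               stringsAsFactors = FALSE)
  }
  hi <- 0.10; lo <- 0.01; e_hi <- 0.08; e_lo <- 0.003
  d <- rbind(
    # tissue amplification (19): 10 plasma-amplified, 9 plasma-negative;
    # MSAF > 5% in 10 (7 of the plasma-amplified); EGFR > 5% in 6 (3 amplified)
    block(3, "amplification", "amplification", hi, e_hi),
    block(4, "amplification", "amplification", hi, e_lo),
    block(3, "amplification", "amplification", lo, e_lo),
    block(3, "amplification", "negative", hi, e_hi),
    block(6, "amplification", "negative", lo, e_lo),
    # tissue pan-MET amplification (8): 2 concordant, 6 plasma-negative
    block(2, "pan_met_amplification", "pan_met_amplification", hi, e_lo),
    block(6, "pan_met_amplification", "negative", lo, e_lo),
    # tissue polysomy (48): 6 plasma-polysomy, 42 plasma-negative;
    # MSAF > 5% in 12 (5 of the plasma-polysomy); EGFR > 0.5% in 8 (1 polysomy)
    block(5, "polysomy", "polysomy", hi, e_lo),
    block(1, "polysomy", "polysomy", lo, 0.01),
    block(7, "polysomy", "negative", hi, 0.01),
    block(35, "polysomy", "negative", lo, e_lo),
    # tissue negative (186): 181 concordant; the 5 discordant cases are
    # plasma polysomy by convention (no plasma amplification FP published);
    # 39 of the concordant negatives carry EGFR VAF > 5% so that 45
    # patients in total pass the EGFR 5% gate
    block(39, "negative", "negative", lo, e_hi),
    block(142, "negative", "negative", lo, e_lo),
    block(5, "negative", "polysomy", lo, e_lo)
  )
  d$sample_id <- sprintf("P%03d", seq_len(nrow(d)))
  d$msaf_tissue <- 0.20
  d[, c("sample_id", "tissue_status", "plasma_status", "msaf_tissue",
        "msaf_plasma", "egfr_vaf_plasma")]
}
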