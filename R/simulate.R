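# Seeded generator of bin-level copy-number profiles with known MET-status
# truth, emulating a hybrid-capture panel's bin structure: short capture
# bins over the MET gene plus 150 kb off-target bins tiling chromosome 7.
# Tissue profiles carry the full tumour signal; plasma profiles attenuate
# it by the circulating tumour fraction.

MET_GENE_START <- 116312000
MET_GENE_END <- 116440000

#' Bundled synthetic chromosome 7 cytoband map
#'
#' A 160 Mb synthetic chromosome with 4 p-bands and 15 q-bands (q arm
#' 60-160 Mb, each q band 6-8 Mb). The MET gene is placed inside band
#' `q31.2`. This is a synthetic coordinate system for simulation and
#' testing, not a genome-build band map.
#'
#' @return Cytoband `data.frame` (see [read_cytobands()]).
#' @export
synthetic_band_map <- function() {
  q <- c(60, 66, 72, 78, 85, 91, 98, 104, 111, 118, 124, 131, 138, 145,
         152, 160) * 1e6
  qnames <- c("q11.21", "q11.22", "q11.23", "q21.11", "q21.12", "q21.3",
              "q22.1", "q31.1", "q31.2", "q31.31", "q31.33", "q32.1",
              "q33", "q34", "q36.1")
  p <- c(0, 5, 25, 45, 60) * 1e6
  pnames <- c("p22.3", "p21.1", "p14.1", "p11.2")
  as_cytobands(data.frame(
    chrom = "chr7",
    start = c(p[-length(p)], q[-length(q)]),
    end = c(p[-1], q[-1]),
    name = c(pnames, qnames),
    stringsAsFactors = FALSE
  ))
}

#' Write the synthetic band map as a UCSC-style cytoBand file
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_cytobands <- function(path) {
  bm <- synthetic_band_map()
  out <- data.frame(bm$chrom, format(bm$start, scientific = FALSE, trim = TRUE),
                    format(bm$end, scientific = FALSE, trim = TRUE), bm$name,
                    "gneg")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Specification of one synthetic sample
#'
#' Holds the generator parameters: the band map, bin structure, per-bin
#' noise, the truth status and its event magnitude, and the plasma tumour
#' fraction. Event magnitudes left `NULL` are drawn when the profile is
#' simulated: focal amplification height uniform on 5-15 copies, arm-gain
#' level uniform on 2.5-4 copies, pan-MET window fraction uniform on
#' 0.15-0.60 of the arm.
#'
#' @param status Truth label, one of [met_statuses()].
#' @param band_map Cytoband `data.frame` (default [synthetic_band_map()]).
#' @param offtarget_bin_size Off-target bin width in bp (default 150000).
#' @param n_met_capture_bins Number of 120 bp capture bins over MET
#'   (default 20).
#' @param noise_sd_tissue,noise_sd_plasma Gaussian per-bin noise SD on the
#'   linear copy-number scale (defaults 0.15 and 0.25).
#' @param focal_cn Focal amplification copy number (`NULL` = draw).
#' @param arm_gain_cn Arm-gain level for polysomy / pan-MET (`NULL` = draw).
#' @param pan_fraction Target arm fraction of the pan-MET window
#'   (`NULL` = draw; must lie in (0.10, 0.80)).
#' @param tumor_fraction Plasma circulating-tumour fraction in `[0, 1]`
#'   (default 1).
#' @param seed RNG seed of this sample.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(status = "negative",
                           band_map = synthetic_band_map(),
                           offtarget_bin_size = 150000,
                           n_met_capture_bins = 20,
                           noise_sd_tissue = 0.15, noise_sd_plasma = 0.25,
                           focal_cn = NULL, arm_gain_cn = NULL,
                           pan_fraction = NULL, tumor_fraction = 1,
                           seed = 1) {
  if (!status %in% met_statuses()) {
    stop_validation(paste0("invalid status: ", status))
  }
  if (noise_sd_tissue < 0 || noise_sd_plasma < 0) {
    stop_validation("noise SDs must be non-negative")
  }
  if (!is.null(pan_fraction) &&
      (pan_fraction <= 0.10 || pan_fraction >= 0.80)) {
    stop_validation("pan_fraction must lie strictly between 0.10 and 0.80")
  }
  if (tumor_fraction < 0 || tumor_fraction > 1) {
    stop_validation("tumor_fraction must lie in [0, 1]")
  }
  structure(
    list(status = status, band_map = band_map,
         offtarget_bin_size = offtarget_bin_size,
         n_met_capture_bins = n_met_capture_bins,
         noise_sd_tissue = noise_sd_tissue,
         noise_sd_plasma = noise_sd_plasma, focal_cn = focal_cn,
         arm_gain_cn = arm_gain_cn, pan_fraction = pan_fraction,
         tumor_fraction = tumor_fraction, seed = seed),
    class = "synthetic_spec"
  )
}

# Contiguous q-band window containing the MET band whose summed extent,
# as a fraction of the arm, first reaches `target`; grown alternately
# left/right so window edges snap to band boundaries and the truth
# fraction is exact.
pan_window_bands <- function(band_map, met_band, target) {
  qb <- band_map[band_map$arm == "q", , drop = FALSE]
  arm_len <- max(qb$end) - min(qb$start)
  i <- which(qb$name == met_band)
  lo <- hi <- i
  frac <- (qb$end[i] - qb$start[i]) / arm_len
  side <- -1L
  while (frac < target && (lo > 1 || hi < nrow(qb))) {
    if (side < 0 && lo > 1) {
      lo <- lo - 1
    } else if (hi < nrow(qb)) {
      hi <- hi + 1
    } else {
      lo <- lo - 1
    }
    side <- -side
    frac <- (qb$end[hi] - qb$start[lo]) / arm_len
  }
  list(names = qb$name[lo:hi], start = qb$start[lo], end = qb$end[hi],
       fraction = frac)
}

#' Simulate a tissue copy-number profile with known truth
#'
#' Off-target bins tile every band of the map; capture bins cover the MET
#' gene (band `q31.2` of the synthetic map). The underlying copy number is
#' 2 everywhere for `negative`; the whole chromosome is raised to the
#' arm-gain level for `polysomy`; the MET band alone is raised to the
#' focal level for `amplification`; and a band-aligned window containing
#' MET covering the pan fraction of the arm is raised to the arm-gain
#' level for `pan_met_amplification`. Observed copy numbers add Gaussian
#' noise. Identical spec and seed give bit-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `tissue_profile`: `bins` (bin `data.frame`),
#'   `underlying` (per-bin true copy number), `status`, `met_band`,
#'   `truth_fraction` (exact arm fraction of the gained window), `level`
#'   (event copy number), `spec`.
#' @export
simulate_tissue_profile <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  bm <- spec$band_map
  level <- switch(spec$status,
    negative = 2,
    amplification = spec$focal_cn %||% stats::runif(1, 5, 15),
    polysomy = spec$arm_gain_cn %||% stats::runif(1, 2.5, 4),
    pan_met_amplification = spec$arm_gain_cn %||% stats::runif(1, 2.5, 4)
  )
  pan_target <- if (spec$status == "pan_met_amplification") {
    spec$pan_fraction %||% stats::runif(1, 0.15, 0.60)
  } else {
    NA_real_
  }

  met_band <- bm$name[bm$arm == "q" & bm$start <= MET_GENE_START &
                        bm$end > MET_GENE_START][1]
  starts <- unlist(lapply(seq_len(nrow(bm)), function(i) {
    seq(bm$start[i], bm$end[i] - spec$offtarget_bin_size,
        by = spec$offtarget_bin_size)
  }))
  off <- data.frame(chrom = bm$chrom[1], start = starts,
                    end = starts + spec$offtarget_bin_size, gene = "-",
                    stringsAsFactors = FALSE)
  mid <- (off$start + off$end) / 2

  underlying <- rep(2, nrow(off))
  truth_fraction <- 0
  qb <- bm[bm$arm == "q", ]
  arm_len <- max(qb$end) - min(qb$start)
  met_row <- bm[bm$name == met_band, ]
  if (spec$status == "polysomy") {
    underlying[] <- level
    truth_fraction <- 1
  } else if (spec$status == "amplification") {
    win <- mid >= met_row$start & mid < met_row$end
    underlying[win] <- level
    truth_fraction <- (met_row$end - met_row$start) / arm_len
  } else if (spec$status == "pan_met_amplification") {
    w <- pan_window_bands(bm, met_band, pan_target)
    underlying[mid >= w$start & mid < w$end] <- level
    truth_fraction <- w$fraction
  }

  cap_starts <- round(seq(MET_GENE_START, MET_GENE_END - 120,
                          length.out = spec$n_met_capture_bins))
  cap <- data.frame(chrom = bm$chrom[1], start = cap_starts,
                    end = cap_starts + 120, gene = "MET",
                    stringsAsFactors = FALSE)
  cap_underlying <- rep(if (spec$status == "negative") 2 else level,
                        nrow(cap))

  u <- c(underlying, cap_underlying)
  bins <- rbind(
    cbind(off, kind = "offtarget", stringsAsFactors = FALSE),
    cbind(cap, kind = "capture", stringsAsFactors = FALSE)
  )
  bins$cn <- pmax(0, u + stats::rnorm(length(u), 0, spec$noise_sd_tissue))
  bins$log2 <- NA_real_
  bins$depth <- NA_real_
  ord <- order(bins$chrom, bins$start)
  structure(
    list(bins = as_bins(bins[ord, ]), underlying = u[ord],
         status = spec$status, met_band = met_band,
         truth_fraction = truth_fraction, level = level, spec = spec),
    class = "tissue_profile"
  )
}

#' Simulate a plasma profile by tumour-fraction attenuation
#'
#' The underlying plasma copy number of every bin is
#' `2 + tumor_fraction * (tissue_cn - 2)`: at tumour fraction 0 the signal
#' is purely diploid, at 1 it equals the tissue signal. Plasma noise is
#' then added.
#'
#' @param tissue A `tissue_profile` from [simulate_tissue_profile()].
#' @param tumor_fraction ctDNA fraction in `[0, 1]`; defaults to the
#'   spec's value.
#' @param noise_sd Per-bin noise SD (defaults to the spec's plasma SD).
#' @param seed RNG seed (defaults to the spec's seed plus 1).
#' @return List of class `plasma_profile` with `bins`, `underlying`,
#'   `tumor_fraction`, `status`, `met_band`.
#' @export
simulate_plasma_profile <- function(tissue, tumor_fraction = NULL,
                                    noise_sd = NULL, seed = NULL) {
  stopifnot(inherits(tissue, "tissue_profile"))
  tf <- tumor_fraction %||% tissue$spec$tumor_fraction
  if (tf < 0 || tf > 1) stop_validation("tumor_fraction must lie in [0, 1]")
  sd <- noise_sd %||% tissue$spec$noise_sd_plasma
  set.seed(seed %||% (tissue$spec$seed + 1L))
  u <- 2 + tf * (tissue$underlying - 2)
  bins <- tissue$bins
  bins$cn <- pmax(0, u + stats::rnorm(length(u), 0, sd))
  structure(
    list(bins = bins, underlying = u, tumor_fraction = tf,
         status = tissue$status, met_band = tissue$met_band),
    class = "plasma_profile"
  )
}

fish_truth <- function(status) {
  switch(status,
    amplification = {
      cep7 <- stats::runif(1, 2, 3)
      list(mean_gcn = cep7 * stats::runif(1, 2.5, 5), cep7 = cep7)
    },
    pan_met_amplification = {
      # FISH has no pan category; pan events present amplification-like
      cep7 <- stats::runif(1, 2, 3)
      list(mean_gcn = cep7 * stats::runif(1, 2.5, 5), cep7 = cep7)
    },
    polysomy = {
      gcn <- stats::runif(1, 5, 7)
      list(mean_gcn = gcn, cep7 = gcn / stats::runif(1, 1.2, 2))
    },
    negative = {
      gcn <- stats::runif(1, 1.8, 4)
      list(mean_gcn = gcn, cep7 = gcn / stats::runif(1, 0.8, 1.5))
    }
  )
}

#' Simulate a cohort of synthetic samples
#'
#' Statuses are drawn multinomially from `prevalence`; each sample gets a
#' deterministic per-sample seed derived from `seed`, a tissue profile,
#' optionally a plasma profile, and optionally FISH raw counts consistent
#' with its truth (amplification: MET/CEP7 ratio > 2; polysomy: mean MET
#' copies >= 5 with ratio <= 2; negative: below both). The reported MSAF
#' is `min(1, tumor_fraction / 2)` (heterozygous-variant approximation).
#'
#' @param n Number of samples.
#' @param prevalence Named (or [met_statuses()]-ordered) fractions summing
#'   to 1.
#' @param seed Master seed.
#' @param plasma Also simulate plasma profiles? (default `FALSE`)
#' @param tumor_fraction Fixed value, or length-2 range to draw from
#'   uniformly per sample (default `c(0.05, 0.6)`).
#' @param fish Also emit FISH truth? (default `TRUE`)
#' @param ... Further arguments to [synthetic_spec()].
#' @return List of class `synthetic_cohort`; each element has
#'   `sample_id`, `status`, `tissue`, optional `plasma`, optional `fish`,
#'   `tumor_fraction`, `msaf`.
#' @export
simulate_cohort <- function(n, prevalence = c(negative = 0.77,
                                              amplification = 0.01,
                                              pan_met_amplification = 0.03,
                                              polysomy = 0.19),
                            seed = 1, plasma = FALSE,
                            tumor_fraction = c(0.05, 0.6), fish = TRUE,
                            ...) {
  if (abs(sum(prevalence) - 1) > 1e-9) {
    stop_validation("prevalence fractions must sum to 1")
  }
  if (is.null(names(prevalence))) names(prevalence) <- met_statuses()
  set.seed(seed)
  statuses <- sample(names(prevalence), n, replace = TRUE,
                     prob = prevalence)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  tfs <- if (length(tumor_fraction) == 2) {
    stats::runif(n, tumor_fraction[1], tumor_fraction[2])
  } else {
    rep(tumor_fraction, n)
  }
  fish_draws <- if (fish) lapply(statuses, fish_truth) else vector("list", n)
  samples <- lapply(seq_len(n), function(i) {
    spec <- synthetic_spec(status = statuses[i], seed = seeds[i],
                           tumor_fraction = tfs[i], ...)
    tissue <- simulate_tissue_profile(spec)
    out <- list(sample_id = sprintf("S%04d", i), status = statuses[i],
                tissue = tissue, tumor_fraction = tfs[i],
                msaf = min(1, tfs[i] / 2), fish = fish_draws[[i]])
    if (plasma) out$plasma <- simulate_plasma_profile(tissue)
    out
  })
  structure(samples, class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' One CNR-dialect TSV per sample (tissue, plus plasma when present), a
#' truth table TSV (`sample_id`, `status`, `tumor_fraction`, `msaf`), and
#' the synthetic cytoband file.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort) {
    write_cnr(s$tissue$bins, file.path(dir, paste0(s$sample_id, "_tissue.cnr")))
    if (!is.null(s$plasma)) {
      write_cnr(s$plasma$bins, file.path(dir, paste0(s$sample_id, "_plasma.cnr")))
    }
  }
  truth <- data.frame(
    sample_id = vapply(cohort, `[[`, character(1), "sample_id"),
    status = vapply(cohort, `[[`, character(1), "status"),
    tumor_fraction = vapply(cohort, `[[`, numeric(1), "tumor_fraction"),
    msaf = vapply(cohort, `[[`, numeric(1), "msaf")
  )
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_synthetic_cytobands(file.path(dir, "synthetic_cytoBand.txt"))
  invisible(dir)
}
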