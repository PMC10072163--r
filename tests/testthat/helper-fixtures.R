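# Programmatic fixtures: band maps, bin tables and band profiles built in
# code at test time.

# A q-arm-only band map with k equal bands of `band_len` bp.
toy_band_map <- function(k, band_len = 1e7, chrom = "chr7") {
  starts <- (seq_len(k) - 1) * band_len
  as_cytobands(data.frame(
    chrom = chrom, start = starts, end = starts + band_len,
    name = sprintf("q%02d", seq_len(k)), stringsAsFactors = FALSE
  ))
}

# Off-target bins realising the given per-band copy numbers: band i gets
# length(cns_list[[i]]) bins of 150 kb from its start.
toy_bins <- function(cns_list, band_len = 1e7, chrom = "chr7") {
  rows <- lapply(seq_along(cns_list), function(i) {
    n <- length(cns_list[[i]])
    start <- (i - 1) * band_len + (seq_len(n) - 1) * 150000
    data.frame(chrom = chrom, start = start, end = start + 150000,
               gene = "-", cn = cns_list[[i]], kind = "offtarget",
               stringsAsFactors = FALSE)
  })
  as_bins(do.call(rbind, rows))
}

toy_profiles <- function(cns_list, config = segmentation_config(),
                         band_len = 1e7) {
  assign_bins_to_bands(toy_bins(cns_list, band_len),
                       toy_band_map(length(cns_list), band_len),
                       arm = "q", config = config)
}

# Random step-profile generator for the segmentation oracle comparison.
random_band_cns <- function(k = NULL) {
  k <- k %||% sample(2:8, 1)
  level <- 2
  sd <- stats::runif(1, 0.05, 0.3)
  lapply(seq_len(k), function(i) {
    if (i > 1 && stats::runif(1) < 0.4) {
      level <<- max(0.5, level + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 3))
    }
    pmax(0.01, stats::rnorm(sample(3:8, 1), level, sd))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

synthetic_cytoband_path <- function() {
  system.file("extdata", "synthetic_cytoBand_chr7.txt", package = "metpoly")
}
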