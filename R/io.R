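# Readers and writers for the flat-file interfaces: per-bin copy-number
# tables (CNR-dialect TSV), UCSC cytoBand maps, cohort tables, and the
# JSON + TSV call report. Coordinates are 0-based half-open throughout.

OFFTARGET_GENE_LABELS <- c("-", "", "Antitarget", "Background")

#' Read a per-bin copy-number table
#'
#' Reads a tab-separated bin table in the dialect written by upstream
#' panel copy-number callers: a header line with at least `chromosome`
#' (or `chrom`), `start`, `end`, and one of `log2` / `cn`; optional
#' `gene`, `depth`, `weight` and `kind` columns. When only `log2` is
#' present the linear copy number is derived as `cn = 2 * 2^log2`
#' (diploid = 2). Bins are returned stably sorted by (chrom, start).
#'
#' Bin kind (capture vs off-target) is taken from the `kind` column when
#' present, otherwise inferred from the `gene` label: `-`, empty,
#' `Antitarget` or `Background` mark off-target bins.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `gene`,
#'   `log2`, `cn`, `depth`, `kind`.
#' @export
read_cnr <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  if ("chromosome" %in% names(df)) names(df)[names(df) == "chromosome"] <- "chrom"
  for (col in c("chrom", "start", "end")) {
    if (!col %in% names(df)) {
      stop_format(paste0("missing required column: ", col))
    }
  }
  if (!any(c("log2", "cn") %in% names(df))) {
    stop_format("need at least one of 'log2' or 'cn' columns")
  }
  as_bins(df)
}

#' Coerce a data frame to a validated bin table
#'
#' @param df Data frame with at least `chrom`, `start`, `end` and one of
#'   `log2`/`cn`; see [read_cnr()] for the column contract.
#' @return Validated, sorted bin `data.frame`.
#' @export
as_bins <- function(df) {
  names(df) <- tolower(names(df))
  if ("chromosome" %in% names(df)) names(df)[names(df) == "chromosome"] <- "chrom"
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) || anyNA(v)) {
      ln <- if (length(bad)) bad[1] else which(is.na(v))[1]
      stop_format(sprintf("non-numeric %s coordinate at data line %d", col, ln))
    }
    df[[col]] <- v
  }
  if (!"gene" %in% names(df)) df$gene <- "-"
  if (!"log2" %in% names(df)) df$log2 <- NA_real_
  if (!"cn" %in% names(df)) df$cn <- NA_real_
  if (!"depth" %in% names(df)) df$depth <- NA_real_
  df$log2 <- suppressWarnings(as.numeric(df$log2))
  df$cn <- suppressWarnings(as.numeric(df$cn))
  fill <- is.na(df$cn) & !is.na(df$log2)
  df$cn[fill] <- 2 * 2^df$log2[fill]
  if (anyNA(df$cn)) {
    stop_format(sprintf("bin at data line %d has neither log2 nor cn",
                        which(is.na(df$cn))[1]))
  }
  if (any(df$end <= df$start)) {
    stop_format(sprintf("bin at data line %d has end <= start",
                        which(df$end <= df$start)[1]))
  }
  if (any(df$cn < 0)) {
    stop_format(sprintf("negative copy number at data line %d",
                        which(df$cn < 0)[1]))
  }
  if (!"kind" %in% names(df)) {
    df$kind <- ifelse(is.na(df$gene) | df$gene %in% OFFTARGET_GENE_LABELS,
                      "offtarget", "capture")
  }
  if (!all(df$kind %in% c("capture", "offtarget"))) {
    stop_format("kind must be 'capture' or 'offtarget'")
  }
  ord <- order(df$chrom, df$start)  # stable
  df <- df[ord, c("chrom", "start", "end", "gene", "log2", "cn", "depth",
                  "kind")]
  rownames(df) <- NULL
  df
}

#' Write a bin table as CNR-dialect TSV
#'
#' Copy numbers are written at 6 significant digits; [read_cnr()] of the
#' output restores (chrom, start, end, cn) up to that precision.
#'
#' @param bins Bin `data.frame` (see [read_cnr()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnr <- function(bins, path) {
  bins <- as_bins(bins)
  out <- data.frame(
    chromosome = bins$chrom,
    start = format(bins$start, scientific = FALSE, trim = TRUE),
    end = format(bins$end, scientific = FALSE, trim = TRUE),
    gene = bins$gene,
    log2 = ifelse(is.na(bins$log2), "", formatC(bins$log2, digits = 6,
                                                format = "g")),
    cn = formatC(bins$cn, digits = 6, format = "g"),
    depth = ifelse(is.na(bins$depth), "", formatC(bins$depth, digits = 6,
                                                  format = "g")),
    kind = bins$kind,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a UCSC cytoBand file
#'
#' Parses the 5-column, headerless UCSC `cytoBand.txt` layout
#' (chrom, chromStart, chromEnd, name, gieStain) and returns the bands of
#' one chromosome, sorted and validated to be non-overlapping. The arm is
#' the first character of the band name and must be `p` or `q`.
#'
#' @param path Path to the cytoband file.
#' @param chrom Chromosome to extract, e.g. `"chr7"`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `arm`.
#' @export
read_cytobands <- function(path, chrom) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop_format("cytoband file needs >= 4 tab-separated columns")
  names(df)[1:4] <- c("chrom", "start", "end", "name")
  df <- df[df$chrom == chrom, c("chrom", "start", "end", "name"), drop = FALSE]
  as_cytobands(df)
}

#' Validate a cytoband table
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `name`.
#' @return Sorted, validated band `data.frame` with an `arm` column.
#' @export
as_cytobands <- function(df) {
  if (nrow(df) == 0) stop_validation("no cytobands for requested chromosome")
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df <- df[order(df$start), , drop = FALSE]
  if (any(df$end <= df$start)) stop_validation("cytoband with end <= start")
  arm <- substr(df$name, 1, 1)
  if (!all(arm %in% c("p", "q"))) {
    stop_validation(sprintf("band name '%s' does not start with p or q",
                            df$name[which(!arm %in% c("p", "q"))[1]]))
  }
  if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)])) {
    stop_validation("overlapping cytobands")
  }
  df$arm <- arm
  rownames(df) <- NULL
  df[, c("chrom", "start", "end", "name", "arm")]
}

#' Sample-level sequencing QC gate
#'
#' A sample passes when its fraction of exons at >= 100X is strictly above
#' the coverage threshold, its mean depth is at least the depth threshold,
#' and its mapping rate is at least the mapping threshold. The verdict
#' always returns; failures list every violated criterion.
#'
#' @param exon_cov_frac Fraction of exons covered at >= 100X.
#' @param mean_depth Mean sequencing depth (X).
#' @param map_rate Read mapping rate.
#' @param thresholds A [qc_thresholds()] object.
#' @return List of class `qc_result` with elements `pass` (logical) and
#'   `reasons` (character, empty when passing).
#' @export
qc_check <- function(exon_cov_frac, mean_depth, map_rate,
                     thresholds = qc_thresholds()) {
  stopifnot(is.numeric(exon_cov_frac), is.numeric(mean_depth),
            is.numeric(map_rate))
  reasons <- character()
  if (!(exon_cov_frac > thresholds$min_exon_cov_frac)) {
    reasons <- c(reasons, sprintf(
      "exon coverage: %.4f of exons at >=100X, need more than %.4f",
      exon_cov_frac, thresholds$min_exon_cov_frac))
  }
  if (!(mean_depth >= thresholds$min_depth)) {
    reasons <- c(reasons, sprintf(
      "mean depth: %.1fX, need at least %.1fX", mean_depth,
      thresholds$min_depth))
  }
  if (!(map_rate >= thresholds$min_map_rate)) {
    reasons <- c(reasons, sprintf(
      "mapping rate: %.4f, need at least %.4f", map_rate,
      thresholds$min_map_rate))
  }
  structure(list(pass = length(reasons) == 0, reasons = reasons),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("Sequencing QC:", if (x$pass) "PASS" else "FAIL", "\n")
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' Write a MET status call report
#'
#' Writes a machine-readable JSON report (sample, status, MET gene copy
#' number, amplified fraction of the arm, MET-band region state, regions)
#' plus a flat TSV of the segmentation regions. [read_met_report()] of the
#' JSON restores the call fields bit-exactly.
#'
#' @param call A `met_call` from [call_met_status()] or [classify_met()]
#'   carrying its segmentation.
#' @param path Output path of the JSON report; the regions TSV is written
#'   alongside with suffix `_regions.tsv` unless `regions_path` is given.
#' @param regions_path Optional explicit path of the regions TSV.
#' @return Invisible list of the two paths written.
#' @export
write_met_report <- function(call, path, regions_path = NULL) {
  stopifnot(inherits(call, "met_call"))
  seg <- call$segmentation
  if (is.null(seg) || is.null(seg$regions) || nrow(seg$regions) == 0) {
    stop_validation("call carries no segmentation regions to report")
  }
  regions_path <- regions_path %||% sub("\\.json$", "", path)
  if (identical(regions_path, path)) regions_path <- paste0(path, "_regions")
  regions_path <- paste0(sub("_regions$", "", regions_path), "_regions.tsv")
  rep <- list(
    sample = call$sample,
    status = call$status,
    met_gcn = call$met_gcn,
    amplified_fraction = call$amplified_fraction,
    met_region_cng = call$met_region_cng,
    met_band = call$met_band,
    regions = seg$regions
  )
  # I(17) significant digits: doubles survive the JSON round trip bit-exactly
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = I(17))
  utils::write.table(seg$regions, regions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(json = path, regions = regions_path))
}

#' Read a MET status call report
#'
#' @param path Path to a JSON report written by [write_met_report()].
#' @return A `met_call` object (without the full segmentation; the regions
#'   table is attached as `$regions`).
#' @export
read_met_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(sample = rep$sample, status = rep$status,
         met_gcn = as.numeric(rep$met_gcn),
         amplified_fraction = as.numeric(rep$amplified_fraction),
         met_region_cng = rep$met_region_cng, met_band = rep$met_band,
         regions = rep$regions, segmentation = NULL),
    class = "met_call"
  )
}

#' Read a labeled cohort table
#'
#' Tab-separated table with columns `sample_id`, `fish_label` and
#' `ngs_met_cn` (plus optional FISH raw counts `mean_gcn`, `cep7`), as used
#' for cutoff determination and FISH-NGS comparison.
#'
#' @param path Path to the TSV.
#' @return A `data.frame`.
#' @export
read_labeled_cohort <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "fish_label", "ngs_met_cn")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_format(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  df$ngs_met_cn <- as.numeric(df$ngs_met_cn)
  df
}

#' Read a paired tissue/plasma sample table
#'
#' Tab-separated table with columns `sample_id`, `tissue_status`,
#' `plasma_status`, and optional `msaf_tissue`, `msaf_plasma`,
#' `egfr_vaf_plasma`, `cn7q_tissue`. Status labels must be among
#' [met_statuses()].
#'
#' @param path Path to the TSV.
#' @return A `data.frame`.
#' @export
read_paired_samples <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue_status", "plasma_status")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_format(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  for (col in c("tissue_status", "plasma_status")) {
    bad <- which(!df[[col]] %in% met_statuses())
    if (length(bad)) {
      stop_format(sprintf("unknown status '%s' in %s at data row %d",
                          df[[col]][bad[1]], col, bad[1]))
    }
  }
  for (col in c("msaf_tissue", "msaf_plasma", "egfr_vaf_plasma")) {
    if (col %in% names(df)) {
      v <- as.numeric(df[[col]])
      if (any(v < 0 | v > 1, na.rm = TRUE)) {
        stop_format(paste0(col, " must lie in [0, 1]"))
      }
      df[[col]] <- v
    }
  }
  df
}
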