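# Aggregation of off-target bins into cytoband profiles, and the
# between-band t-test. Band profiles are the unit the segmentation works
# on: each holds the linear copy numbers of its member off-target bins.

#' Two-sided t-test between two band profiles
#'
#' Compares the member-bin copy numbers of two bands with a two-sided
#' Welch (unequal-variance) t-test; the pooled-variance test is available
#' via `var_equal`. P values at or above `alpha` are interpreted as "no
#' difference" between the bands. Degenerate rule: when both bands have
#' zero variance the P value is 1 if the means are equal and 0 otherwise.
#'
#' @param a,b Numeric vectors of bin copy numbers (each length >= 2), or
#'   band-profile lists with a `cns` element.
#' @param alpha Non-significance threshold (default 0.1).
#' @param var_equal Pooled-variance test instead of Welch (default FALSE).
#' @return List with `p_value` and `is_nonsignificant` (`p_value >= alpha`).
#' @export
band_ttest <- function(a, b, alpha = 0.1, var_equal = FALSE) {
  x <- if (is.list(a)) a$cns else a
  y <- if (is.list(b)) b$cns else b
  if (length(x) < 2 || length(y) < 2) {
    stop_validation("band t-test requires >= 2 bins in each band")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
  } else {
    p <- stats::t.test(x, y, var.equal = var_equal)$p.value
  }
  list(p_value = p, is_nonsignificant = p >= alpha)
}

#' Assign off-target bins to chromosome-arm cytobands
#'
#' Each off-target bin is assigned to the band containing its midpoint;
#' capture bins are excluded. Bands holding fewer than
#' `config$min_bins_per_band` bins are pre-merged into the neighbouring
#' band with the closer mean copy number (a band with no bins at all is
#' absorbed by its left neighbour, or the right one if it is leftmost),
#' so that every retained profile supports a t-test.
#'
#' @param bins Bin `data.frame` (see [read_cnr()]).
#' @param bands Cytoband `data.frame` (see [read_cytobands()]).
#' @param arm Chromosome arm to profile, `"q"` (default) or `"p"`.
#' @param config A [segmentation_config()].
#' @return An object of class `band_profiles`: list with `chrom`, `arm`,
#'   `arm_start`, `arm_end`, and `profiles`, a list of per-band lists
#'   (`name`, `bands` = constituent band names, `start`, `end`, `cns`).
#' @export
assign_bins_to_bands <- function(bins, bands, arm = "q",
                                 config = segmentation_config()) {
  stopifnot(arm %in% c("p", "q"))
  ab <- bands[bands$arm == arm, , drop = FALSE]
  if (nrow(ab) == 0) stop_validation(paste0("no ", arm, "-arm bands in map"))
  chrom <- ab$chrom[1]
  off <- bins[bins$kind == "offtarget" & bins$chrom == chrom, , drop = FALSE]
  mid <- (off$start + off$end) / 2
  idx <- findInterval(mid, ab$start)
  keep <- idx >= 1 & idx <= nrow(ab) & mid < ab$end[pmax(idx, 1)]
  off <- off[keep, , drop = FALSE]
  idx <- idx[keep]
  if (nrow(off) == 0) {
    stop_validation(paste0("no off-target bins on ", chrom, arm))
  }
  profiles <- lapply(seq_len(nrow(ab)), function(i) {
    list(name = ab$name[i], bands = ab$name[i], start = ab$start[i],
         end = ab$end[i], cns = off$cn[idx == i])
  })

  # pre-merge under-populated bands into the closer-mean neighbour
  repeat {
    nb <- vapply(profiles, function(p) length(p$cns), integer(1))
    small <- which(nb < config$min_bins_per_band)
    if (length(small) == 0 || length(profiles) == 1) break
    i <- small[1]
    left <- if (i > 1) i - 1L else NA_integer_
    right <- if (i < length(profiles)) i + 1L else NA_integer_
    j <- if (is.na(left)) {
      right
    } else if (is.na(right)) {
      left
    } else if (nb[i] == 0) {
      left
    } else {
      m <- mean(profiles[[i]]$cns)
      dl <- abs(m - mean(profiles[[left]]$cns))
      dr <- abs(m - mean(profiles[[right]]$cns))
      if (dl <= dr) left else right
    }
    a <- min(i, j); b <- max(i, j)
    merged <- list(
      name = paste(profiles[[a]]$name, profiles[[b]]$name, sep = "+"),
      bands = c(profiles[[a]]$bands, profiles[[b]]$bands),
      start = profiles[[a]]$start, end = profiles[[b]]$end,
      cns = c(profiles[[a]]$cns, profiles[[b]]$cns)
    )
    profiles[[a]] <- merged
    profiles[[b]] <- NULL
  }

  structure(
    list(chrom = chrom, arm = arm, arm_start = min(ab$start),
         arm_end = max(ab$end), profiles = profiles),
    class = "band_profiles"
  )
}

#' @export
print.band_profiles <- function(x, ...) {
  cat(sprintf("%s%s: %d band profile(s) over %.1f Mb\n", x$chrom, x$arm,
              length(x$profiles), (x$arm_end - x$arm_start) / 1e6))
  for (p in x$profiles) {
    cat(sprintf("  %-18s %9.0f-%9.0f  n=%3d  mean_cn=%.3f\n", p$name,
                p$start, p$end, length(p$cns), mean(p$cns)))
  }
  invisible(x)
}

# Symmetric matrix of between-band P values (diagonal 1). Band profiles
# never change after pre-merging, so this is computed once per arm.
band_p_matrix <- function(profiles, config) {
  k <- length(profiles)
  P <- matrix(1, k, k)
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        p <- band_ttest(profiles[[i]], profiles[[j]], alpha = config$alpha,
                        var_equal = config$var_equal)$p_value
        P[i, j] <- P[j, i] <- p
      }
    }
  }
  P
}
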