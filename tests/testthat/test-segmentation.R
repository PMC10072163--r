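test_that("off-target bins are assigned by midpoint and capture bins excluded", {
  bands <- toy_band_map(10)
  bins <- toy_bins(replicate(10, rep(2, 10), simplify = FALSE))
  prof <- assign_bins_to_bands(bins, bands)
  expect_equal(length(prof$profiles), 10)
  expect_true(all(vapply(prof$profiles, function(p) length(p$cns), integer(1)) == 10))

  # bin straddling the band 1 / band 2 boundary, midpoint in band 2
  straddle <- as_bins(data.frame(
    chrom = "chr7", start = 1e7 - 50000, end = 1e7 + 100000, gene = "-",
    cn = 9, kind = "offtarget"))
  prof2 <- assign_bins_to_bands(rbind(bins, straddle), bands)
  expect_true(9 %in% prof2$profiles[[2]]$cns)
  expect_false(9 %in% prof2$profiles[[1]]$cns)

  # capture bins never enter band profiles
  cap <- as_bins(data.frame(chrom = "chr7", start = 100, end = 220,
                            gene = "MET", cn = 50, kind = "capture"))
  prof3 <- assign_bins_to_bands(rbind(bins, cap), bands)
  expect_false(50 %in% unlist(lapply(prof3$profiles, `[[`, "cns")))

  expect_error(assign_bins_to_bands(cap, bands),
               class = "metpoly_validation_error")
})

test_that("under-populated bands pre-merge into the closer-mean neighbour", {
  prof <- toy_profiles(list(rep(2.0, 5), 2.1, rep(4.0, 5)))
  expect_equal(length(prof$profiles), 2)
  expect_equal(length(prof$profiles[[1]]$cns), 6)  # merged left (|2.1-2| < |2.1-4|)
  expect_equal(prof$profiles[[1]]$bands, c("q01", "q02"))
  expect_equal(prof$profiles[[1]]$end, 2e7)  # extent absorbed

  prof <- toy_profiles(list(rep(2.0, 5), 3.9, rep(4.0, 5)))
  expect_equal(length(prof$profiles[[2]]$cns), 6)  # merged right
})

test_that("band_ttest matches the Welch closed form and its degenerate rule", {
  set.seed(21)
  for (i in 1:25) {
    x <- rnorm(sample(2:15, 1), runif(1, 1, 4), runif(1, 0.01, 0.5))
    y <- rnorm(sample(2:15, 1), runif(1, 1, 4), runif(1, 0.01, 0.5))
    expect_equal(band_ttest(x, y)$p_value, welch_p_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_equal(band_ttest(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_equal(band_ttest(c(2, 2), c(6, 6))$p_value, 0)
  # strongly separated means are detected
  set.seed(22)
  res <- band_ttest(rnorm(20, 2, 0.01), rnorm(20, 6, 0.01))
  expect_lt(res$p_value, 1e-6)
  expect_false(res$is_nonsignificant)
  expect_true(band_ttest(c(2, 2.0001, 2), c(2, 2, 2.0001))$is_nonsignificant)
  expect_error(band_ttest(2, c(2, 2)), class = "metpoly_validation_error")
})

test_that("initial region formation splits exactly at a copy-number step", {
  # identical within-band scatter: every within-level t statistic is 0
  # (p = 1) while the 2-vs-4 step is overwhelmingly significant
  pat <- seq(-0.05, 0.05, length.out = 10)
  flat <- lapply(1:10, function(i) 2 + pat)
  expect_equal(length(form_initial_regions(toy_profiles(flat))), 1)

  step <- lapply(1:10, function(i) (if (i <= 5) 2 else 4) + pat)
  regions <- form_initial_regions(toy_profiles(step))
  expect_equal(regions, list(1:5, 6:10))

  one <- toy_profiles(list(rnorm(5, 2, 0.1)))
  expect_equal(form_initial_regions(one), list(1L))
})

test_that("merge rules follow the cross-pair fraction table", {
  # fabricate the cross-region P fractions directly
  mk_P <- function(nA, nB, n_nonsig) {
    k <- nA + nB
    P <- matrix(1, k, k)
    cross <- expand.grid(a = 1:nA, b = nA + 1:nB)
    p <- rep(0.001, nrow(cross))
    p[seq_len(n_nonsig)] <- 0.5
    for (r in seq_len(nrow(cross))) {
      P[cross$a[r], cross$b[r]] <- P[cross$b[r], cross$a[r]] <- p[r]
    }
    P
  }
  cfg <- segmentation_config()
  sweep <- getFromNamespace("merge_sweep", "metpoly")

  # rule (i): f = 0.6 > 0.5 -> merged
  expect_equal(sweep(list(1:5, 6:10), mk_P(5, 5, 15), cfg), list(1:10))
  # rule (ii): larger region 8 bands, f = 0.35 in (0.3, 0.5] -> merged
  expect_equal(sweep(list(1:5, 6:13), mk_P(5, 8, 14), cfg), list(1:13))
  # larger region only 5 bands, f = 0.35 -> fails both rules
  expect_equal(sweep(list(1:4, 5:9), mk_P(4, 5, 7), cfg), list(1:4, 5:9))
  # f exactly 0.5 is not 'higher than 50%'
  expect_equal(sweep(list(1:4, 5:8), mk_P(4, 4, 8), cfg), list(1:4, 5:8))
})

test_that("segmentation equals the brute-force partition oracle", {
  set.seed(41)
  for (i in 1:60) {
    cns <- random_band_cns()
    prof <- toy_profiles(cns)
    if (length(prof$profiles) != length(cns)) next  # oracle assumes no pre-merge
    seg <- segment_arm(toy_bins(cns), toy_band_map(length(cns)))
    expect_equal(seg$region_bands, oracle_segment(cns), info = paste("case", i))
  }
})

test_that("merging conserves the bin partition and is a fixpoint", {
  set.seed(51)
  for (i in 1:20) {
    cns <- random_band_cns()
    prof <- toy_profiles(cns)
    initial <- form_initial_regions(prof)
    merged <- merge_regions(initial, prof)
    expect_equal(sort(unlist(merged)), seq_along(prof$profiles))
    expect_equal(merge_regions(merged, prof), merged)  # fixpoint
    n_bins_before <- length(unlist(lapply(prof$profiles, `[[`, "cns")))
    seg <- segment_arm(toy_bins(cns), toy_band_map(length(cns)))
    expect_equal(sum(seg$regions$n_bins), n_bins_before)
  }
})

test_that("region means are scale-equivariant", {
  set.seed(61)
  cns <- lapply(1:6, function(i) rnorm(8, sample(c(2, 4), 1), 0.1))
  seg <- segment_arm(toy_bins(cns), toy_band_map(6))
  for (c_scale in c(0.5, 3)) {
    scaled <- lapply(cns, function(v) c_scale * v)
    prof <- toy_profiles(scaled)
    stats_fn <- getFromNamespace("region_stats", "metpoly")
    for (r in seq_along(seg$region_bands)) {
      m <- stats_fn(seg$region_bands[[r]], prof$profiles,
                    segmentation_config())$mean_cn
      expect_equal(m, c_scale * seg$regions$mean_cn[r], tolerance = 1e-12)
    }
  }
})

test_that("amplified fraction is computed over CNG regions and is monotone in the threshold", {
  set.seed(71)
  # one 30 Mb gained region on a 100 Mb arm
  cns <- lapply(1:10, function(i) rnorm(12, if (i %in% 4:6) 4 else 2, 0.05))
  seg <- segment_arm(toy_bins(cns), toy_band_map(10))
  expect_equal(seg$amplified_fraction, 0.30, tolerance = 1e-12)

  flat_low <- segment_arm(toy_bins(lapply(1:6, function(i) rnorm(10, 2, 0.05))),
                          toy_band_map(6))
  expect_equal(flat_low$amplified_fraction, 0)
  flat_high <- segment_arm(toy_bins(lapply(1:6, function(i) rnorm(10, 4, 0.05))),
                           toy_band_map(6))
  expect_equal(flat_high$amplified_fraction, 1)

  thresholds <- seq(1.5, 5, by = 0.25)
  fr <- vapply(thresholds, function(t) amplified_fraction(seg, t), numeric(1))
  expect_true(all(diff(fr) <= 0))
})
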