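test_that("noiseless tissue profiles realise their event geometry exactly", {
  neg <- simulate_tissue_profile(synthetic_spec("negative",
                                                noise_sd_tissue = 0, seed = 1))
  expect_true(all(neg$bins$cn == 2))

  amp <- simulate_tissue_profile(synthetic_spec("amplification",
                                                focal_cn = 10,
                                                noise_sd_tissue = 0, seed = 1))
  met_bins <- amp$bins$gene == "MET"
  expect_true(all(amp$bins$cn[met_bins] == 10))
  bm <- synthetic_band_map()
  met_band <- bm[bm$name == "q31.2", ]
  mid <- (amp$bins$start + amp$bins$end) / 2
  in_band <- mid >= met_band$start & mid < met_band$end
  expect_true(all(amp$bins$cn[!met_bins & in_band] == 10))
  expect_true(all(amp$bins$cn[!in_band & !met_bins] == 2))
  expect_equal(amp$truth_fraction, 0.07)  # 7 Mb band on a 100 Mb arm

  poly <- simulate_tissue_profile(synthetic_spec("polysomy", arm_gain_cn = 3,
                                                 noise_sd_tissue = 0, seed = 1))
  expect_true(all(poly$bins$cn[poly$bins$kind == "offtarget"] == 3))
  expect_equal(poly$truth_fraction, 1)

  pan <- simulate_tissue_profile(synthetic_spec("pan_met_amplification",
                                                arm_gain_cn = 3,
                                                pan_fraction = 0.4,
                                                noise_sd_tissue = 0, seed = 1))
  expect_gte(pan$truth_fraction, 0.4)
  expect_lt(pan$truth_fraction, 0.5)  # snapped up to band boundaries
  gained <- unique(pan$bins$cn[pan$bins$kind == "offtarget"])
  expect_setequal(gained, c(2, 3))
})

test_that("profiles are bit-identical under the same spec and seed", {
  s <- synthetic_spec("pan_met_amplification", seed = 99)
  p1 <- simulate_tissue_profile(s)
  p2 <- simulate_tissue_profile(s)
  expect_identical(p1$bins, p2$bins)
  expect_identical(p1$level, p2$level)
  pl1 <- simulate_plasma_profile(p1, tumor_fraction = 0.3)
  pl2 <- simulate_plasma_profile(p2, tumor_fraction = 0.3)
  expect_identical(pl1$bins, pl2$bins)
})

test_that("plasma attenuation follows 2 + tf * (cn - 2)", {
  tis <- simulate_tissue_profile(synthetic_spec("polysomy", arm_gain_cn = 3,
                                                noise_sd_tissue = 0, seed = 5))
  pl <- simulate_plasma_profile(tis, tumor_fraction = 0.05, noise_sd = 0)
  off <- pl$bins$kind == "offtarget"
  expect_true(all(abs(pl$bins$cn[off] - 2.05) < 1e-12))
  pl0 <- simulate_plasma_profile(tis, tumor_fraction = 0, noise_sd = 0)
  expect_true(all(pl0$bins$cn == 2))
  pl1 <- simulate_plasma_profile(tis, tumor_fraction = 1, noise_sd = 0)
  expect_equal(pl1$bins$cn, tis$underlying)
  expect_error(simulate_plasma_profile(tis, tumor_fraction = 1.2),
               class = "metpoly_validation_error")
})

test_that("cohorts are deterministic, honour prevalence, and carry consistent FISH truth", {
  c1 <- simulate_cohort(12, seed = 42, plasma = TRUE)
  c2 <- simulate_cohort(12, seed = 42, plasma = TRUE)
  expect_identical(lapply(c1, function(s) s$tissue$bins),
                   lapply(c2, function(s) s$tissue$bins))
  expect_identical(vapply(c1, `[[`, character(1), "status"),
                   vapply(c2, `[[`, character(1), "status"))

  all_poly <- simulate_cohort(10, prevalence = c(0, 0, 0, 1), seed = 1)
  expect_true(all(vapply(all_poly, `[[`, character(1), "status") == "polysomy"))

  expect_error(simulate_cohort(5, prevalence = c(0.5, 0.5, 0.5, 0)),
               class = "metpoly_validation_error")

  co <- simulate_cohort(40, prevalence = c(0.25, 0.25, 0.25, 0.25), seed = 9)
  for (s in co) {
    expect_equal(s$msaf, min(1, s$tumor_fraction / 2))
    fish_status <- classify_fish(s$fish$mean_gcn, s$fish$cep7)$status
    expected <- switch(s$status,
                       pan_met_amplification = "amplification",
                       s$status)
    expect_equal(fish_status, expected)
  }
})

test_that("invalid generator settings are rejected", {
  expect_error(synthetic_spec("wild_type"), class = "metpoly_validation_error")
  expect_error(synthetic_spec(pan_fraction = 0.9),
               class = "metpoly_validation_error")
  expect_error(synthetic_spec(tumor_fraction = -0.1),
               class = "metpoly_validation_error")
  expect_error(synthetic_spec(noise_sd_tissue = -1),
               class = "metpoly_validation_error")
})

test_that("recovery of non-negative truths is non-decreasing in tumour fraction", {
  bm <- synthetic_band_map()
  recover_rate <- function(tf) {
    co <- simulate_cohort(24, prevalence = c(0, 1/3, 1/3, 1/3), seed = 400,
                          fish = FALSE)
    hits <- vapply(co, function(s) {
      pl <- simulate_plasma_profile(s$tissue, tumor_fraction = tf)
      call <- call_met_status(pl$bins, bm)
      call$status == s$status
    }, logical(1))
    mean(hits)
  }
  rates <- vapply(c(0.02, 0.3, 1.0), recover_rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.5)   # near-diploid plasma signal at 2% ctDNA
  expect_gt(rates[3], 0.9)   # undiluted signal is recovered
})
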