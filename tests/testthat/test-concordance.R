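test_that("confusion counts pairs with the reference on the columns", {
  m0 <- example_fish_ngs_cohort()
  pairs <- confusion_pairs(m0)
  expect_equal(nrow(pairs), 53)
  m <- confusion(pairs$reference, pairs$test,
                 classes = c("amplification", "polysomy", "negative"))
  expect_equal(m$counts, m0$counts)

  expect_error(confusion(character(), character()),
               class = "metpoly_validation_error")
  expect_error(confusion("amplification", "oops",
                         classes = c("amplification", "polysomy")),
               class = "metpoly_validation_error")
  m1 <- confusion(rep("polysomy", 4), rep("polysomy", 4),
                  classes = c("amplification", "polysomy"))
  expect_equal(sum(m1$counts), m1$counts["polysomy", "polysomy"])
})

test_that("one-vs-rest metrics reproduce the tissue cohort percentages", {
  m <- example_fish_ngs_cohort()
  amp <- class_metrics(m, "amplification")
  expect_equal(amp$tp, 13); expect_equal(amp$fn, 1); expect_equal(amp$fp, 0)
  expect_equal(as_percent(amp$sensitivity), 92.9)
  expect_equal(as_percent(amp$specificity), 100)
  expect_equal(as_percent(amp$agreement), 98.1)
  poly <- class_metrics(m, "polysomy")
  expect_equal(as_percent(poly$sensitivity), 90)
  expect_equal(as_percent(poly$agreement), 96.2)

  perfect <- confusion_from_counts(diag(c(5, 7, 9)), c("a", "b", "c"))
  for (cl in c("a", "b", "c")) {
    cm <- class_metrics(perfect, cl)
    expect_equal(cm$sensitivity, 1)
    expect_equal(cm$specificity, 1)
    expect_equal(cm$agreement, 1)
  }
})

test_that("metrics with zero denominators are undefined, not zero", {
  m <- confusion_from_counts(matrix(c(5, 0, 0, 0), 2), c("pos", "neg"))
  cm <- class_metrics(m, "neg")
  expect_true(is.na(cm$sensitivity))  # no reference negatives
  expect_true(is.na(cm$ppv))          # no test negatives either
})

test_that("one-vs-rest counts are conserved across classes", {
  m <- example_fish_ngs_cohort()
  ms <- lapply(m$classes, function(cl) class_metrics(m, cl))
  expect_equal(sum(vapply(ms, `[[`, numeric(1), "tp")), sum(diag(m$counts)))
  expect_equal(sum(vapply(ms, function(x) x$tp + x$fn, numeric(1))),
               sum(m$counts))
})

test_that("Cohen's kappa matches its closed form and limiting cases", {
  expect_equal(cohen_kappa(confusion_from_counts(diag(c(10, 10, 10)),
                                                 c("a", "b", "c"))), 1)
  # counts proportional to row x column marginals: exact independence
  ind <- outer(c(2, 3, 5), c(4, 1, 5))
  expect_equal(cohen_kappa(confusion_from_counts(ind, c("a", "b", "c"))), 0)
  m <- example_fish_ngs_cohort()
  expect_equal(cohen_kappa(m), (50/53 - 1152/2809) / (1 - 1152/2809),
               tolerance = 1e-12)
  # independent implementation agreement
  ek <- e1071::classAgreement(m$counts)$kappa
  expect_equal(cohen_kappa(m), ek, tolerance = 1e-12)
  degen <- confusion_from_counts(diag(c(5, 0)), c("a", "b"))
  expect_error(cohen_kappa(degen), class = "metpoly_validation_error")
})

test_that("msaf takes the maximum fraction with an empty-list convention of 0", {
  expect_equal(msaf(c(0.12, 0.03)), 0.12)
  expect_equal(msaf(numeric()), 0)
  expect_equal(msaf(0.5), 0.5)
  expect_error(msaf(c(0.2, 1.4)), class = "metpoly_validation_error")
})

test_that("stratified agreement reproduces the plasma optimization counts", {
  pairs <- example_tissue_plasma_cohort()
  gate <- function(d) d$msaf_plasma > 0.05
  amp <- stratified_agreement(pairs, "amplification", gate)
  expect_equal(amp$n_selected, sum(pairs$msaf_plasma > 0.05))
  expect_equal(amp$ppa, 7 / 10)
  poly <- stratified_agreement(pairs, "polysomy", gate)
  expect_equal(poly$ppa, 5 / 12)
  expect_equal(as_percent(poly$ppa, 0), 42)

  # vacuous filter equals the unstratified one-vs-rest collapse
  m <- confusion(pairs$tissue_status, pairs$plasma_status,
                 classes = met_statuses())
  for (cl in c("amplification", "polysomy")) {
    s <- stratified_agreement(pairs, cl, NULL)
    cm <- class_metrics(m, cl)
    expect_equal(s$ppa, cm$sensitivity)
    expect_equal(s$npa, cm$specificity)
  }

  empty <- stratified_agreement(pairs, "amplification",
                                function(d) d$msaf_plasma > 1)
  expect_equal(empty$n_selected, 0L)
  expect_true(is.na(empty$ppa))
  only_neg <- stratified_agreement(pairs, "amplification",
                                   function(d) d$tissue_status == "negative")
  expect_true(is.na(only_neg$ppa))  # no tissue positives selected
})

test_that("cohort prevalence counts statuses and sums to one", {
  calls <- c(rep("polysomy", 19), rep("negative", 81))
  p <- cohort_prevalence(calls)
  expect_equal(p[["polysomy"]], 0.19)
  expect_equal(sum(p), 1)
  expect_equal(cohort_prevalence(rep("negative", 5)),
               c(negative = 1, amplification = 0,
                 pan_met_amplification = 0, polysomy = 0))
  set.seed(101)
  for (i in 1:10) {
    s <- sample(met_statuses(), sample(1:50, 1), replace = TRUE)
    expect_equal(sum(cohort_prevalence(s)), 1)
  }
  expect_error(cohort_prevalence(character()),
               class = "metpoly_validation_error")
})
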