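meta_days <- function(days, material = "CFDNA_PB", patient = "P1") {
  tibble::tibble(
    sample_id = sprintf("%s_%s_%02d", patient, material, seq_along(days)),
    patient_id = patient,
    collection_date = as.Date("2017-01-01") + days,
    material = material, response_raw = "ID",
    serology = "UNKNOWN", involved_chain = "IGK"
  )
}

test_that("repetitive samples are dropped against the retained anchor", {
  expect_equal(nrow(dedup_samples(meta_days(0))), 1L)
  expect_equal(nrow(dedup_samples(meta_days(c(0, 10)))), 1L)
  expect_equal(nrow(dedup_samples(meta_days(c(0, 16)))), 2L)
  # day 10 dropped; day 20 kept because the anchor is still day 0
  kept <- dedup_samples(meta_days(c(0, 10, 20)))
  expect_equal(as.integer(kept$collection_date - as.Date("2017-01-01")),
               c(0L, 20L))
})

test_that("deduplication is idempotent and per material stream", {
  meta <- dplyr::bind_rows(
    meta_days(c(0, 5, 20, 30)),
    meta_days(c(0, 5, 20, 30), material = "WHOLEBLOOD_PB"),
    meta_days(c(0, 40), patient = "P2")
  )
  once <- dedup_samples(meta)
  expect_identical(dedup_samples(once), once)
  # both material streams keep days 0 and 20 independently
  expect_equal(sum(once$material == "CFDNA_PB" & once$patient_id == "P1"), 2L)
  expect_equal(sum(once$material == "WHOLEBLOOD_PB"), 2L)
  expect_equal(sum(once$patient_id == "P2"), 2L)
})

test_that("unparseable dates are rejected", {
  meta <- meta_days(0)
  meta$collection_date <- "not-a-date"
  expect_error(dedup_samples(meta), "date")
})

test_that("response labels merge and group as reported", {
  expect_equal(map_response_group("sCR"), "CR")
  expect_equal(map_response_group("MR"), "SD/PD")
  expect_equal(map_response_group(c("ID", "RD")), c("ID/RD", "ID/RD"))
  expect_equal(map_response_group(c("SD", "PD")), c("SD/PD", "SD/PD"))
  expect_equal(map_response_group(c("PRa", "PRb", "PR")), rep("PR", 3))
  expect_equal(response_sublabel(c("PRa", "PR")), c("PRa", NA))
  expect_error(map_response_group("XX"), "unknown")
})

test_that("binarization matches the assay positivity definitions", {
  expect_equal(binarize_ngs(c("MM_TOP", "MM_DETECTED", "MM_NOT_DETECTED")),
               c(TRUE, TRUE, FALSE))
  expect_true(is.na(binarize_ngs("NO_CLONE_DEFINED")))
  expect_equal(binarize_flow(c("MM_PC", "MM_AND_N_PC", "N_PC", "NO_PC")),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_error(binarize_ngs("YES"))
})

make_pairs <- function(a, b, c_, d) {
  tibble::tibble(ngs = rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c_, d)),
                 mfc = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c_, d)))
}

test_that("concordance reproduces hand-computed 2x2 statistics", {
  res <- concordance(make_pairs(16, 4, 1, 4))
  expect_equal(res$percent_agreement, 80)
  expect_equal(res$kappa, 0.48979592, tolerance = 1e-6)
  expect_equal(round(res$kappa, 3), 0.490)

  perfect <- concordance(make_pairs(10, 0, 0, 10))
  expect_equal(perfect$percent_agreement, 100)
  expect_equal(perfect$kappa, 1)

  indep <- concordance(make_pairs(9, 3, 3, 1))
  expect_equal(indep$kappa, 0)

  expect_error(concordance(make_pairs(0, 0, 0, 0)), "no pairs")
  expect_error(concordance(tibble::tibble(ngs = c(TRUE, NA),
                                          mfc = c(TRUE, TRUE))), "NA")
})

test_that("kappa stays in [-1,1] and matches the 2x2 algebraic oracle", {
  set.seed(51)
  for (i in 1:100) {
    cells <- as.integer(stats::rmultinom(1, sample(4:100, 1), rep(1 / 4, 4)))
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    pr <- make_pairs(a, b, c_, d)
    p_e <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / nrow(pr)^2
    if (p_e == 1 && (a + d) < nrow(pr)) next  # kappa undefined by design
    res <- concordance(pr)
    expect_gte(res$kappa, -1)
    expect_lte(res$kappa, 1)
    # independent identity: kappa = 2(ad-bc) / ((a+b)(b+d) + (a+c)(c+d))
    denom <- (a + b) * (b + d) + (a + c_) * (c_ + d)
    if (denom > 0) {
      expect_equal(res$kappa, 2 * (a * d - b * c_) / denom,
                   tolerance = 1e-12)
    }
    # count-based agreement oracle
    expect_equal(res$percent_agreement,
                 100 * mean(pr$ngs == pr$mfc), tolerance = 1e-12)
    # transposing the two methods leaves kappa unchanged
    expect_equal(concordance(tibble::tibble(ngs = pr$mfc,
                                            mfc = pr$ngs))$kappa, res$kappa)
    # joint relabeling leaves agreement unchanged
    expect_equal(concordance(tibble::tibble(ngs = !pr$ngs,
                                            mfc = !pr$mfc))$percent_agreement,
                 res$percent_agreement)
  }
})

test_that("tidy and glance expose the concordance result", {
  res <- concordance(make_pairs(16, 4, 1, 4))
  td <- tidy(res)
  expect_equal(sum(td$count), 25)
  expect_equal(td$count[td$ngs & td$mfc], 16)
  gl <- glance(res)
  expect_named(gl, c("n", "percent_agreement", "kappa"))
})

test_that("Spearman correlation matches rank arithmetic", {
  up <- tibble::tibble(freq_a = c(0.1, 0.2, 0.3, 0.4),
                       freq_b = c(0.15, 0.22, 0.31, 0.44))
  expect_equal(spearman_clone_correlation(up)$rho, 1)
  three <- tibble::tibble(freq_a = c(1, 2, 3), freq_b = c(2, 1, 3))
  expect_equal(spearman_clone_correlation(three)$rho, 0.5)
  down <- tibble::tibble(freq_a = 1:5, freq_b = 5:1)
  expect_equal(spearman_clone_correlation(down)$rho, -1)
  expect_error(spearman_clone_correlation(
    tibble::tibble(freq_a = 1:2, freq_b = 2:1)), "3 pairs")
})

test_that("cohort summaries give within-group percentages summing to 100", {
  results <- tibble::tibble(
    group = rep(c("ID/RD", "CR"), c(18, 10)),
    category = c(rep("MM_DETECTED", 7), rep("NO_CLONE_DEFINED", 11),
                 rep("MM_NOT_DETECTED", 10))
  )
  sm <- summarize_cohort(results)
  idrd_det <- sm$percent[sm$group == "ID/RD" & sm$category == "MM_DETECTED"]
  expect_equal(round(idrd_det, 1), 38.9)
  sums <- tapply(sm$percent, sm$group, sum)
  expect_true(all(abs(sums - 100) < 0.1))
  expect_equal(sum(sm$count), nrow(results))
  expect_false("VGPR" %in% sm$group)  # empty groups omitted
  single <- summarize_cohort(tibble::tibble(group = "PR", category = "X"))
  expect_equal(single$percent, 100)
})
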