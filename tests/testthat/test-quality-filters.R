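# Technical QC: site quality, coverage, strand bias, upstream filters.

test_that("site quality applies strict thresholds to qual and carrier depth", {
  # qual 35, carrier depths {12, 9} -> pass
  co <- mk_cohort(1, samples = c("A", "B", "C"), gt = c(1, 1, 0),
                  dp = c(12, 9, 2), qual = 35)
  expect_true(qc_site_quality(co))
  # boundary qual exactly 20 fails the strict rule
  expect_false(qc_site_quality(mk_cohort(1, qual = 20)))
  # one carrier at depth exactly 5 fails despite qual 50
  co <- mk_cohort(1, samples = c("A", "B"), gt = c(1, 1), dp = c(30, 5),
                  qual = 50)
  expect_false(qc_site_quality(co))
  # non-carrier low depth does not veto under carrier scope...
  co <- mk_cohort(1, samples = c("A", "B"), gt = c(1, 0), dp = c(30, 2))
  expect_true(qc_site_quality(co))
  # ...but does under depth_scope = "all"
  expect_false(qc_site_quality(co, qc_thresholds(depth_scope = "all")))
  # carrier with missing depth fails
  co <- mk_cohort(1, samples = c("A", "B"), gt = c(1, 0),
                  dp = matrix(c(NA, 30), 1))
  expect_false(qc_site_quality(co))
  # relaxed mode: >= instead of >
  expect_true(qc_site_quality(mk_cohort(1, qual = 20, dp = 5),
                              qc_thresholds(strict = FALSE)))
})

test_that("strand bias pools alt reads over carriers and needs both strands", {
  co <- mk_cohort(1, samples = c("A", "B"), gt = c(1, 0),
                  adf = c(1, 0), adr = c(1, 0))
  expect_true(qc_strand_bias(co))
  co <- mk_cohort(1, samples = c("A", "B"), gt = c(1, 1),
                  adf = c(7, 0), adr = c(0, 0))
  expect_false(qc_strand_bias(co))
  co <- mk_cohort(1, gt = 0, adf = 0, adr = 0)
  expect_false(qc_strand_bias(co))  # no alt evidence at all
  # pooling: each carrier one-sided, together two-sided
  co <- mk_cohort(1, samples = c("A", "B"), gt = c(1, 1),
                  adf = c(3, 0), adr = c(0, 4), dp = 10)
  expect_true(qc_strand_bias(co))
  expect_error(qc_strand_bias(mk_cohort(1, vclass = "INDEL")), "SNV")
})

test_that("upstream FILTER rule for indels", {
  expect_true(qc_upstream_filter(mk_cohort(1, vclass = "INDEL",
                                           filter = "PASS")))
  expect_false(qc_upstream_filter(mk_cohort(1, vclass = "INDEL",
                                            filter = "badReads")))
  miss <- mk_cohort(1, vclass = "INDEL", filter = NA)
  expect_false(qc_upstream_filter(miss))
  expect_true(qc_upstream_filter(miss,
                                 qc_thresholds(missing_filter_fails = FALSE)))
})

test_that("apply_technical_qc matches a per-record oracle on a mixed fixture", {
  set.seed(41)
  n <- 40
  qual <- sample(c(15, 25, 50), n, replace = TRUE)
  gt <- matrix(sample(0:1, n * 3, replace = TRUE), n, 3)
  dp <- matrix(sample(c(3, 10, 30), n * 3, replace = TRUE), n, 3)
  adf <- matrix(sample(0:5, n * 3, replace = TRUE), n, 3) * gt
  adr <- matrix(sample(0:5, n * 3, replace = TRUE), n, 3) * gt
  dp <- pmax(dp, adf + adr)
  vclass <- sample(c("SNV", "INDEL"), n, replace = TRUE)
  filter <- sample(c("PASS", "badReads"), n, replace = TRUE)
  co <- mk_cohort(n, samples = c("A", "B", "C"), gt = gt, dp = dp,
                  adf = adf, adr = adr, qual = qual, vclass = vclass,
                  filter = filter)
  st <- apply_technical_qc(co)
  expected <- vapply(seq_len(n), function(i) {
    carr <- which(gt[i, ] >= 1)
    if (!(qual[i] > 20)) return(FALSE)
    if (any(dp[i, carr] <= 5)) return(FALSE)
    if (vclass[i] == "SNV")
      sum(adf[i, carr]) >= 1 && sum(adr[i, carr]) >= 1
    else filter[i] == "PASS"
  }, logical(1))
  expect_equal(st$verdict, expected)
  # survivors are a subset of the input
  expect_true(all(st$cohort$variants$variant_id %in% co$variants$variant_id))
  # idempotence
  st2 <- apply_technical_qc(st$cohort)
  expect_identical(st2$cohort$variants, st$cohort$variants)
})

test_that("technical QC is monotone in its thresholds", {
  set.seed(42)
  co <- mk_cohort(30, gt = matrix(sample(0:1, 90, TRUE), 30),
                  dp = matrix(sample(2:40, 90, TRUE), 30),
                  qual = sample(10:60, 30, TRUE))
  base <- apply_technical_qc(co, qc_thresholds())$verdict
  for (thr in list(qc_thresholds(min_qual = 35),
                   qc_thresholds(min_depth = 12),
                   qc_thresholds(min_qual = 35, min_depth = 12))) {
    harder <- apply_technical_qc(co, thr)$verdict
    expect_true(all(base | !harder))  # raising thresholds never adds survivors
  }
})
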