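# Segregation under the dominant model with five-level statuses.

# canonical worked family: definite cases A, B; phenocopy-possible C;
# non-carrier controls D, E; possible-carrier F (all founders for simplicity
# -- segregation constraints read statuses, not the family graph)
worked_ped <- function() {
  pedigree(id = c("A", "B", "C", "D", "E", "F"),
           sex = "unknown", sequenced = TRUE,
           status = c("CASE_DEFINITE", "CASE_DEFINITE",
                      "CASE_POSSIBLE_PHENOCOPY", "CONTROL_NONCARRIER",
                      "CONTROL_NONCARRIER", "CONTROL_POSSIBLE_CARRIER"))
}

gt_for <- function(carriers, members = c("A", "B", "C", "D", "E", "F")) {
  setNames(as.numeric(members %in% carriers), members)
}

test_that("carrier_set follows the dominant model and tracks missing separately", {
  cs <- carrier_set(c(A = 1, B = 0, C = 2))
  expect_equal(cs$carriers, c("A", "C"))
  expect_equal(cs$unknown, character(0))
  expect_equal(carrier_set(c(A = 0, B = 0))$carriers, character(0))
  cs <- carrier_set(c(A = NA, B = 1))
  expect_equal(cs$carriers, "B")
  expect_equal(cs$unknown, "A")
})

test_that("worked-family verdicts: tolerated phenocopy and possible carrier", {
  ped <- worked_ped()
  # carriers {A, B, F}: C's absence tolerated, F's carriage tolerated
  expect_true(segregates(gt_for(c("A", "B", "F")), ped)$passes)
  v <- segregates(gt_for(c("A", "B", "C", "D")), ped)
  expect_false(v$passes)
  expect_equal(v$violated_constraints$member_id, "D")
  expect_equal(v$violated_constraints$constraint, "noncarrier-control-carries")
  v <- segregates(gt_for("A"), ped)
  expect_false(v$passes)
  expect_true("B" %in% v$violated_constraints$member_id)
  expect_true("definite-case-missing" %in% v$violated_constraints$constraint)
})

test_that("verdicts equal the brute-force oracle over all 2^6 carrier patterns", {
  ped <- worked_ped()
  members <- c("A", "B", "C", "D", "E", "F")
  status <- ped$status[match(members, ped$id)]
  policies <- list(
    segregation_policy(),
    segregation_policy(max_missing_definite_cases = 1),
    segregation_policy(max_carrier_noncarrier_controls = 1),
    segregation_policy(max_missing_phenocopy_cases = 0,
                       max_carrier_possible_controls = 0))
  for (policy in policies) {
    for (pattern in 0:(2^6 - 1)) {
      gt <- setNames(as.numeric(bitwAnd(pattern, 2^(0:5)) > 0), members)
      expect_equal(
        segregates(gt, ped, policy)$passes,
        oracle_segregates(gt, status,
                          policy$max_missing_definite_cases,
                          policy$max_missing_phenocopy_cases,
                          policy$max_carrier_noncarrier_controls,
                          policy$max_carrier_possible_controls),
        info = sprintf("pattern %d", pattern))
    }
  }
})

test_that("missing genotypes: noninformative vs strict rules", {
  ped <- worked_ped()
  gt <- gt_for(c("B", "F"))
  gt["A"] <- NA  # definite case with missing genotype
  expect_true(segregates(gt, ped)$passes)  # counts toward no constraint
  strict <- segregation_policy(missing_genotype_rule = "strict")
  expect_false(segregates(gt, ped, strict)$passes)
  gt2 <- gt_for(c("A", "B"))
  gt2["D"] <- NA  # non-carrier control missing
  expect_true(segregates(gt2, ped)$passes)
  expect_false(segregates(gt2, ped, strict)$passes)
})

test_that("verdicts ignore UNINFORMATIVE members and record order", {
  ped <- worked_ped()
  ped2 <- pedigree(id = c(ped$id, "Z"), sex = "unknown",
                   sequenced = c(ped$sequenced, TRUE),
                   status = c(ped$status, "UNINFORMATIVE"))
  gt <- gt_for(c("A", "B"))
  for (zgt in c(0, 1, NA)) {
    gtz <- c(gt, Z = zgt)
    expect_equal(segregates(gtz, ped2)$passes, segregates(gt, ped)$passes)
  }
  set.seed(5)
  co <- mk_gt_cohort(matrix(sample(0:1, 20 * 6, TRUE), 20,
                            dimnames = list(NULL, ped$id)))
  shuffle <- sample(20)
  a <- apply_segregation(co, ped)$verdict
  b <- apply_segregation(co[shuffle], ped)$verdict
  expect_equal(b, a[shuffle])
})

test_that("relaxing any tolerance never removes a survivor", {
  ped <- worked_ped()
  set.seed(6)
  gt <- matrix(sample(c(0, 1, NA), 60 * 6, TRUE, prob = c(0.5, 0.4, 0.1)),
               60, 6, dimnames = list(NULL, ped$id))
  co <- mk_gt_cohort(gt)
  base <- apply_segregation(co, ped)$verdict
  relaxed <- list(
    segregation_policy(max_missing_definite_cases = 1),
    segregation_policy(max_carrier_noncarrier_controls = 2),
    segregation_policy(max_missing_definite_cases = 2,
                       max_carrier_noncarrier_controls = 1))
  for (policy in relaxed) {
    v <- apply_segregation(co, ped, policy)$verdict
    expect_true(all(v | !base))
  }
  # tightening the optional tolerances only removes survivors
  tight <- segregation_policy(max_missing_phenocopy_cases = 0,
                              max_carrier_possible_controls = 0)
  v <- apply_segregation(co, ped, tight)$verdict
  expect_true(all(base | !v))
})

test_that("apply_segregation keeps a constructed causal pattern and errors on unknown samples", {
  ped <- worked_ped()
  co <- mk_gt_cohort(matrix(c(1, 1, 0, 0, 0, 1), 1,
                            dimnames = list(NULL, ped$id)))
  st <- apply_segregation(co, ped)
  expect_equal(st$verdict, TRUE)
  bad <- mk_gt_cohort(matrix(1, 1, 2, dimnames = list(NULL, c("A", "NOPE"))))
  expect_error(apply_segregation(bad, ped), "not in pedigree")
  unseq <- pedigree(id = c("A", "B"), sex = "unknown",
                    sequenced = c(TRUE, FALSE),
                    status = c("CASE_DEFINITE", NA))
  both <- mk_gt_cohort(matrix(1, 1, 2, dimnames = list(NULL, c("A", "B"))))
  expect_error(apply_segregation(both, unseq), "sequenced")
})
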