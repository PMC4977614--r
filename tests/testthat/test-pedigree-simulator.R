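# The gene-drop simulator.

test_that("simulated pedigrees are valid, deterministic, and template-shaped", {
  spec <- simulation_spec()
  p1 <- simulate_pedigree(spec, seed = 4)
  p2 <- simulate_pedigree(spec, seed = 4)
  expect_identical(p1, p2)
  expect_s3_class(validate_pedigree(p1), "pedigree")
  expect_equal(max(p1$generation), spec$generations - 1L)
  # sexes consistent with parenthood by construction (validate would throw)
  p3 <- simulate_pedigree(simulation_spec(generations = 4, sibship = 2),
                          seed = 4)
  expect_equal(max(p3$generation), 3L)
})

test_that("gene_drop obeys the degenerate frequencies and Mendel's law", {
  ped <- simulate_pedigree(simulation_spec(), seed = 2)
  expect_true(all(gene_drop(ped, freq = 0, n = 5, seed = 1) == 0))
  expect_true(all(gene_drop(ped, freq = 1, n = 5, seed = 1) == 2))
  # het x hom-ref: offspring carrier fraction 1/2 over many drops
  trio <- pedigree(id = c("P", "Q", "K"), father = c(NA, NA, "P"),
                   mother = c(NA, NA, "Q"),
                   sex = c("male", "female", "female"))
  n <- 2e4
  dos <- matrix(0, n, 3, dimnames = list(NULL, trio$id))
  dos[, "P"] <- 1
  kid <- pedscreen:::gene_drop_core(trio, dos)[, "K"]
  phat <- mean(kid >= 1)
  expect_lt(abs(phat - 0.5), 2.576 * sqrt(0.25 / n))  # binomial 99% CI
  # origin mode: single het copy in the designated founder
  g <- gene_drop(ped, origin = founders(ped)[1], n = 3, seed = 9)
  expect_true(all(g[, founders(ped)[1]] == 1))
  expect_true(all(g[, setdiff(founders(ped), founders(ped)[1])] == 0))
  expect_error(gene_drop(ped, origin = "G3I1"), "founder")
})

test_that("causal injection: deterministic limit and phenotype-only statuses", {
  spec <- simulation_spec()
  ped <- simulate_pedigree(spec, seed = 8)
  set.seed(1)
  inj <- inject_causal(ped, spec)
  # penetrance 1, phenocopy 0: affected set == carrier set
  expect_setequal(inj$ped$id[inj$ped$affected], inj$carriers)
  # statuses never contradict observable phenotype
  st <- inj$ped$status
  aff <- inj$ped$affected
  expect_true(all(st[aff & inj$ped$sequenced] %in%
                    c("CASE_DEFINITE", "CASE_POSSIBLE_PHENOCOPY")))
  expect_true(all(st[!aff & inj$ped$sequenced] %in%
                    c("CONTROL_NONCARRIER", "CONTROL_POSSIBLE_CARRIER")))
  # a young unaffected carrier is a possible carrier, not a non-carrier
  young <- inj$ped$id[!aff & (spec$ref_year - inj$ped$birth_year) <
                        spec$young_control_age]
  expect_true(all(st[match(young, inj$ped$id)] == "CONTROL_POSSIBLE_CARRIER"))
})

test_that("phenocopies appear and default segregation still passes the causal variant", {
  spec <- simulation_spec(phenocopy_rate = 0.4)
  # find a seeded replicate exhibiting an affected non-carrier
  found <- FALSE
  for (s in 1:30) {
    sim <- simulate_cohort(spec, seed = s)
    pheno <- setdiff(sim$ped$id[sim$ped$affected], sim$truth$carriers)
    if (length(pheno) > 0) { found <- TRUE; break }
  }
  expect_true(found)
  expect_true(all(sim$ped$status[match(pheno, sim$ped$id)] %in%
                    c("CASE_POSSIBLE_PHENOCOPY", "CASE_DEFINITE")))
  # under the default policy a *late-onset* phenocopy cannot kill the causal
  # variant; verify the causal variant still segregates in this replicate
  late <- sim$ped$diagnosis_year - sim$ped$birth_year >= spec$late_onset_age
  if (all(match(pheno, sim$ped$id) %in% which(late))) {
    gt <- sim$cohort$geno$gt[sim$truth$causal_index, ]
    expect_true(segregates(gt, sim$ped)$passes)
  }
})

test_that("simulated cohorts are seed-reproducible end to end", {
  s1 <- simulate_cohort(simulation_spec(n_decoys = 25), seed = 12)
  s2 <- simulate_cohort(simulation_spec(n_decoys = 25), seed = 12)
  expect_identical(s1$cohort$variants, s2$cohort$variants)
  expect_identical(s1$cohort$geno, s2$cohort$geno)
  expect_identical(s1$cohort$annotations, s2$cohort$annotations)
  expect_identical(s1$ped, s2$ped)
  s3 <- simulate_cohort(simulation_spec(n_decoys = 25), seed = 13)
  expect_false(identical(s1$cohort$geno$gt, s3$cohort$geno$gt))
})

test_that("causal annotations pass every gate by construction; boundary decoys sit on thresholds", {
  sim <- simulate_cohort(simulation_spec(), seed = 19)
  i <- sim$truth$causal_index
  a <- sim$cohort$annotations[i, ]
  expect_true(is_rare(a))
  expect_true(passes_cadd_gate(a$cadd_phred))
  expect_true(consensus_deleterious(a[c("mutation_taster", "polyphen2",
                                        "provean", "sift")]))
  expect_true(passes_conservation(a))
  # planted boundary decoys: exact threshold values occur in the pool
  ann <- sim$cohort$annotations
  expect_true(any(ann$cadd_phred == 10, na.rm = TRUE))
  expect_true(any(ann$maf_1kg == 0.001, na.rm = TRUE))
  expect_true(any(ann$gerp == 2.0, na.rm = TRUE))
  # and the strict gates exclude them
  expect_false(passes_cadd_gate(10))
  expect_false(is_rare(data.frame(maf_1kg = 0.001, maf_exac = NA)))
})
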