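# Domain types and VCF / PED / sidecar readers and writers.

vcf_header <- function(samples, extra = character(0)) {
  c("##fileformat=VCFv4.2",
    '##INFO=<ID=CADD,Number=1,Type=Float,Description="x">',
    '##INFO=<ID=REGION,Number=1,Type=String,Description="x">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="x">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="x">',
    '##FORMAT=<ID=ADF,Number=1,Type=Integer,Description="x">',
    '##FORMAT=<ID=ADR,Number=1,Type=Integer,Description="x">',
    extra,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

write_tmp_vcf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("reading a small annotated VCF maps fields and leaves the rest missing", {
  path <- write_tmp_vcf(c(
    vcf_header(c("S1", "S2", "S3")),
    "1\t100\t.\tA\tG\t60\tPASS\tCADD=12.5;REGION=missense\tGT:DP\t0/1:20\t0/0:18\t1/1:22",
    "2\t200\t.\tC\tT\t45\tPASS\tREGION=utr3\tGT:DP\t0/0:30\t0/1:25\t./.:10"))
  cohort <- read_annotated_vcf(path)
  expect_s3_class(cohort, "variant_cohort")
  expect_equal(n_variants(cohort), 2L)
  expect_equal(cohort$samples, c("S1", "S2", "S3"))
  expect_equal(cohort$annotations$cadd_phred, c(12.5, NA))
  # everything not mapped stays missing, never defaulted
  expect_true(all(is.na(cohort$annotations$maf_1kg)))
  expect_true(all(is.na(cohort$annotations$sift)))
  expect_equal(cohort$variants$region, c("missense", "utr3"))
  expect_equal(unname(cohort$geno$gt[1, ]), c(1, 0, 2))
  expect_equal(unname(cohort$geno$gt[2, ]), c(0, 1, NA))
  expect_equal(unname(cohort$geno$dp[2, ]), c(30, 25, 10))
})

test_that("multi-allelic sites decompose into one record per alt allele", {
  path <- write_tmp_vcf(c(
    vcf_header("S1"),
    "1\t100\t.\tA\tG,T\t60\tPASS\tREGION=missense\tGT\t1/2",
    "1\t200\t.\tC\tT\t50\tPASS\tREGION=utr5\tGT\t0/1"))
  cohort <- read_annotated_vcf(path)
  # allele-count conservation: 2 + 1 alt alleles in -> 3 records out
  expect_equal(n_variants(cohort), 3L)
  expect_equal(cohort$variants$alt[1:2], c("G", "T"))
  expect_equal(cohort$variants$pos[1:2], c(100L, 100L))
  # genotype 1/2 is het for each decomposed alt separately
  expect_equal(unname(cohort$geno$gt[1:2, 1]), c(1, 1))
})

test_that("per-sample strand fields populate from the mapped FORMAT keys", {
  path <- write_tmp_vcf(c(
    vcf_header(c("S1", "S2")),
    paste0("1\t100\t.\tA\tG\t60\tPASS\tREGION=missense\tGT:DP:ADF:ADR\t",
           "0/1:20:7:5\t0/0:18:0:0")))
  cohort <- read_annotated_vcf(path)
  # hand-parsed expectations from the fixture line
  expect_equal(unname(cohort$geno$adf[1, ]), c(7, 0))
  expect_equal(unname(cohort$geno$adr[1, ]), c(5, 0))
  expect_equal(unname(cohort$geno$dp[1, ]), c(20, 18))
})

test_that("a VCF without sample columns is a configuration error", {
  path <- write_tmp_vcf(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=REGION,Number=1,Type=String,Description="x">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    "1\t100\t.\tA\tG\t60\tPASS\tREGION=missense"))
  expect_error(read_annotated_vcf(path), "sample columns")
})

test_that("variant_cohort enforces its invariants", {
  expect_error(mk_cohort(1, qual = 50, region = "bogus"), "region")
  v <- data.frame(variant_id = "1:1:A:A", chrom = "1", pos = 1, ref = "A",
                  alt = "A", vclass = "SNV", region = "missense", qual = 1,
                  filter = NA)
  expect_error(variant_cohort(v, "S1"), "ref must differ")
  v$alt <- "AT"
  v$variant_id <- "1:1:A:AT"
  expect_error(variant_cohort(v, "S1"), "vclass")
  co <- mk_cohort(2, samples = c("A", "B"))
  expect_error(variant_cohort(co$variants, co$samples,
                              modifyList(co$geno, list(gt = co$geno$gt + 3))),
               "dosages")
})

test_that("PED + sidecar reading resolves founders, statuses and errors", {
  ped_path <- withr::local_tempfile(fileext = ".ped")
  st_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("FAM1\tP1\t0\t0\t1\t2",
               "FAM1\tP2\t0\t0\t2\t1",
               "FAM1\tK1\tP1\tP2\t1\t2",
               "FAM1\tK2\tP1\tP2\t2\t1"), ped_path)
  writeLines(c("individual_id\tstatus",
               "K1\tCASE_DEFINITE",
               "K2\tCONTROL_NONCARRIER"), st_path)
  ped <- read_pedigree(ped_path, st_path)
  expect_s3_class(ped, "pedigree")
  expect_true(is.na(ped$father[ped$id == "P1"]))      # founder convention
  expect_equal(sort(sequenced_members(ped)), c("K1", "K2"))
  expect_equal(ped$status[ped$id == "P1"], "UNINFORMATIVE")
  expect_false(ped$sequenced[ped$id == "P1"])

  writeLines(c("individual_id\tstatus", "NOPE\tCASE_DEFINITE"), st_path)
  expect_error(read_pedigree(ped_path, st_path), "unknown individual")
})

test_that("pedigree validation rejects cycles and sex-inconsistent parents", {
  # an individual who is their own grandparent
  expect_error(pedigree(id = c("A", "B", "C"),
                        father = c("C", "A", "B"),
                        mother = c(NA, NA, NA),
                        sex = "male"),
               "cyclic")
  expect_error(pedigree(id = c("A", "B"), father = c(NA, "A"),
                        mother = c(NA, NA),
                        sex = c("female", "male")),
               "father listed as female")
  expect_error(pedigree(id = "A", sequenced = TRUE), "status")
})

test_that("worked-example family loads with the narrative statuses", {
  ped <- example_family()
  expect_equal(sum(ped$sequenced), 6L)
  st <- ped$status[ped$sequenced]
  expect_equal(sum(st == "CASE_DEFINITE"), 2L)
  expect_equal(sum(st == "CASE_POSSIBLE_PHENOCOPY"), 1L)
  expect_equal(sum(st == "CONTROL_NONCARRIER"), 2L)
  expect_equal(sum(st == "CONTROL_POSSIBLE_CARRIER"), 1L)
})

test_that("simulator output round-trips through VCF + PED + sidecar exactly", {
  sim <- simulate_cohort(simulation_spec(n_decoys = 40), seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_cohort(sim$cohort, sim$ped, dir)
  back <- read_annotated_vcf(paths["vcf"])
  expect_identical(back$geno$gt, sim$cohort$geno$gt)
  expect_identical(back$geno$dp, sim$cohort$geno$dp)
  expect_identical(back$geno$adf, sim$cohort$geno$adf)
  expect_identical(back$geno$adr, sim$cohort$geno$adr)
  expect_equal(back$annotations, sim$cohort$annotations)
  expect_equal(back$variants, sim$cohort$variants)
  ped2 <- read_pedigree(paths["ped"], paths["statuses"])
  expect_identical(ped2$status, sim$ped$status)
  expect_identical(ped2$sequenced, sim$ped$sequenced)
  # the TSV sidecar transport carries the same annotations
  side <- read_annotation_tsv(paths["annotations"])
  blank <- sim$cohort
  blank$annotations <- pedscreen:::empty_annotations(blank$variants$variant_id)
  merged <- merge_annotations(blank, side)
  expect_equal(merged$annotations$cadd_phred, sim$cohort$annotations$cadd_phred)
  expect_equal(merged$annotations$sift, sim$cohort$annotations$sift)
  expect_equal(merged$annotations$haploreg_flags,
               sim$cohort$annotations$haploreg_flags)
})

test_that("write_outputs is deterministic and handles zero candidates", {
  sim <- simulate_cohort(simulation_spec(n_decoys = 30), seed = 9)
  res <- suppressWarnings(run_pipeline(sim$cohort, sim$ped))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_outputs(res, d1)
  p2 <- write_outputs(res, d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  # empty result: header-only candidate table plus a complete funnel
  cfg <- pipeline_config(cadd_min = 99.9)
  res0 <- suppressWarnings(run_pipeline(sim$cohort, sim$ped, cfg))
  expect_equal(nrow(res0$candidates), 0L)
  d0 <- withr::local_tempdir()
  p0 <- write_outputs(res0, d0)
  tab <- read.delim(p0[["candidates"]])
  expect_equal(nrow(tab), 0L)
  fl <- jsonlite::read_json(p0[["funnel"]], simplifyVector = TRUE)
  expect_equal(fl$stages$stage,
               c("input", "technical_qc", "rarity", "segregation",
                 "cadd_gate", "conservation", "branch"))
})
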