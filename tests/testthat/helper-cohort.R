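# Compact builders for in-code fixtures.

# Build a variant_cohort from per-variant scalars/vectors and genotype
# matrices. Matrix arguments are recycled row-wise from vectors if needed.
mk_cohort <- function(n = 1L, samples = c("A", "B", "C"),
                      gt = 1, dp = 30, adf = 8, adr = 7,
                      region = "missense", vclass = NULL,
                      qual = 50, filter = "PASS", ann = list()) {
  as_mat <- function(x) {
    if (is.matrix(x)) {
      stopifnot(nrow(x) == n, ncol(x) == length(samples))
      x
    } else {
      matrix(rep_len(x, n * length(samples)), n, length(samples),
             byrow = TRUE)
    }
  }
  region <- rep_len(region, n)
  if (is.null(vclass)) vclass <- rep("SNV", n)
  vclass <- rep_len(vclass, n)
  ref <- ifelse(vclass == "SNV", "A", "AT")
  variants <- data.frame(
    variant_id = sprintf("1:%d:%s:%s", seq_len(n) * 100L, ref, "C"),
    chrom = "1", pos = seq_len(n) * 100L, ref = ref, alt = "C",
    vclass = vclass, region = region,
    qual = rep_len(qual, n), filter = rep_len(filter, n),
    stringsAsFactors = FALSE)
  anndf <- NULL
  if (length(ann) > 0L) {
    anndf <- data.frame(variant_id = variants$variant_id,
                        stringsAsFactors = FALSE)
    for (k in names(ann)) anndf[[k]] <- rep_len(ann[[k]], n)
  }
  dpm <- as_mat(dp)
  adfm <- pmin(as_mat(adf), dpm)      # keep read-count invariant when only
  adrm <- pmin(as_mat(adr), dpm - adfm)  # dp is customised by a test
  variant_cohort(variants, samples,
                 list(gt = as_mat(gt), dp = dpm, adf = adfm, adr = adrm),
                 anndf)
}

# Minimal cohort wrapping a pre-built genotype matrix (e.g. from gene_drop)
mk_gt_cohort <- function(gt, region = "missense", qual = 50, ann = list()) {
  n <- nrow(gt)
  mk_cohort(n = n, samples = colnames(gt), gt = gt,
            dp = matrix(30, n, ncol(gt)), adf = matrix(8, n, ncol(gt)),
            adr = matrix(7, n, ncol(gt)), region = region, qual = qual,
            ann = ann)
}

# The segregation-null test pedigree: origin founder F, one constrained
# lineage. Sequenced/constrained members: A, B, D definite cases; C, E
# non-carrier controls. Exactly 5 informative meioses for a variant private
# to F (F->A, A->B, A->C, A->D, D->E), so a decoy from F survives the
# default policy with probability 2^-5.
null_test_pedigree <- function() {
  pedigree(
    id = c("F", "M", "A", "SA", "B", "C", "D", "SD", "E"),
    father = c(NA, NA, "F", NA, "A", "A", "A", NA, "D"),
    mother = c(NA, NA, "M", NA, "SA", "SA", "SA", NA, "SD"),
    sex = c("male", "female", "male", "female", "male", "female", "male",
            "female", "female"),
    affected = c(NA, NA, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    status = c(NA, NA, "CASE_DEFINITE", NA, "CASE_DEFINITE",
               "CONTROL_NONCARRIER", "CASE_DEFINITE", NA,
               "CONTROL_NONCARRIER"),
    sequenced = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  )
}

# A three-generation pedigree with first cousins for kinship tests:
# F x M -> A, B; A x SA -> C; B x SB -> D; C and D are first cousins.
cousin_pedigree <- function() {
  pedigree(
    id = c("F", "M", "A", "B", "SA", "SB", "C", "D"),
    father = c(NA, NA, "F", "F", NA, NA, "A", "B"),
    mother = c(NA, NA, "M", "M", NA, NA, "SA", "SB"),
    sex = c("male", "female", "male", "male", "female", "female",
            "female", "male")
  )
}
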