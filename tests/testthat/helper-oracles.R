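# Independent oracles. These deliberately re-derive every rule with plain
# per-record loops and never call the package's filter predicates.

# Monte-Carlo kinship by gene-dropping unique founder allele labels:
# phi(i, j) = P(allele drawn from i IBD to allele drawn from j).
mc_kinship <- function(ped, i, j, ndrop = 1e5) {
  ord <- order(ped$generation)
  n_mem <- nrow(ped)
  a1 <- matrix(0L, ndrop, n_mem, dimnames = list(NULL, ped$id))
  a2 <- a1
  lab <- 0L
  for (k in seq_len(n_mem)[order(ped$generation)]) {
    if (is.na(ped$father[k])) {
      lab <- lab + 2L
      a1[, k] <- lab - 1L
      a2[, k] <- lab
    } else {
      fa <- ped$father[k]; mo <- ped$mother[k]
      pick <- stats::runif(ndrop) < 0.5
      a1[, k] <- ifelse(pick, a1[, fa], a2[, fa])
      pick <- stats::runif(ndrop) < 0.5
      a2[, k] <- ifelse(pick, a1[, mo], a2[, mo])
    }
  }
  ibd <- (a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
    (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])
  est <- mean(ibd / 4)
  se <- stats::sd(ibd / 4) / sqrt(ndrop)
  list(est = est, se = se)
}

# Straight-line segregation rule for one genotype vector (default-policy
# semantics parameterised by tolerances), independent of seg_counts().
oracle_segregates <- function(gt, status,
                              max_def = 0, max_phe = Inf,
                              max_ctl = 0, max_pos = Inf,
                              missing_rule = "noninformative") {
  nd <- np <- nc <- np2 <- 0
  for (s in seq_along(gt)) {
    g <- gt[s]; st <- status[s]
    carr <- !is.na(g) && g >= 1
    noncarr <- !is.na(g) && g == 0
    miss <- is.na(g)
    if (st == "CASE_DEFINITE" &&
        (noncarr || (miss && missing_rule == "strict"))) nd <- nd + 1
    if (st == "CASE_POSSIBLE_PHENOCOPY" && noncarr) np <- np + 1
    if (st == "CONTROL_NONCARRIER" &&
        (carr || (miss && missing_rule == "strict"))) nc <- nc + 1
    if (st == "CONTROL_POSSIBLE_CARRIER" && carr) np2 <- np2 + 1
  }
  nd <= max_def && np <= max_phe && nc <= max_ctl && np2 <= max_pos
}

# Full per-record filter-cascade oracle under the default configuration
# (flag-mode conservation/intolerance/miRNA). Returns the surviving
# variant ids.
oracle_candidates <- function(cohort, ped) {
  v <- cohort$variants
  a <- cohort$annotations
  gt <- cohort$geno$gt; dp <- cohort$geno$dp
  adf <- cohort$geno$adf; adr <- cohort$geno$adr
  status <- ped$status[match(colnames(gt), ped$id)]
  keep <- character(0)
  for (i in seq_len(nrow(v))) {
    g <- gt[i, ]
    carr <- which(!is.na(g) & g >= 1)
    # technical QC
    if (!(v$qual[i] > 20)) next
    ok <- TRUE
    for (s in carr) if (is.na(dp[i, s]) || !(dp[i, s] > 5)) ok <- FALSE
    if (!ok) next
    if (v$vclass[i] == "SNV") {
      f <- sum(adf[i, carr], na.rm = TRUE)
      r <- sum(adr[i, carr], na.rm = TRUE)
      if (!(f >= 1 && r >= 1)) next
    } else {
      if (is.na(v$filter[i]) || v$filter[i] != "PASS") next
    }
    # rarity
    if (!is.na(a$maf_1kg[i]) && a$maf_1kg[i] >= 0.001) next
    if (!is.na(a$maf_exac[i]) && a$maf_exac[i] >= 0.001) next
    # segregation (default policy)
    if (!oracle_segregates(g, status)) next
    # CADD gate
    if (is.na(a$cadd_phred[i]) || !(a$cadd_phred[i] > 10)) next
    # conservation: flag mode, no drop
    # branch
    reg <- v$region[i]
    if (reg == "missense") {
      votes <- 0
      for (k in c("mutation_taster", "polyphen2", "provean", "sift"))
        if (!is.na(a[[k]][i]) && a[[k]][i] == "deleterious")
          votes <- votes + 1
      if (votes < 3) next
    } else if (reg == "other_coding") {
      next  # manual review, not auto-passed
    }
    # splicing: retained high-impact; non-coding branches: evidence gate
    # vacuous at level 0, miRNA flag-mode; "other": reported
    keep <- c(keep, v$variant_id[i])
  }
  keep
}
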