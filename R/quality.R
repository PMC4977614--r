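# Technical QC stage: site quality, coverage, strand bias, upstream filters.

#' Technical QC thresholds
#'
#' @param min_qual minimum Phred site quality (default 20). With
#'   `strict = TRUE` the comparison is `qual > min_qual`.
#' @param min_depth minimum per-sample read depth (default 5), enforced on
#'   carrier samples by default (`depth_scope = "carrier"`) or on every
#'   sample (`"all"`).
#' @param strict use strict inequalities (`>`) for quality and depth
#'   (default), or `>=` when `FALSE`.
#' @param require_strand require pooled alt support on both strands for SNVs.
#' @param missing_filter_fails treat a missing FILTER value on an indel as a
#'   failure (default); set `FALSE` to let missing FILTER pass.
#' @param depth_scope `"carrier"` or `"all"` (see `min_depth`).
#' @return object of class `qc_thresholds`
#' @export
qc_thresholds <- function(min_qual = 20, min_depth = 5, strict = TRUE,
                          require_strand = TRUE, missing_filter_fails = TRUE,
                          depth_scope = c("carrier", "all")) {
  stopifnot(min_qual >= 0, min_depth >= 0)
  depth_scope <- match.arg(depth_scope)
  structure(list(min_qual = min_qual, min_depth = min_depth, strict = strict,
                 require_strand = require_strand,
                 missing_filter_fails = missing_filter_fails,
                 depth_scope = depth_scope),
            class = "qc_thresholds")
}

cmp_gt <- function(x, thr, strict) if (strict) x > thr else x >= thr

#' Site quality and coverage check
#'
#' A variant passes when its site quality exceeds `min_qual` and every
#' in-scope sample (carriers by default) has known depth exceeding
#' `min_depth`. A carrier with missing depth fails the check.
#'
#' @param cohort a [variant_cohort()]
#' @param thr a [qc_thresholds()]
#' @return logical vector, one verdict per variant
#' @export
qc_site_quality <- function(cohort, thr = qc_thresholds()) {
  qual_ok <- cmp_gt(cohort$variants$qual, thr$min_qual, thr$strict)
  qual_ok[is.na(qual_ok)] <- FALSE
  gt <- cohort$geno$gt
  dp <- cohort$geno$dp
  scope <- if (thr$depth_scope == "carrier") {
    !is.na(gt) & gt >= 1
  } else {
    matrix(TRUE, nrow(gt), ncol(gt))
  }
  depth_bad <- scope & (is.na(dp) | !cmp_gt(dp, thr$min_depth, thr$strict))
  unname(qual_ok & rowSums(depth_bad) == 0L)
}

#' Strand-bias check for SNVs
#'
#' Pooled over carrier samples, at least one alt-supporting read must be
#' observed on each strand. Missing strand counts contribute zero evidence.
#' SNV-only: calling this on indel rows is a contract violation and errors.
#'
#' @param cohort a [variant_cohort()]
#' @return logical vector, one verdict per SNV
#' @export
qc_strand_bias <- function(cohort) {
  if (any(cohort$variants$vclass != "SNV"))
    stop("strand-bias check applies to SNVs only")
  carr <- !is.na(cohort$geno$gt) & cohort$geno$gt >= 1
  adf <- ifelse(is.na(cohort$geno$adf), 0, cohort$geno$adf)
  adr <- ifelse(is.na(cohort$geno$adr), 0, cohort$geno$adr)
  unname(rowSums(adf * carr) >= 1 & rowSums(adr * carr) >= 1)
}

#' Upstream caller filter check for indels
#'
#' An indel passes when the VCF FILTER column is `PASS` (the upstream
#' caller's internal filters). Missing FILTER fails by default.
#'
#' @param cohort a [variant_cohort()]
#' @param thr a [qc_thresholds()]
#' @return logical vector, one verdict per variant
#' @export
qc_upstream_filter <- function(cohort, thr = qc_thresholds()) {
  f <- cohort$variants$filter
  ok <- !is.na(f) & f == "PASS"
  if (!thr$missing_filter_fails) ok <- ok | is.na(f) | f == "."
  ok[!is.na(f) & f == "."] <- !thr$missing_filter_fails
  ok
}

#' Apply the technical QC stage
#'
#' SNVs must pass site quality and (by default) the strand-bias rule; indels
#' must pass site quality and the upstream caller's FILTER.
#'
#' @param cohort a [variant_cohort()]
#' @param thr a [qc_thresholds()]
#' @return list with `cohort` (survivors), `verdict` (logical per input
#'   variant) and `stage` name
#' @export
apply_technical_qc <- function(cohort, thr = qc_thresholds()) {
  n <- n_variants(cohort)
  verdict <- qc_site_quality(cohort, thr)
  is_snv <- cohort$variants$vclass == "SNV"
  if (any(is_snv) && thr$require_strand) {
    strand <- qc_strand_bias(cohort[is_snv])
    verdict[is_snv] <- verdict[is_snv] & strand
  }
  if (any(!is_snv)) {
    up <- qc_upstream_filter(cohort, thr)
    verdict[!is_snv] <- verdict[!is_snv] & up[!is_snv]
  }
  list(cohort = cohort[verdict], verdict = verdict, stage = "technical_qc")
}
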