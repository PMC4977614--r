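# Population-frequency rarity filter.

#' Rarity test against population frequency resources
#'
#' A variant is rare when its frequency is below the cutoff in *every*
#' resource that has data for it. A missing frequency counts as rare:
#' variants absent from the population catalogues are the prime candidates.
#' The comparison is strict (`< cutoff`).
#'
#' @param annotations annotation data.frame of a [variant_cohort()] (or any
#'   data.frame with `maf_1kg` / `maf_exac` columns).
#' @param cutoff allele-fraction cutoff in `[0, 1]`; default 0.001 (0.1%).
#'   `cutoff = 1` is vacuous; `cutoff = 0` keeps only catalogue-absent
#'   variants.
#' @return logical vector, one verdict per row
#' @export
is_rare <- function(annotations, cutoff = 0.001) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff >= 0, cutoff <= 1)
  m1 <- annotations$maf_1kg
  m2 <- annotations$maf_exac
  if (any(m1 < 0 | m1 > 1, na.rm = TRUE) || any(m2 < 0 | m2 > 1, na.rm = TRUE))
    stop("MAF values must lie in [0, 1]")
  (is.na(m1) | m1 < cutoff) & (is.na(m2) | m2 < cutoff)
}

#' Apply the rarity filter stage
#'
#' @param cohort a [variant_cohort()]
#' @param cutoff see [is_rare()]
#' @return list with `cohort` (survivors), `verdict`, and `stage` name
#' @export
apply_rarity_filter <- function(cohort, cutoff = 0.001) {
  verdict <- is_rare(cohort$annotations, cutoff)
  list(cohort = cohort[verdict], verdict = verdict, stage = "rarity")
}
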