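# CADD tiers, conservation gating, and routing into the distal branches.

#' CADD tier of a scaled PHRED score
#'
#' A scaled PHRED CADD score above 10 places a substitution in the top 10%
#' of probable functional variants; above 20 in the top 1%; above 30 in the
#' top 0.1%. All boundaries are strict.
#'
#' @param cadd_phred numeric vector of scaled PHRED scores (`NA` = missing)
#' @return character vector over `{"below","top10","top1","top01","missing"}`
#' @export
cadd_tier <- function(cadd_phred) {
  if (any(cadd_phred < 0, na.rm = TRUE))
    stop("scaled CADD scores must be non-negative")
  out <- rep("below", length(cadd_phred))
  out[cadd_phred > 10] <- "top10"
  out[cadd_phred > 20] <- "top1"
  out[cadd_phred > 30] <- "top01"
  out[is.na(cadd_phred)] <- "missing"
  out
}

#' CADD gate
#'
#' Variants with scaled CADD above the threshold (default 10, strict) are
#' taken into further consideration. A missing score fails the gate by
#' default: a variant cannot be ranked without its ranking score.
#'
#' @param cadd_phred numeric vector of scaled PHRED scores
#' @param threshold gate threshold (default 10); may be a vector for
#'   per-region overrides
#' @param missing_passes let variants with no CADD score through (default
#'   `FALSE`)
#' @return logical vector
#' @export
passes_cadd_gate <- function(cadd_phred, threshold = 10,
                             missing_passes = FALSE) {
  tier_ok <- !is.na(cadd_phred) & cadd_phred > threshold
  if (any(cadd_phred < 0, na.rm = TRUE))
    stop("scaled CADD scores must be non-negative")
  tier_ok | (missing_passes & is.na(cadd_phred))
}

#' Conservation check (GERP and PhastCons)
#'
#' GERP > 2.0 and PhastCons > 0.3 indicate good conservation. In
#' `"either"` mode (default) one passing score suffices; in `"both"` mode
#' both must pass. A missing score never passes its own sub-test.
#'
#' @param annotations data.frame with `gerp` and `phastcons` columns
#' @param mode `"either"` or `"both"`
#' @param gerp_min,phastcons_min strict thresholds (defaults 2.0 and 0.3)
#' @return logical vector
#' @export
passes_conservation <- function(annotations, mode = c("either", "both"),
                                gerp_min = 2.0, phastcons_min = 0.3) {
  mode <- match.arg(mode)
  g <- annotations$gerp
  p <- annotations$phastcons
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("phastcons must lie in [0, 1]")
  g_ok <- !is.na(g) & g > gerp_min
  p_ok <- !is.na(p) & p > phastcons_min
  if (mode == "either") g_ok | p_ok else g_ok & p_ok
}

#' Route a variant's region class to a distal branch
#'
#' Coding classes (missense, other coding, splicing) go to the coding
#' branch; each UTR has its own branch; intronic and intergenic variants are
#' evaluated together on the regulatory (intergenic) branch. Anything else
#' is reported under `"other"`, never silently dropped.
#'
#' @param region character vector over [REGION_LEVELS]
#' @return character vector over `{"coding","utr5","utr3","intergenic","other"}`
#' @export
route_region <- function(region) {
  map <- c(missense = "coding", other_coding = "coding", splicing = "coding",
           utr5 = "utr5", utr3 = "utr3",
           intronic = "intergenic", intergenic = "intergenic",
           other = "other")
  out <- unname(map[region])
  out[is.na(out)] <- "other"
  out
}

#' Apply the CADD gate stage
#'
#' @param cohort a [variant_cohort()]
#' @param threshold,missing_passes see [passes_cadd_gate()]
#' @return list with `cohort`, `verdict`, `stage`
#' @export
apply_cadd_gate <- function(cohort, threshold = 10, missing_passes = FALSE) {
  verdict <- passes_cadd_gate(cohort$annotations$cadd_phred, threshold,
                              missing_passes)
  list(cohort = cohort[verdict], verdict = verdict, stage = "cadd_gate")
}

#' Apply the conservation stage
#'
#' In `"flag"` mode (default) the conservation verdict is recorded as a
#' reported column but no variant is dropped; in `"gate"` mode failing
#' variants are removed.
#'
#' @param cohort a [variant_cohort()]
#' @param mode,gerp_min,phastcons_min see [passes_conservation()]
#' @param action `"flag"` (report only) or `"gate"` (drop failures)
#' @return list with `cohort`, `verdict` (the stage-survival verdict),
#'   `conserved` (the raw conservation flag), `stage`
#' @export
apply_conservation <- function(cohort, mode = c("either", "both"),
                               gerp_min = 2.0, phastcons_min = 0.3,
                               action = c("flag", "gate")) {
  action <- match.arg(action)
  conserved <- passes_conservation(cohort$annotations, mode,
                                   gerp_min, phastcons_min)
  verdict <- if (action == "gate") conserved
             else rep(TRUE, n_variants(cohort))
  list(cohort = cohort[verdict], verdict = verdict, conserved = conserved,
       stage = "conservation")
}
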