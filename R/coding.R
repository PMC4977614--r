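# Coding branch: four-predictor consensus vote + gene-intolerance sub-stage.

#' Consensus deleteriousness vote
#'
#' A missense variant is kept when at least `min_votes` (default 3) of the
#' four predictors (MutationTaster, PolyPhen-2, PROVEAN, SIFT) call it
#' deleterious. A missing call is no vote; the threshold does not shrink
#' with missing predictors.
#'
#' @param calls data.frame (or list) with columns/elements exactly
#'   `mutation_taster`, `polyphen2`, `provean`, `sift`, each
#'   `"deleterious"`, `"tolerated"` or `NA`.
#' @param min_votes votes required (default 3)
#' @return logical vector
#' @export
consensus_deleterious <- function(calls, min_votes = 3) {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  extra <- setdiff(names(calls), c("variant_id", PREDICTOR_KEYS))
  keep <- intersect(names(calls), PREDICTOR_KEYS)
  if (length(keep) < 4L || length(extra) > 0L)
    stop("predictor calls must be keyed exactly by: ",
         paste(PREDICTOR_KEYS, collapse = ", "))
  votes <- Reduce(`+`, lapply(calls[PREDICTOR_KEYS], function(x) {
    bad <- !is.na(x) & !x %in% c("deleterious", "tolerated")
    if (any(bad)) stop("calls must be deleterious/tolerated/NA")
    as.integer(!is.na(x) & x == "deleterious")
  }))
  votes >= min_votes
}

#' Gene-intolerance check
#'
#' At least `min_sources` of the available intolerance percentiles (in-house,
#' ESP, ExAC; lower percentile = more intolerant gene) must be at or below
#' `max_pct`. When fewer than `min_sources` percentiles are available the
#' variant passes with an `unassessed` flag: intolerance is supplementary
#' evidence, not an exclusion criterion.
#'
#' @param pcts data.frame with columns `intol_inhouse`, `intol_esp`,
#'   `intol_exac` (percentiles in `[0, 100]`, `NA` = missing).
#' @param max_pct qualifying percentile ceiling (default 25)
#' @param min_sources sources required, 1--3 (default 1)
#' @return data.frame with logical columns `pass` and `unassessed`
#' @export
passes_intolerance <- function(pcts, max_pct = 25, min_sources = 1) {
  stopifnot(max_pct >= 0, max_pct <= 100, min_sources %in% 1:3)
  pm <- as.matrix(as.data.frame(pcts)[INTOLERANCE_KEYS])
  if (any(pm < 0 | pm > 100, na.rm = TRUE))
    stop("intolerance percentiles must lie in [0, 100]")
  available <- rowSums(!is.na(pm))
  qualifying <- rowSums(!is.na(pm) & pm <= max_pct)
  unassessed <- available < min_sources
  data.frame(pass = unassessed | qualifying >= min_sources,
             unassessed = unassessed)
}

#' Evaluate the coding branch
#'
#' Missense variants are kept when the consensus vote passes. Splicing
#' variants cannot be scored by missense predictors and bypass the vote with
#' a high-impact flag. Other coding classes (synonymous etc.) are rejected
#' with an explicit manual-review reason rather than auto-passed. The
#' intolerance check runs as a second, separately counted sub-stage so both
#' with- and without-intolerance counts are reported; in `"flag"` mode
#' (default) it annotates without dropping.
#'
#' @param cohort a [variant_cohort()] containing only coding-routed records
#' @param min_votes see [consensus_deleterious()]
#' @param max_pct,min_sources see [passes_intolerance()]
#' @param intolerance_action `"flag"` (annotate only, default) or `"gate"`
#'   (drop failing variants), or `"off"` (skip the sub-stage entirely).
#' @return list with `cohort` (survivors), `verdict`, per-variant columns
#'   (`vote_pass`, `high_impact`, `review_reason`, `intolerance_pass`,
#'   `intolerance_unassessed`), counts `n_post_vote` and `n_post_intolerance`,
#'   and `stage`
#' @export
evaluate_coding <- function(cohort, min_votes = 3, max_pct = 25,
                            min_sources = 1,
                            intolerance_action = c("flag", "gate", "off")) {
  intolerance_action <- match.arg(intolerance_action)
  if (any(route_region(cohort$variants$region) != "coding"))
    stop("evaluate_coding expects coding-routed records only")
  region <- cohort$variants$region
  vote <- consensus_deleterious(
    cohort$annotations[c("variant_id", PREDICTOR_KEYS)], min_votes)
  high_impact <- region == "splicing"
  review <- rep(NA_character_, n_variants(cohort))
  review[region == "other_coding"] <-
    "non-missense coding class: predictor vote not applicable, manual review"
  review[region == "missense" & !vote] <- "consensus vote below threshold"

  verdict <- (region == "missense" & vote) | high_impact
  intol <- passes_intolerance(cohort$annotations, max_pct, min_sources)
  n_post_vote <- sum(verdict)
  if (intolerance_action == "gate") {
    verdict_final <- verdict & intol$pass
  } else {
    verdict_final <- verdict
  }
  n_post_intol <- if (intolerance_action == "off") n_post_vote
                  else sum(verdict & intol$pass)
  list(cohort = cohort[verdict_final], verdict = verdict_final,
       vote_pass = vote, high_impact = high_impact, review_reason = review,
       intolerance_pass = intol$pass,
       intolerance_unassessed = intol$unassessed,
       n_post_vote = n_post_vote, n_post_intolerance = n_post_intol,
       stage = "coding_branch")
}
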