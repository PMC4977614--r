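# Relatedness QC: rare-variant sharing vs pedigree-expected kinship.

#' Observed rare-variant sharing between two samples
#'
#' The Jaccard index of the two rare-variant carrier sets:
#' `|Ri intersect Rj| / |Ri union Rj|`. Symmetric and scale-free. When both
#' sets are empty the statistic is undefined and `NA` is returned.
#'
#' @param rare_carrier_sets named list mapping sample id to a character
#'   vector of rare-variant keys carried by that sample
#' @param i,j sample ids
#' @return Jaccard fraction in `[0, 1]`, or `NA`
#' @export
observed_sharing <- function(rare_carrier_sets, i, j) {
  ri <- unique(rare_carrier_sets[[i]])
  rj <- unique(rare_carrier_sets[[j]])
  u <- length(union(ri, rj))
  if (u == 0L) return(NA_real_)
  length(intersect(ri, rj)) / u
}

#' Relatedness thresholds for the sharing check
#'
#' The concordance rule is rank-based: observed Jaccard sharing has no
#' closed-form mapping to kinship, but its ordering across pairs should
#' follow the ordering of expected kinship. A pair is flagged when
#' (a) it takes part in more than `rank_tolerance` rank inversions against
#' pairs whose expected kinship differs by more than `kinship_gap` and whose
#' observed sharing differs by more than `sharing_gap` (the gaps guard
#' against flagging sampling noise), or (b) its expected kinship is 0 but
#' its observed sharing exceeds `unrelated_max_sharing`.
#'
#' @param rank_tolerance inversions tolerated per pair (default 0)
#' @param kinship_gap minimum expected-kinship difference for an inversion
#'   to count (default 0.05)
#' @param sharing_gap minimum observed-sharing difference for an inversion
#'   to count (default 0.02); on top of this, the difference must exceed
#'   `noise_z` standard errors of the Jaccard difference (binomial SE from
#'   the union sizes), so that sparse rare-variant sets do not produce
#'   spurious inversions
#' @param noise_z z-multiplier of the sampling-noise guard (default 4)
#' @param unrelated_max_sharing absolute sharing ceiling for pairs with
#'   expected kinship 0 (default 0.10)
#' @return object of class `relatedness_thresholds`
#' @export
relatedness_thresholds <- function(rank_tolerance = 0, kinship_gap = 0.05,
                                   sharing_gap = 0.02, noise_z = 4,
                                   unrelated_max_sharing = 0.10) {
  structure(list(rank_tolerance = rank_tolerance, kinship_gap = kinship_gap,
                 sharing_gap = sharing_gap, noise_z = noise_z,
                 unrelated_max_sharing = unrelated_max_sharing),
            class = "relatedness_thresholds")
}

#' Pairwise relatedness check
#'
#' Compares observed rare-variant sharing against pedigree-expected kinship
#' for every pair of sequenced samples and flags discordant pairs (sample
#' swaps, pedigree errors). The check is advisory: callers decide whether a
#' flag warns or aborts.
#'
#' @param ped a [pedigree()]
#' @param rare_carrier_sets named list (sample id -> rare-variant keys); see
#'   [observed_sharing()]. Sample ids must be sequenced pedigree members.
#' @param thresholds a [relatedness_thresholds()]
#' @return object of class `relatedness_report`: data.frame with one row per
#'   unordered pair (`i`, `j`, `expected_kinship`, `observed_sharing`,
#'   `concordant`, `reason`), plus attribute `flagged` (data.frame of
#'   flagged pairs)
#' @export
relatedness_check <- function(ped, rare_carrier_sets,
                              thresholds = relatedness_thresholds()) {
  ids <- names(rare_carrier_sets)
  if (length(ids) < 2L) stop("need at least two sequenced samples")
  phi <- kinship_matrix(ped, ids)
  pairs <- utils::combn(ids, 2L)
  np <- ncol(pairs)
  exp_k <- phi[cbind(pairs[1, ], pairs[2, ])]
  obs <- vapply(seq_len(np), function(p) {
    observed_sharing(rare_carrier_sets, pairs[1, p], pairs[2, p])
  }, numeric(1))
  unions <- vapply(seq_len(np), function(p) {
    length(union(rare_carrier_sets[[pairs[1, p]]],
                 rare_carrier_sets[[pairs[2, p]]]))
  }, numeric(1))
  se <- sqrt(pmax(obs * (1 - obs), 0.25 / pmax(unions, 1)) / pmax(unions, 1))

  inversions <- integer(np)
  usable <- !is.na(obs)
  for (p in seq_len(np)) {
    if (!usable[p]) next
    partner <- usable & seq_len(np) != p
    gap <- thresholds$sharing_gap +
      thresholds$noise_z * sqrt(se[partner]^2 + se[p]^2)
    inv <- (exp_k[partner] > exp_k[p] + thresholds$kinship_gap &
              obs[partner] < obs[p] - gap) |
           (exp_k[partner] < exp_k[p] - thresholds$kinship_gap &
              obs[partner] > obs[p] + gap)
    inversions[p] <- sum(inv)
  }
  rank_flag <- inversions > thresholds$rank_tolerance
  abs_flag <- usable & exp_k == 0 &
    obs > thresholds$unrelated_max_sharing + thresholds$noise_z * se
  reason <- rep(NA_character_, np)
  reason[rank_flag] <- "kinship-rank inversion"
  reason[abs_flag] <- ifelse(rank_flag[abs_flag],
                             "kinship-rank inversion; unrelated pair shares",
                             "unrelated pair shares")
  rep_df <- data.frame(i = pairs[1, ], j = pairs[2, ],
                       expected_kinship = exp_k, observed_sharing = obs,
                       concordant = !(rank_flag | abs_flag),
                       reason = reason, stringsAsFactors = FALSE)
  structure(rep_df,
            flagged = rep_df[!rep_df$concordant, , drop = FALSE],
            class = c("relatedness_report", "data.frame"))
}

#' Rare-variant carrier sets from a cohort
#'
#' Builds, for each sample, the set of rare variants it carries — the input
#' to [relatedness_check()]. By default the cohort is first restricted to
#' rare variants with [is_rare()].
#'
#' @param cohort a [variant_cohort()]
#' @param cutoff rarity cutoff (see [is_rare()]); `NULL` to use all variants
#' @return named list of character vectors of variant ids
#' @export
rare_carrier_sets <- function(cohort, cutoff = 0.001) {
  if (!is.null(cutoff)) cohort <- cohort[is_rare(cohort$annotations, cutoff)]
  carr <- carrier_matrix(cohort)
  carr[is.na(carr)] <- FALSE
  stats::setNames(lapply(cohort$samples, function(s) {
    rownames(carr)[carr[, s]]
  }), cohort$samples)
}
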