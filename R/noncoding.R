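# Non-coding branches: regulatory evidence and miRNA-target scoring.

#' miRNA target call from a mirSVR score
#'
#' A mirSVR score lower than -0.1 indicates a good miRNA target. Missing
#' scores are no evidence.
#'
#' @param mirsvr numeric vector of mirSVR scores (`NA` = missing)
#' @param cutoff strict upper bound (default -0.1)
#' @return logical vector
#' @export
good_mirna_target <- function(mirsvr, cutoff = -0.1) {
  !is.na(mirsvr) & mirsvr < cutoff
}

#' Regulatory evidence level
#'
#' Combines the RegulomeDB-style rank (category `"1a"` strongest through
#' `"7"` weakest) with the number of HaploReg-style evidence flags
#' (enhancer, promoter, TFBS, eQTL, ...). The combination is lexicographic:
#' rank first, then flag count — the ordinal is
#' `rank_ordinal * 100 + flag_count`, so any rank difference dominates any
#' number of flags. Missing everything maps to the lowest level (0).
#'
#' @param annotations data.frame with `regulome_rank` (category string or
#'   `NA`) and `haploreg_flags` (`"|"`-separated tag string or `NA`).
#' @return data.frame with `ordinal` (numeric evidence level),
#'   `regulome_ordinal`, `flag_count`, and `evidence` (human-readable tag
#'   list, `""` when empty)
#' @export
regulatory_evidence <- function(annotations) {
  rank <- annotations$regulome_rank
  bad <- !is.na(rank) & !rank %in% REGULOME_LEVELS
  if (any(bad))
    stop("unrecognised regulome category: ",
         paste(unique(rank[bad]), collapse = ", "))
  reg_ord <- match(rank, REGULOME_LEVELS)
  reg_ord[is.na(reg_ord)] <- 0L

  flags <- annotations$haploreg_flags
  flag_list <- strsplit(ifelse(is.na(flags) | flags == "", "", flags),
                        "|", fixed = TRUE)
  flag_count <- lengths(flag_list)

  evidence <- mapply(function(r, fl) {
    tags <- c(if (!is.na(r)) paste0("regulome:", r),
              if (length(fl) > 0L) paste0("haploreg:", fl))
    paste(tags, collapse = ",")
  }, rank, flag_list, USE.NAMES = FALSE)

  data.frame(ordinal = reg_ord * 100 + flag_count,
             regulome_ordinal = reg_ord,
             flag_count = flag_count,
             evidence = evidence,
             stringsAsFactors = FALSE)
}

#' Evaluate a non-coding branch
#'
#' All three non-coding branches rank their records by regulatory evidence
#' (and, as a secondary key, the conservation flag when supplied). The 3'UTR
#' branch additionally computes the miRNA-target call and promotes good
#' targets to the top of the ranking; by default the call promotes but does
#' not filter (`mirna_action = "flag"`). Records at or above
#' `min_evidence_level` survive; the default level 0 reports everything.
#' Ranking is stable: ties keep input order.
#'
#' @param cohort a [variant_cohort()] containing only records routed to
#'   `branch`
#' @param branch `"utr5"`, `"utr3"` or `"intergenic"`
#' @param min_evidence_level minimum evidence ordinal to survive (default 0)
#' @param mirsvr_cutoff see [good_mirna_target()]
#' @param mirna_action `"flag"` (promote only, default) or `"gate"` (3'UTR
#'   records failing the miRNA call are dropped)
#' @param conserved optional logical vector (conservation flag) used as a
#'   secondary ranking key
#' @return list with `cohort` (survivors, ranked), `verdict` (in input
#'   order), `rank_order` (permutation of surviving input indices),
#'   per-record `evidence` data.frame, `mirna_target` (3'UTR, else all
#'   `FALSE`), and `stage`
#' @export
evaluate_noncoding <- function(cohort, branch = c("utr5", "utr3",
                                                  "intergenic"),
                               min_evidence_level = 0, mirsvr_cutoff = -0.1,
                               mirna_action = c("flag", "gate"),
                               conserved = NULL) {
  branch <- match.arg(branch)
  mirna_action <- match.arg(mirna_action)
  routed <- route_region(cohort$variants$region)
  if (any(routed != branch))
    stop("evaluate_noncoding(", branch, ") received records routed elsewhere")
  n <- n_variants(cohort)
  ev <- regulatory_evidence(cohort$annotations)
  mirna <- if (branch == "utr3") {
    good_mirna_target(cohort$annotations$mirsvr, mirsvr_cutoff)
  } else {
    rep(FALSE, n)
  }
  if (is.null(conserved)) conserved <- rep(FALSE, n)

  verdict <- ev$ordinal >= min_evidence_level
  if (branch == "utr3" && mirna_action == "gate") verdict <- verdict & mirna

  keep <- which(verdict)
  # stable sort: miRNA target first (3'UTR), then evidence, then
  # conservation; ties keep input order
  ord <- keep[order(-as.integer(mirna[keep]), -ev$ordinal[keep],
                    -as.integer(conserved[keep]))]
  list(cohort = cohort[ord], verdict = verdict, rank_order = ord,
       evidence = ev, mirna_target = mirna,
       stage = paste0(branch, "_branch"))
}
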