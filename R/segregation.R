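# Segregation filtering under a dominant model with five-level statuses.

#' Segregation policy
#'
#' Tolerances controlling how strictly a variant must co-segregate with the
#' phenotype. Defaults encode the strict dominant rule: every definite case
#' carries, no non-carrier control carries; members whose status admits a
#' phenocopy or hidden carriage are unconstrained by default.
#'
#' @param model inheritance model; only `"dominant"` is implemented.
#' @param max_missing_definite_cases number of `CASE_DEFINITE` members
#'   allowed to lack the variant (default 0).
#' @param max_missing_phenocopy_cases number of `CASE_POSSIBLE_PHENOCOPY`
#'   members allowed to lack it (default `Inf`).
#' @param max_carrier_noncarrier_controls number of `CONTROL_NONCARRIER`
#'   members allowed to carry it (default 0).
#' @param max_carrier_possible_controls number of `CONTROL_POSSIBLE_CARRIER`
#'   members allowed to carry it (default `Inf`).
#' @param missing_genotype_rule `"noninformative"` (a missing genotype counts
#'   toward no constraint) or `"strict"` (a missing genotype in a
#'   `CASE_DEFINITE` or `CONTROL_NONCARRIER` member fails that member's
#'   constraint).
#' @return object of class `segregation_policy`
#' @export
segregation_policy <- function(model = "dominant",
                               max_missing_definite_cases = 0,
                               max_missing_phenocopy_cases = Inf,
                               max_carrier_noncarrier_controls = 0,
                               max_carrier_possible_controls = Inf,
                               missing_genotype_rule = c("noninformative",
                                                         "strict")) {
  model <- match.arg(model, "dominant")
  missing_genotype_rule <- match.arg(missing_genotype_rule)
  tol <- c(max_missing_definite_cases, max_missing_phenocopy_cases,
           max_carrier_noncarrier_controls, max_carrier_possible_controls)
  if (any(tol < 0)) stop("tolerances must be non-negative")
  structure(list(model = model,
                 max_missing_definite_cases = max_missing_definite_cases,
                 max_missing_phenocopy_cases = max_missing_phenocopy_cases,
                 max_carrier_noncarrier_controls = max_carrier_noncarrier_controls,
                 max_carrier_possible_controls = max_carrier_possible_controls,
                 missing_genotype_rule = missing_genotype_rule),
            class = "segregation_policy")
}

#' Carrier set of a variant under the dominant model
#'
#' @param gt named numeric vector of alt-allele dosages (names = sample ids);
#'   `NA` = missing genotype.
#' @param model inheritance model (only `"dominant"`).
#' @return list with `carriers` (het or hom-alt sample ids) and `unknown`
#'   (samples with missing genotype, tracked separately).
#' @export
carrier_set <- function(gt, model = "dominant") {
  match.arg(model, "dominant")
  list(carriers = names(gt)[!is.na(gt) & gt >= 1],
       unknown = names(gt)[is.na(gt)])
}

# status-group count core shared by segregates() and apply_segregation();
# gt is a variants x samples dosage matrix with sample columns.
seg_counts <- function(gt, ped, policy) {
  ids <- colnames(gt)
  idx <- match(ids, ped$id)
  if (anyNA(idx))
    stop("samples not in pedigree: ",
         paste(ids[is.na(idx)], collapse = ", "))
  if (any(!ped$sequenced[idx]))
    stop("genotyped samples must be sequenced pedigree members: ",
         paste(ids[!ped$sequenced[idx]], collapse = ", "))
  status <- ped$status[idx]

  carr <- !is.na(gt) & gt >= 1
  noncarr <- !is.na(gt) & gt == 0
  miss <- is.na(gt)
  strict <- policy$missing_genotype_rule == "strict"

  count_in <- function(ind, statuses) {
    cols <- status %in% statuses
    if (!any(cols)) return(rep(0L, nrow(gt)))
    rowSums(ind[, cols, drop = FALSE])
  }
  # "not in the carrier set": strictly observed non-carriage under the
  # noninformative rule, non-carriage-or-missing under strict.
  def_missing <- count_in(if (strict) noncarr | miss else noncarr,
                          "CASE_DEFINITE")
  phe_missing <- count_in(noncarr, "CASE_POSSIBLE_PHENOCOPY")
  ctl_carrier <- count_in(if (strict) carr | miss else carr,
                          "CONTROL_NONCARRIER")
  pos_carrier <- count_in(carr, "CONTROL_POSSIBLE_CARRIER")
  list(status = status,
       def_missing = def_missing, phe_missing = phe_missing,
       ctl_carrier = ctl_carrier, pos_carrier = pos_carrier,
       carr = carr, noncarr = noncarr, miss = miss)
}

seg_pass <- function(cnt, policy) {
  cnt$def_missing <= policy$max_missing_definite_cases &
    cnt$phe_missing <= policy$max_missing_phenocopy_cases &
    cnt$ctl_carrier <= policy$max_carrier_noncarrier_controls &
    cnt$pos_carrier <= policy$max_carrier_possible_controls
}

#' Segregation verdict for one variant
#'
#' Evaluates the per-status-group constraints for a single genotype vector
#' and reports which members violated which constraint.
#'
#' @param gt named numeric dosage vector over the sequenced members.
#' @param ped a [pedigree()]
#' @param policy a [segregation_policy()]
#' @return list with `passes` (logical) and `violated_constraints`
#'   (data.frame of `member_id`, `constraint`; empty iff `passes`). Member
#'   violations are reported whenever the group's tolerance is finite and
#'   exceeded.
#' @export
segregates <- function(gt, ped, policy = segregation_policy()) {
  gtm <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  cnt <- seg_counts(gtm, ped, policy)
  strict <- policy$missing_genotype_rule == "strict"
  viol <- data.frame(member_id = character(), constraint = character(),
                     stringsAsFactors = FALSE)
  add <- function(ids, what) {
    if (length(ids) > 0L)
      viol <<- rbind(viol, data.frame(member_id = ids, constraint = what,
                                      stringsAsFactors = FALSE))
  }
  ids <- colnames(cnt$carr)
  if (cnt$def_missing > policy$max_missing_definite_cases) {
    bad <- cnt$status == "CASE_DEFINITE" &
      (cnt$noncarr[1, ] | (strict & cnt$miss[1, ]))
    add(ids[bad], "definite-case-missing")
  }
  if (cnt$phe_missing > policy$max_missing_phenocopy_cases)
    add(ids[cnt$status == "CASE_POSSIBLE_PHENOCOPY" & cnt$noncarr[1, ]],
        "phenocopy-case-missing")
  if (cnt$ctl_carrier > policy$max_carrier_noncarrier_controls) {
    bad <- cnt$status == "CONTROL_NONCARRIER" &
      (cnt$carr[1, ] | (strict & cnt$miss[1, ]))
    add(ids[bad], "noncarrier-control-carries")
  }
  if (cnt$pos_carrier > policy$max_carrier_possible_controls)
    add(ids[cnt$status == "CONTROL_POSSIBLE_CARRIER" & cnt$carr[1, ]],
        "possible-carrier-control-carries")
  list(passes = nrow(viol) == 0L, violated_constraints = viol)
}

#' Apply the segregation stage
#'
#' Vectorised over all variants of the cohort; only sequenced pedigree
#' members constrain the verdict, and `UNINFORMATIVE` members never do.
#'
#' @param cohort a [variant_cohort()]
#' @param ped a [pedigree()]
#' @param policy a [segregation_policy()]
#' @return list with `cohort` (survivors), `verdict`, and `stage` name
#' @export
apply_segregation <- function(cohort, ped, policy = segregation_policy()) {
  cnt <- seg_counts(cohort$geno$gt, ped, policy)
  verdict <- unname(seg_pass(cnt, policy))
  list(cohort = cohort[verdict], verdict = verdict, stage = "segregation")
}
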