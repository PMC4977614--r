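# Stage orchestration: technical QC -> rarity -> relatedness (advisory) ->
# segregation -> CADD gate -> conservation -> region routing -> branch
# evaluation; funnel and provenance assembly.

PIPELINE_STAGES <- c("technical_qc", "rarity", "segregation", "cadd_gate",
                     "conservation", "branch")

#' Run the full prioritization pipeline
#'
#' Executes the filter cascade on an annotated cohort and pedigree. The
#' relatedness check runs after the rarity filter (its statistic is defined
#' on rare variants) and is advisory: flagged pairs warn, unless
#' `strict_relatedness` aborts. Every eliminated variant's first failing
#' stage is recorded in the provenance table.
#'
#' @param cohort a [variant_cohort()]
#' @param ped a [pedigree()]; the cohort's samples must be its sequenced
#'   members
#' @param config a [pipeline_config()]
#' @return object of class `pipeline_result`: list with `candidates`
#'   (ranked data.frame of surviving variants with per-stage verdicts and
#'   branch annotations), `funnel` (a `filter_funnel`), `relatedness` (a
#'   `relatedness_report` or `NULL`), `provenance` (per input variant:
#'   stage verdicts and `first_failing_stage`), and `config`
#' @export
run_pipeline <- function(cohort, ped, config = pipeline_config()) {
  config <- validate_config(config)
  n <- n_variants(cohort)
  vid <- cohort$variants$variant_id
  prov <- data.frame(variant_id = vid, stringsAsFactors = FALSE)
  for (s in PIPELINE_STAGES) prov[[s]] <- NA
  funnel <- new_funnel()
  funnel <- funnel_add(funnel, "input", cohort$variants$region)

  record <- function(stage, keep_ids, verdict) {
    idx <- match(keep_ids, vid)
    prov[[stage]][idx] <<- verdict
  }

  # -- technical QC ---------------------------------------------------------
  thr <- qc_thresholds(config$min_qual, config$min_depth, config$strict_qc,
                       config$require_strand, config$missing_filter_fails,
                       config$depth_scope)
  st <- apply_technical_qc(cohort, thr)
  record("technical_qc", cohort$variants$variant_id, st$verdict)
  cur <- st$cohort
  funnel <- funnel_add(funnel, "technical_qc", cur$variants$region)

  # -- rarity ---------------------------------------------------------------
  st <- apply_rarity_filter(cur, config$maf_cutoff)
  record("rarity", cur$variants$variant_id, st$verdict)
  cur <- st$cohort
  funnel <- funnel_add(funnel, "rarity", cur$variants$region)

  # -- relatedness QC (advisory, not a variant filter) ----------------------
  relatedness <- NULL
  if (length(cur$samples) >= 2L && n_variants(cur) > 0L) {
    sets <- rare_carrier_sets(cur, cutoff = NULL)
    relatedness <- relatedness_check(
      ped, sets,
      relatedness_thresholds(
        rank_tolerance = config$relatedness_rank_tolerance,
        kinship_gap = config$relatedness_kinship_gap,
        sharing_gap = config$relatedness_sharing_gap,
        noise_z = config$relatedness_noise_z,
        unrelated_max_sharing = config$relatedness_unrelated_max))
    flagged <- attr(relatedness, "flagged")
    if (nrow(flagged) > 0L) {
      msg <- paste0("relatedness check flagged ", nrow(flagged), " pair(s): ",
                    paste(flagged$i, flagged$j, sep = "-", collapse = ", "))
      if (isTRUE(config$strict_relatedness)) stop(msg) else warning(msg)
    }
  }

  # -- segregation ----------------------------------------------------------
  policy <- segregation_policy(config$seg_model,
                               config$seg_max_missing_definite,
                               config$seg_max_missing_phenocopy,
                               config$seg_max_carrier_noncarrier,
                               config$seg_max_carrier_possible,
                               config$seg_missing_rule)
  st <- apply_segregation(cur, ped, policy)
  record("segregation", cur$variants$variant_id, st$verdict)
  cur <- st$cohort
  funnel <- funnel_add(funnel, "segregation", cur$variants$region)

  # -- CADD gate (per-region threshold overrides where configured) ----------
  thr_cadd <- rep(config$cadd_min, n_variants(cur))
  rb <- route_region(cur$variants$region)
  for (b in c("coding", "utr5", "utr3", "intergenic")) {
    ov <- config[[paste0("cadd_min_", b)]]
    if (!is.null(ov) && !is.na(ov)) thr_cadd[rb == b] <- ov
  }
  st <- apply_cadd_gate(cur, thr_cadd, config$cadd_missing_passes)
  record("cadd_gate", cur$variants$variant_id, st$verdict)
  cur <- st$cohort
  funnel <- funnel_add(funnel, "cadd_gate", cur$variants$region)

  # -- conservation ---------------------------------------------------------
  st <- apply_conservation(cur, config$conservation_mode, config$gerp_min,
                           config$phastcons_min, config$conservation_action)
  record("conservation", cur$variants$variant_id, st$verdict)
  conserved <- st$conserved[st$verdict]
  cur <- st$cohort
  funnel <- funnel_add(funnel, "conservation", cur$variants$region)

  # -- region routing + branch evaluation -----------------------------------
  branch <- route_region(cur$variants$region)
  m <- n_variants(cur)
  bverdict <- rep(TRUE, m)
  cols <- list(vote_pass = rep(NA, m), high_impact = rep(FALSE, m),
               review_reason = rep(NA_character_, m),
               intolerance_pass = rep(NA, m),
               intolerance_unassessed = rep(NA, m),
               mirna_target = rep(FALSE, m),
               evidence_level = rep(NA_real_, m),
               evidence = rep(NA_character_, m),
               branch_rank = rep(NA_integer_, m))
  intol_with <- intol_without <- NULL

  cidx <- which(branch == "coding")
  if (length(cidx) > 0L) {
    ev <- evaluate_coding(cur[cidx], config$vote_min,
                          config$intolerance_max_pct,
                          config$intolerance_min_sources,
                          config$intolerance_action)
    bverdict[cidx] <- ev$verdict
    cols$vote_pass[cidx] <- ev$vote_pass
    cols$high_impact[cidx] <- ev$high_impact
    cols$review_reason[cidx] <- ev$review_reason
    cols$intolerance_pass[cidx] <- ev$intolerance_pass
    cols$intolerance_unassessed[cidx] <- ev$intolerance_unassessed
    coding_regions <- cur$variants$region[cidx]
    keep_wo <- ev$verdict
    keep_wi <- ev$verdict & ev$intolerance_pass
    intol_without <- table(factor(coding_regions[keep_wo],
                                  levels = REGION_LEVELS))
    intol_with <- if (config$intolerance_action == "off") intol_without
                  else table(factor(coding_regions[keep_wi],
                                    levels = REGION_LEVELS))
  }
  for (b in c("utr5", "utr3", "intergenic")) {
    bidx <- which(branch == b)
    if (length(bidx) == 0L) next
    ev <- evaluate_noncoding(cur[bidx], b, config$min_evidence_level,
                             config$mirsvr_cutoff, config$mirna_action,
                             conserved = conserved[bidx])
    bverdict[bidx] <- ev$verdict
    cols$mirna_target[bidx] <- ev$mirna_target
    cols$evidence_level[bidx] <- ev$evidence$ordinal
    cols$evidence[bidx] <- ev$evidence$evidence
    cols$branch_rank[bidx[ev$rank_order]] <- seq_along(ev$rank_order)
  }
  # branch "other": reported, never silently dropped
  oidx <- which(branch == "other")
  cols$review_reason[oidx] <- "region class outside the four distal branches"

  record("branch", cur$variants$variant_id, bverdict)
  surv <- cur[bverdict]
  funnel <- funnel_add(funnel, "branch", surv$variants$region)
  funnel$intolerance <- if (is.null(intol_with)) NULL else
    list(with = as.list(intol_with), without = as.list(intol_without))

  # -- provenance: first failing stage --------------------------------------
  fail_stage <- rep(NA_character_, n)
  for (s in rev(PIPELINE_STAGES)) fail_stage[!is.na(prov[[s]]) &
                                               !prov[[s]]] <- s
  prov$first_failing_stage <- fail_stage

  # -- candidate assembly + ranking -----------------------------------------
  keep <- bverdict
  cand <- cbind(cur$variants[keep, , drop = FALSE],
                cur$annotations[keep, setdiff(names(cur$annotations),
                                              "variant_id"), drop = FALSE])
  cand$branch <- branch[keep]
  cand$cadd_tier <- cadd_tier(cand$cadd_phred)
  cand$conserved <- conserved[keep]
  for (cn in names(cols)) cand[[cn]] <- cols[[cn]][keep]
  cand$vote_count <- if (nrow(cand) == 0L) integer(0) else
    rowSums(matrix(vapply(PREDICTOR_KEYS,
                          function(k) !is.na(cand[[k]]) &
                            cand[[k]] == "deleterious",
                          logical(nrow(cand))),
                   nrow = nrow(cand)))
  tier_ord <- match(cand$cadd_tier, c("missing", "below", "top10", "top1",
                                      "top01"))
  ord <- order(-tier_ord, -cand$vote_count,
               -ifelse(is.na(cand$cadd_phred), -1, cand$cadd_phred))
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  cand$rank <- seq_len(nrow(cand))

  validate_funnel(funnel)
  structure(list(candidates = cand, funnel = funnel,
                 relatedness = relatedness, provenance = prov,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", nrow(x$candidates), "candidate variant(s)\n")
  print(x$funnel)
  if (!is.null(x$relatedness)) {
    fl <- attr(x$relatedness, "flagged")
    cat("relatedness:", nrow(fl), "flagged pair(s)\n")
  }
  invisible(x)
}

#' Run the pipeline from files
#'
#' Convenience wrapper for the CLI: reads the VCF, PED and status sidecar
#' (plus an optional TSV annotation sidecar), runs [run_pipeline()].
#'
#' @param vcf,ped_path,statuses input file paths
#' @param config a [pipeline_config()] or a JSON config path
#' @param annotations optional annotation sidecar TSV
#' @param key_map see [default_key_map()]
#' @return a `pipeline_result`
#' @export
run_pipeline_files <- function(vcf, ped_path, statuses,
                               config = pipeline_config(),
                               annotations = NULL,
                               key_map = default_key_map()) {
  if (is.character(config)) config <- read_config(config)
  cohort <- read_annotated_vcf(vcf, key_map, annotation_tsv = annotations)
  ped <- read_pedigree(ped_path, statuses)
  missing <- setdiff(cohort$samples, sequenced_members(ped))
  if (length(missing) > 0L)
    stop("VCF sample(s) not sequenced in the pedigree: ",
         paste(missing, collapse = ", "))
  run_pipeline(cohort, ped, config)
}

#' Write pipeline outputs
#'
#' Writes the candidate table (TSV, one row per surviving variant with all
#' annotation fields and per-stage verdicts), the machine-readable funnel
#' report (JSON, stages in executed order), the per-variant provenance
#' table and, when available, the relatedness report. Output is
#' deterministic: re-running on identical inputs gives byte-identical files.
#'
#' @param result a `pipeline_result`
#' @param out_dir output directory (created if needed)
#' @return named character vector of written paths
#' @export
write_outputs <- function(result, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- c(candidates = file.path(out_dir, "candidates.tsv"),
             funnel = file.path(out_dir, "funnel.json"),
             provenance = file.path(out_dir, "provenance.tsv"))
  utils::write.table(result$candidates, paths["candidates"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  fdf <- as.data.frame(result$funnel)
  fl <- list(stages = lapply(seq_len(nrow(fdf)), function(i) {
    list(stage = fdf$stage[i],
         counts = as.list(fdf[i, REGION_LEVELS]),
         total = fdf$total[i])
  }))
  if (!is.null(result$funnel$intolerance))
    fl$intolerance <- result$funnel$intolerance
  jsonlite::write_json(fl, paths["funnel"], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  utils::write.table(result$provenance, paths["provenance"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  if (!is.null(result$relatedness)) {
    paths <- c(paths, relatedness = file.path(out_dir, "relatedness.tsv"))
    utils::write.table(as.data.frame(result$relatedness),
                       paths["relatedness"], sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  }
  paths
}
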