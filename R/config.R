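# Flat pipeline configuration: defaults, JSON round-trip, validation.

config_descriptions <- c(
  min_qual = "Phred site quality a variant must exceed (strict)",
  min_depth = "read depth each carrier sample must exceed (strict)",
  strict_qc = "use strict > comparisons for quality/depth (FALSE: >=)",
  require_strand = "SNVs need pooled alt support on both strands",
  missing_filter_fails = "indels with missing FILTER fail technical QC",
  depth_scope = "enforce min_depth on 'carrier' samples or 'all' samples",
  maf_cutoff = "population MAF below which a variant counts as rare (strict <)",
  relatedness_rank_tolerance = "kinship-rank inversions tolerated per sample pair",
  relatedness_kinship_gap = "minimum expected-kinship difference for an inversion to count",
  relatedness_sharing_gap = "minimum observed-sharing difference for an inversion to count",
  relatedness_noise_z = "binomial-SE multiplier guarding the sharing comparisons against sampling noise",
  relatedness_unrelated_max = "max rare-variant Jaccard sharing for expectedly unrelated pairs",
  strict_relatedness = "abort the run on any flagged pair (default: warn)",
  seg_model = "inheritance model for the carrier set (dominant)",
  seg_max_missing_definite = "definite cases allowed to lack the variant",
  seg_max_missing_phenocopy = "possible-phenocopy cases allowed to lack it ('unlimited')",
  seg_max_carrier_noncarrier = "non-carrier controls allowed to carry it",
  seg_max_carrier_possible = "possible-carrier controls allowed to carry it ('unlimited')",
  seg_missing_rule = "'noninformative': missing genotype constrains nothing; 'strict': fails definite-case/non-carrier-control constraints",
  cadd_min = "scaled CADD a variant must exceed to stay in consideration",
  cadd_min_coding = "per-region override of cadd_min for the coding branch (NA: use cadd_min)",
  cadd_min_utr5 = "per-region override of cadd_min for 5'UTR variants (NA: use cadd_min)",
  cadd_min_utr3 = "per-region override of cadd_min for 3'UTR variants (NA: use cadd_min)",
  cadd_min_intergenic = "per-region override of cadd_min for intronic/intergenic variants (NA: use cadd_min)",
  cadd_missing_passes = "let variants without a CADD score through the gate",
  conservation_mode = "'either': GERP or PhastCons passing suffices; 'both': require both",
  conservation_action = "'flag': report conservation only; 'gate': drop failures",
  gerp_min = "GERP score indicating good conservation (strict >)",
  phastcons_min = "PhastCons score indicating good conservation (strict >)",
  vote_min = "deleterious calls (of 4 predictors) a missense variant needs",
  intolerance_max_pct = "gene-intolerance percentile at or below which a source qualifies",
  intolerance_min_sources = "qualifying intolerance sources required (1-3)",
  intolerance_action = "'flag': annotate only; 'gate': drop; 'off': skip sub-stage",
  mirsvr_cutoff = "mirSVR score below which a 3'UTR variant is a good miRNA target (strict <)",
  mirna_action = "'flag': promote good targets in ranking; 'gate': drop non-targets",
  min_evidence_level = "minimum regulatory-evidence ordinal for non-coding survivors (0 reports all)"
)

#' Pipeline configuration
#'
#' One flat key/value set holding every threshold of the cascade. The
#' defaults are the pipeline's canonical operating point: site quality > 20,
#' carrier depth > 5x, MAF < 0.1%, scaled CADD > 10, GERP > 2.0 /
#' PhastCons > 0.3, 3-of-4 deleterious consensus, mirSVR < -0.1.
#'
#' @param ... named overrides of individual keys (see
#'   [write_config_template()] for the full key list with descriptions)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_qual = 20, min_depth = 5, strict_qc = TRUE, require_strand = TRUE,
    missing_filter_fails = TRUE, depth_scope = "carrier",
    maf_cutoff = 0.001,
    relatedness_rank_tolerance = 0, relatedness_kinship_gap = 0.05,
    relatedness_sharing_gap = 0.02, relatedness_noise_z = 4,
    relatedness_unrelated_max = 0.10,
    strict_relatedness = FALSE,
    seg_model = "dominant", seg_max_missing_definite = 0,
    seg_max_missing_phenocopy = Inf, seg_max_carrier_noncarrier = 0,
    seg_max_carrier_possible = Inf, seg_missing_rule = "noninformative",
    cadd_min = 10, cadd_min_coding = NA, cadd_min_utr5 = NA,
    cadd_min_utr3 = NA, cadd_min_intergenic = NA,
    cadd_missing_passes = FALSE,
    conservation_mode = "either", conservation_action = "flag",
    gerp_min = 2.0, phastcons_min = 0.3,
    vote_min = 3, intolerance_max_pct = 25, intolerance_min_sources = 1,
    intolerance_action = "flag",
    mirsvr_cutoff = -0.1, mirna_action = "flag",
    min_evidence_level = 0
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(structure(cfg, class = "pipeline_config"))
}

validate_config <- function(cfg) {
  required <- names(config_descriptions)
  miss <- setdiff(required, names(cfg))
  if (length(miss) > 0L)
    stop("missing required config key(s): ", paste(miss, collapse = ", "))
  if (!cfg$intolerance_min_sources %in% 1:3)
    stop("contradictory config: intolerance_min_sources must be 1, 2 or 3")
  if (cfg$vote_min < 0 || cfg$vote_min > 4)
    stop("contradictory config: vote_min must be between 0 and 4")
  if (cfg$maf_cutoff < 0 || cfg$maf_cutoff > 1)
    stop("contradictory config: maf_cutoff must lie in [0, 1]")
  stopifnot(cfg$seg_model == "dominant",
            cfg$depth_scope %in% c("carrier", "all"),
            cfg$conservation_mode %in% c("either", "both"),
            cfg$conservation_action %in% c("flag", "gate"),
            cfg$intolerance_action %in% c("flag", "gate", "off"),
            cfg$mirna_action %in% c("flag", "gate"),
            cfg$seg_missing_rule %in% c("noninformative", "strict"))
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' Missing keys take their defaults; the string `"unlimited"` (or -1, or
#' `null`) means an unlimited segregation tolerance.
#'
#' @param path JSON file
#' @return a [pipeline_config()]
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[!startsWith(names(raw), "_")]
  for (k in grep("^seg_max_", names(raw), value = TRUE)) {
    v <- raw[[k]]
    if (is.null(v) || identical(v, "unlimited") ||
        (is.numeric(v) && v < 0)) raw[[k]] <- Inf
  }
  # JSON null (e.g. an unset per-region override) means "use the default"
  for (k in names(raw)) if (is.null(raw[[k]])) raw[[k]] <- NA
  do.call(pipeline_config, raw)
}

#' Write a config template with documented defaults
#'
#' Emits the default configuration as JSON; a parallel `_descriptions`
#' block explains what each threshold does.
#'
#' @param path output path
#' @return invisibly, `path`
#' @export
write_config_template <- function(path) {
  cfg <- unclass(pipeline_config())
  for (k in names(cfg)) if (is.infinite(cfg[[k]])) cfg[[k]] <- "unlimited"
  out <- c(cfg, list(`_descriptions` = as.list(config_descriptions)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
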