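# Core containers: the annotated multi-sample variant cohort.

#' Region classes recognised by the pipeline
#'
#' Functional region classes a variant may be assigned by the upstream
#' annotator. `missense`, `other_coding` and `splicing` are coding classes;
#' `utr5`/`utr3` are untranslated regions; `intronic` and `intergenic` are
#' evaluated together on the regulatory branch.
#'
#' @export
REGION_LEVELS <- c("missense", "other_coding", "splicing",
                   "utr5", "utr3", "intronic", "intergenic", "other")

#' Five-level analysis statuses for sequenced pedigree members
#'
#' Each sequenced member is assigned a carrier-probability status that
#' determines how the segregation filter constrains them:
#' `CASE_DEFINITE` (affected, assumed to carry the familial variant),
#' `CASE_POSSIBLE_PHENOCOPY` (affected but plausibly a phenocopy, e.g. very
#' late onset), `CONTROL_NONCARRIER` (unaffected past the family's diagnostic
#' age, assumed non-carrier), `CONTROL_POSSIBLE_CARRIER` (unaffected but
#' plausibly a carrier, e.g. young or with heavy first-degree family
#' history), and `UNINFORMATIVE` (never constrains segregation).
#'
#' @export
STATUS_LEVELS <- c("CASE_DEFINITE", "CASE_POSSIBLE_PHENOCOPY",
                   "CONTROL_NONCARRIER", "CONTROL_POSSIBLE_CARRIER",
                   "UNINFORMATIVE")

# RegulomeDB-style rank vocabulary, weakest first; ordinal = position.
REGULOME_LEVELS <- c("7", "6", "5", "4", "3b", "3a",
                     "2c", "2b", "2a", "1f", "1e", "1d", "1c", "1b", "1a")

PREDICTOR_KEYS <- c("mutation_taster", "polyphen2", "provean", "sift")
INTOLERANCE_KEYS <- c("intol_inhouse", "intol_esp", "intol_exac")

ANNOTATION_COLS <- c("maf_1kg", "maf_exac", "cadd_phred", "gerp", "phastcons",
                     PREDICTOR_KEYS, INTOLERANCE_KEYS,
                     "regulome_rank", "haploreg_flags", "mirsvr")

#' Construct an annotated variant cohort
#'
#' The central in-memory container: per-variant site information, per-sample
#' genotype/read evidence matrices, and the external annotation bundle. All
#' downstream filter stages operate on this object.
#'
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `vclass` ("SNV"/"INDEL"), `region` (one of
#'   [REGION_LEVELS]), `qual` (Phred site quality), `filter` (upstream caller
#'   FILTER string, `NA` if missing).
#' @param samples character vector of sample identifiers (the sequenced
#'   cohort members, in VCF column order).
#' @param geno list of numeric matrices, one row per variant and one column
#'   per sample: `gt` (alt-allele dosage 0/1/2, `NA` = missing genotype),
#'   `dp` (read depth), `adf`/`adr` (alt-supporting forward/reverse reads).
#' @param annotations data.frame with one row per variant carrying the
#'   annotation bundle; missing annotations are `NA`, never imputed.
#'
#' @return An object of class `variant_cohort`.
#' @export
variant_cohort <- function(variants, samples, geno = NULL, annotations = NULL) {
  stopifnot(is.data.frame(variants))
  req <- c("variant_id", "chrom", "pos", "ref", "alt", "vclass", "region",
           "qual", "filter")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0L)
    stop("variants is missing columns: ", paste(miss, collapse = ", "))
  variants <- as.data.frame(variants)[req]
  variants$pos <- as.integer(variants$pos)
  n <- nrow(variants)
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant_id values")
  if (any(variants$pos < 1L, na.rm = TRUE)) stop("pos must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref must differ from alt")
  is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  if (any(is_snv != (variants$vclass == "SNV")))
    stop("vclass must be SNV exactly when ref and alt are single bases")
  bad_region <- !variants$region %in% REGION_LEVELS
  if (any(bad_region))
    stop("unknown region class: ",
         paste(unique(variants$region[bad_region]), collapse = ", "))

  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  m <- length(samples)

  blank <- function() {
    matrix(NA_real_, nrow = n, ncol = m,
           dimnames = list(variants$variant_id, samples))
  }
  if (is.null(geno)) geno <- list()
  for (k in c("gt", "dp", "adf", "adr")) {
    if (is.null(geno[[k]])) {
      geno[[k]] <- blank()
    } else {
      gm <- as.matrix(geno[[k]])
      if (!all(dim(gm) == c(n, m)))
        stop("geno$", k, " must be ", n, " x ", m)
      dimnames(gm) <- list(variants$variant_id, samples)
      storage.mode(gm) <- "double"
      geno[[k]] <- gm
    }
  }
  geno <- geno[c("gt", "dp", "adf", "adr")]
  if (any(geno$gt < 0 | geno$gt > 2, na.rm = TRUE))
    stop("gt dosages must be 0, 1 or 2")
  known <- !is.na(geno$adf) & !is.na(geno$adr) & !is.na(geno$dp)
  if (any((geno$adf + geno$adr)[known] > geno$dp[known]))
    stop("alt strand reads exceed depth")

  if (is.null(annotations)) {
    annotations <- empty_annotations(variants$variant_id)
  } else {
    annotations <- as.data.frame(annotations)
    if (!"variant_id" %in% names(annotations))
      stop("annotations needs a variant_id column")
    for (k in setdiff(ANNOTATION_COLS, names(annotations)))
      annotations[[k]] <- if (k %in% c(PREDICTOR_KEYS, "regulome_rank",
                                       "haploreg_flags")) NA_character_
                          else NA_real_
    annotations <- annotations[match(variants$variant_id,
                                     annotations$variant_id),
                               c("variant_id", ANNOTATION_COLS)]
    if (anyNA(annotations$variant_id))
      stop("annotations missing rows for some variants")
    rownames(annotations) <- NULL
  }
  validate_annotations(annotations)

  structure(list(variants = variants, samples = samples, geno = geno,
                 annotations = annotations),
            class = "variant_cohort")
}

empty_annotations <- function(ids) {
  ann <- data.frame(variant_id = ids, stringsAsFactors = FALSE)
  for (k in ANNOTATION_COLS)
    ann[[k]] <- if (k %in% c(PREDICTOR_KEYS, "regulome_rank",
                             "haploreg_flags")) NA_character_ else NA_real_
  ann
}

validate_annotations <- function(ann) {
  rng <- function(x, lo, hi, what) {
    if (any(x < lo | x > hi, na.rm = TRUE))
      stop(what, " outside [", lo, ", ", hi, "]")
  }
  rng(ann$maf_1kg, 0, 1, "maf_1kg")
  rng(ann$maf_exac, 0, 1, "maf_exac")
  rng(ann$phastcons, 0, 1, "phastcons")
  if (any(ann$cadd_phred < 0, na.rm = TRUE))
    stop("cadd_phred must be non-negative")
  for (k in INTOLERANCE_KEYS) rng(ann[[k]], 0, 100, k)
  for (k in PREDICTOR_KEYS) {
    bad <- !is.na(ann[[k]]) & !ann[[k]] %in% c("deleterious", "tolerated")
    if (any(bad)) stop(k, " calls must be deleterious/tolerated/NA")
  }
  bad_rank <- !is.na(ann$regulome_rank) &
    !ann$regulome_rank %in% REGULOME_LEVELS
  if (any(bad_rank))
    stop("unrecognised regulome rank: ",
         paste(unique(ann$regulome_rank[bad_rank]), collapse = ", "))
  invisible(ann)
}

#' @export
print.variant_cohort <- function(x, ...) {
  cat("variant_cohort:", nrow(x$variants), "variants x",
      length(x$samples), "samples\n")
  tab <- table(factor(x$variants$region, levels = REGION_LEVELS))
  cat("  regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' Number of variants in a cohort
#' @param cohort a [variant_cohort()]
#' @return integer count
#' @export
n_variants <- function(cohort) nrow(cohort$variants)

#' Subset a cohort by variant
#'
#' @param x a [variant_cohort()]
#' @param i variant index (logical, integer or variant_id character)
#' @param ... ignored
#' @return the subsetted `variant_cohort`
#' @export
`[.variant_cohort` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$variants$variant_id)
  v <- x$variants[i, , drop = FALSE]
  rownames(v) <- NULL
  a <- x$annotations[i, , drop = FALSE]
  rownames(a) <- NULL
  g <- lapply(x$geno, function(mat) mat[i, , drop = FALSE])
  structure(list(variants = v, samples = x$samples, geno = g,
                 annotations = a),
            class = "variant_cohort")
}

# carrier indicator matrix under the dominant model; NA preserved
carrier_matrix <- function(cohort) cohort$geno$gt >= 1

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
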